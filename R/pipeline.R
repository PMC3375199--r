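#' Run the full promoter-quadruplex analysis
#'
#' Orchestrates the stages scan -> map -> differential expression -> G4
#' membership enrichment -> positional subsets -> loop-combination grid ->
#' loop-composition KDE/KS, and writes every stage output plus a
#' reproducibility manifest into `out_dir`.
#'
#' Inputs may be given either as in-memory objects (`seqs`, `anchors`,
#' `expr`) or generated with `simulate = TRUE` under `sim` (a
#' [sim_config()]).
#'
#' @param seqs Named character vector of sequences (ignored with
#'   `simulate = TRUE`).
#' @param anchors Annotation data.frame.
#' @param expr A `"g4prom_expr"` object.
#' @param condition Condition of interest for the DE stage; defaults to the
#'   second condition label.
#' @param simulate Generate the inputs with the synthetic module.
#' @param sim A [sim_config()] used when `simulate = TRUE`.
#' @param window Promoter half-window in bp (default 2000).
#' @param mode Motif-to-gene assignment mode (`"nearest"` or `"all"`).
#' @param p_max,r_min,p_unchanged DE selection thresholds.
#' @param out_dir Output directory; `NULL` (default) skips writing.
#' @param probe_gene Optional probe-to-gene map (data.frame `probe_id`,
#'   `gene_id`).
#' @return List of class `"g4prom_run"` with elements `motifs`,
#'   `assignments`, `de`, `gene_sets`, `membership` (per-set enrichment),
#'   `subsets` (af/ar/bf/br enrichment per set), `combos` (loop-combination
#'   tables), `distribution` (per-gene motif-count table), `summary`
#'   (Table-1-like per-set summary), `composition` (KDE/KS tables) and
#'   `manifest`.
#' @export
run_pipeline <- function(seqs = NULL, anchors = NULL, expr = NULL,
                         condition = NULL, simulate = FALSE,
                         sim = sim_config(), window = 2000L,
                         mode = "nearest", p_max = 0.05, r_min = 0.9,
                         p_unchanged = 0.75, out_dir = NULL,
                         probe_gene = NULL) {
  t0 <- Sys.time()
  truth <- NULL
  if (simulate) {
    genome <- simulate_genome(sim)
    xp <- simulate_expression(sim, genome)
    seqs <- genome$seqs
    anchors <- genome$anchors
    expr <- xp$expr
    probe_gene <- xp$probe_gene
    truth <- list(genome = genome$truth, de = xp$truth)
    window <- sim$window
  }
  stopifnot(!is.null(seqs), !is.null(anchors), !is.null(expr))
  if (is.null(condition)) condition <- unique(expr$groups)[2L]

  motifs <- deduplicate_motifs(scan_pg4(seqs))
  asg <- assign_motifs(motifs, anchors, window = window, mode = mode)
  de <- run_de(expr, condition, p_max = p_max, r_min = r_min,
               p_unchanged = p_unchanged, probe_gene = probe_gene)
  gene_sets <- list(up = de$up, down = de$down, de = union(de$up, de$down),
                    unchanged = de$unchanged, universe = de$universe)

  counts <- genes_with_motif(asg$assignments)
  g4_genes <- names(counts)
  membership <- do.call(rbind, lapply(
    c("up", "down", "de", "unchanged"), function(nm) {
      cbind(data.frame(set = nm, stringsAsFactors = FALSE),
            membership_enrichment(gene_sets[[nm]], g4_genes,
                                  gene_sets$universe))
    }))

  by_set <- function(nm) {
    a <- asg$assignments
    a[a$gene_id %in% gene_sets[[nm]], , drop = FALSE]
  }
  ref_asg <- by_set("unchanged")
  subsets <- NULL
  if (nrow(ref_asg) > 0L) {
    subsets <- do.call(rbind, lapply(c("up", "down"), function(nm) {
      cbind(data.frame(set = nm, stringsAsFactors = FALSE),
            subset_enrichment(by_set(nm), ref_asg))
    }))
  }

  dedup_asg_motifs <- function(a) {
    four_tract_subset(deduplicate_motifs(
      a[, c("seq_id", "start", "end", "motif_strand", "n_tracts",
            "matched", "loops")]))
  }
  bg4 <- four_tract_subset(motifs)
  combos <- lapply(c("up", "down", "unchanged"), function(nm) {
    loop_combo_enrichment(dedup_asg_motifs(by_set(nm)), bg4)
  })
  names(combos) <- c("up", "down", "unchanged")

  distribution <- count_distribution(
    counts, gene_sets[c("up", "down", "unchanged", "universe")])

  summary_tab <- do.call(rbind, lapply(
    c("up", "down", "de", "unchanged", "universe"), function(nm) {
      gs <- gene_sets[[nm]]
      m4 <- dedup_asg_motifs(by_set(nm))
      data.frame(set = nm, n_genes = length(gs),
                 n_genes_with_motif = sum(g4_genes %in% gs),
                 n_motifs = nrow(dedup_asg_motifs_all(by_set(nm))),
                 avg_loop_length = if (nrow(m4) > 0L)
                   average_loop_length(m4) else NA_real_,
                 stringsAsFactors = FALSE)
    }))

  composition <- .composition_tables(dedup_asg_motifs, by_set)

  manifest <- list(
    tool = "g4prom",
    version = tryCatch(as.character(utils::packageVersion("g4prom")),
                       error = function(e) "dev"),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    parameters = list(window = window, mode = mode, p_max = p_max,
                      r_min = r_min, p_unchanged = p_unchanged,
                      condition = condition,
                      simulate = simulate,
                      seed = if (simulate) sim$seed else NULL),
    counts = list(n_sequences = length(seqs), n_anchors = nrow(anchors),
                  n_motifs = nrow(motifs),
                  n_assigned = nrow(asg$assignments),
                  n_unassigned = nrow(asg$unassigned),
                  n_probes = nrow(expr$values),
                  n_up = length(de$up), n_down = length(de$down),
                  n_unchanged = length(de$unchanged)))

  out <- structure(list(motifs = motifs, assignments = asg$assignments,
                        unassigned = asg$unassigned, de = de,
                        gene_sets = gene_sets, membership = membership,
                        subsets = subsets, combos = combos,
                        distribution = distribution, summary = summary_tab,
                        composition = composition, manifest = manifest,
                        truth = truth),
                   class = "g4prom_run")
  if (!is.null(out_dir)) .write_run(out, out_dir)
  out
}

# all deduplicated motifs of an assignment subset (any tract count)
dedup_asg_motifs_all <- function(a) {
  deduplicate_motifs(a[, c("seq_id", "start", "end", "motif_strand",
                           "n_tracts", "matched", "loops")])
}

# per-query composition samples, KDE grids and KS tests vs the unchanged set
.composition_tables <- function(dedup_asg_motifs, by_set) {
  queries <- c("A", "C", "G", "T", "AT", "CT", "GT")
  sets <- c("up", "down", "unchanged")
  samples <- list()
  for (nm in sets) {
    m4 <- dedup_asg_motifs(by_set(nm))
    for (q in queries)
      samples[[paste(nm, q, sep = ".")]] <-
        if (nrow(m4) > 0L) loop_composition(m4, q) else numeric(0)
  }
  ks_rows <- list()
  kde_rows <- list()
  for (q in queries) {
    ref <- samples[[paste("unchanged", q, sep = ".")]]
    for (nm in c("up", "down")) {
      x <- samples[[paste(nm, q, sep = ".")]]
      if (length(x) >= 2L && length(ref) >= 2L) {
        kt <- ks_two_sample(x, ref)
        ks_rows[[paste(nm, q)]] <- data.frame(
          set = nm, query = q, n_set = length(x), n_ref = length(ref),
          D = kt$D, p = kt$p, ties = kt$ties,
          zero_fraction_set = zero_exclusion_fraction(x),
          zero_fraction_ref = zero_exclusion_fraction(ref),
          stringsAsFactors = FALSE)
      }
    }
    for (nm in sets) {
      x <- samples[[paste(nm, q, sep = ".")]]
      if (length(unique(x)) >= 2L) {
        k <- kde(x)
        kde_rows[[paste(nm, q)]] <- data.frame(
          set = nm, query = q, grid = k$grid, density = k$density,
          bandwidth = k$bandwidth, stringsAsFactors = FALSE)
      }
    }
  }
  list(samples = samples,
       ks = if (length(ks_rows) > 0L) do.call(rbind, ks_rows) else NULL,
       kde = if (length(kde_rows) > 0L) do.call(rbind, kde_rows) else NULL)
}

.write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_motifs_bed(run$motifs, p("motifs.bed"))
  write_assignments(run$assignments, p("assignments.tsv"),
                    params = run$manifest$parameters["window"])
  .write_tsv(run$de$stats, p("de_stats.tsv"))
  write_gene_lists(list(de.up = run$gene_sets$up,
                        de.down = run$gene_sets$down,
                        de.unchanged = run$gene_sets$unchanged,
                        de.universe = run$gene_sets$universe),
                   p("gene_sets.tsv"))
  write_enrichment(run$membership, p("membership_enrichment.tsv"))
  if (!is.null(run$subsets))
    write_enrichment(run$subsets, p("subset_enrichment.tsv"))
  for (nm in names(run$combos))
    write_enrichment(run$combos[[nm]], p(paste0("loop_combos_", nm, ".tsv")))
  .write_tsv(run$distribution, p("motif_count_distribution.tsv"))
  .write_tsv(run$summary, p("set_summary.tsv"))
  if (!is.null(run$composition$ks))
    .write_tsv(run$composition$ks, p("composition_ks.tsv"))
  if (!is.null(run$composition$kde))
    .write_tsv(run$composition$kde, p("composition_kde.tsv"))
  jsonlite::write_json(run$manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.g4prom_run <- function(x, ...) {
  cat("g4prom run:", x$manifest$counts$n_motifs, "motifs on",
      x$manifest$counts$n_sequences, "sequences;",
      x$manifest$counts$n_up, "up,", x$manifest$counts$n_down, "down,",
      x$manifest$counts$n_unchanged, "unchanged genes\n")
  invisible(x)
}
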