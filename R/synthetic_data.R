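#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic promoter / expression
#' generator.  Identical seed and configuration give byte-identical outputs;
#' the genome and expression stages draw from deterministically derived
#' substreams (`seed` and `seed + 1`) so either stage can be regenerated
#' independently.
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes (one promoter contig per gene, TSS
#'   centered).
#' @param window Promoter half-window in bp within which motifs are planted
#'   and mapped (default 2000).
#' @param promoter_len Contig length in bp (default `2 * window + 500`, so
#'   the full window fits on the contig).
#' @param gc_background Background GC fraction (default 0.45).
#' @param g4_gene_fraction Fraction of genes that receive planted motifs
#'   (default 0.65).
#' @param motifs_per_gene Either a fixed integer or a list
#'   `list(prob =, max =)` describing a truncated geometric distribution
#'   (number of motifs = 1 + truncated geometric; default `prob = 0.6`,
#'   `max = 16`).
#' @param loop_len_probs Probability vector over loop lengths 1-7.
#' @param loop_base_probs Named probability vector over `A,C,G,T` for loop
#'   bases (tokens containing `GGG` are rejection-sampled away).
#' @param side_probs Probabilities of planting before/after the TSS.
#' @param strand_probs Probabilities of the forward/reverse relative strand.
#' @param groups Two condition labels, control first (default
#'   `c("control", "treated")`).
#' @param n_samples_per_group Replicates per condition (default 3).
#' @param de_fraction Fraction of genes that are truly differentially
#'   expressed (default 0.15).
#' @param effect_size Log-intensity shift applied to DE genes in the
#'   treatment group (default 2.5, i.e. five noise standard deviations: a
#'   strong, clean treatment effect, so that the correlation filter of the
#'   selection stage is well powered at triplicate depth).
#' @param g4_de_odds_ratio Planted odds ratio between motif-bearing and DE
#'   status (default 1).
#' @param noise_sd Per-observation Gaussian noise sd (default 0.5).
#' @param baseline_mean,baseline_sd Distribution of per-probe baseline
#'   log-intensities (defaults 8 and 1.5).
#' @return Validated configuration list of class `"g4prom_sim_config"`.
#' @export
sim_config <- function(seed = 1L, n_genes = 200L, window = 2000L,
                       promoter_len = 2L * window + 500L,
                       gc_background = 0.45, g4_gene_fraction = 0.65,
                       motifs_per_gene = list(prob = 0.6, max = 16L),
                       loop_len_probs = c(0.30, 0.20, 0.15, 0.12, 0.10,
                                          0.08, 0.05),
                       loop_base_probs = c(A = 0.30, C = 0.15, G = 0.20,
                                           T = 0.35),
                       side_probs = c(before = 0.5, after = 0.5),
                       strand_probs = c(forward = 0.5, reverse = 0.5),
                       groups = c("control", "treated"),
                       n_samples_per_group = 3L,
                       de_fraction = 0.15, effect_size = 2.5,
                       g4_de_odds_ratio = 1, noise_sd = 0.5,
                       baseline_mean = 8, baseline_sd = 1.5) {
  chk_prob <- function(p, len, what) {
    if (length(p) != len || any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop(what, " must be a length-", len, " probability vector summing to 1")
  }
  stopifnot(n_genes >= 10L, window > 0L, promoter_len > 2L * 30L,
            gc_background >= 0, gc_background <= 1,
            g4_gene_fraction >= 0, g4_gene_fraction <= 1,
            n_samples_per_group >= 2L, length(groups) == 2L,
            de_fraction >= 0, de_fraction <= 1,
            g4_de_odds_ratio > 0, noise_sd > 0)
  chk_prob(loop_len_probs, 7L, "loop_len_probs")
  chk_prob(loop_base_probs, 4L, "loop_base_probs")
  chk_prob(side_probs, 2L, "side_probs")
  chk_prob(strand_probs, 2L, "strand_probs")
  cfg <- as.list(environment())
  cfg$chk_prob <- NULL
  structure(cfg, class = "g4prom_sim_config")
}

# draw a motif-per-gene count
.draw_motif_count <- function(spec, n) {
  if (is.numeric(spec) && length(spec) == 1L) return(rep(as.integer(spec), n))
  pmin(stats::rgeom(n, spec$prob) + 1L, as.integer(spec$max))
}

# sample one motif string and its loop tokens; no loop contains "GGG"
.sample_motif <- function(cfg) {
  lens <- sample(1:7, 3L, replace = TRUE, prob = cfg$loop_len_probs)
  # tokens may not contain GGG nor start/end with G: this keeps the four
  # planted stems the only GGG substrings of the motif, so the greedy parse
  # is unique and equals the planted decomposition exactly
  loops <- vapply(lens, function(l) {
    for (try in 1:200) {
      tok <- paste(sample(names(cfg$loop_base_probs), l, replace = TRUE,
                          prob = cfg$loop_base_probs), collapse = "")
      if (!grepl("GGG", tok, fixed = TRUE) && !startsWith(tok, "G") &&
          !endsWith(tok, "G")) return(tok)
    }
    stop("could not sample an admissible loop token")
  }, character(1))
  list(text = paste0("GGG", loops[1], "GGG", loops[2], "GGG", loops[3],
                     "GGG"),
       loops = loops)
}

.pg4_pattern <- function(min_loop = 1L, max_loop = 7L, min_tracts = 4L) {
  sprintf("(?:G{3}[ACGT]{%d,%d}){%d,}G{3}", min_loop, max_loop,
          min_tracts - 1L)
}

# fast reverse complement of one short string (avoids Biostrings overhead
# inside the per-motif planting loop)
.rc1 <- function(s) {
  ch <- strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]
  paste(rev(ch), collapse = "")
}

#' Simulate promoter contigs with planted PG4 motifs
#'
#' One contig per gene, TSS centered, background bases i.i.d. at the
#' configured GC.  Motif-bearing genes receive motifs with loops drawn from
#' the configured length and base distributions, planted on the sampled
#' side/relative strand at a uniform distance within the window.  Planted
#' motifs are spaced well apart, their loops never contain `GGG`, 10-bp
#' flanking zones are cleared of bases that could extend a match, and every
#' contig is verified against a PCRE scan of both strands so that the
#' per-strand match spans are exactly the planted spans (contigs failing
#' verification are resampled; this is what makes the planted truth table an
#' exact oracle for the scanner).
#'
#' @param cfg A `"g4prom_sim_config"`.
#' @return List with `seqs` (named character vector of contigs), `anchors`
#'   (annotation data.frame), `truth` (planted-motif data.frame with the same
#'   columns as a scan plus `gene_id`, `distance`, `side`, `rel_strand`,
#'   `subset`) and `config`.
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "g4prom_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  L <- cfg$promoter_len
  tss <- L %/% 2L
  gene_id <- sprintf("g%05d", seq_len(n))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  n_pos <- round(cfg$g4_gene_fraction * n)
  pos_idx <- if (n_pos > 0L) sort(sample.int(n, n_pos)) else integer(0)
  m_counts <- integer(n)
  m_counts[pos_idx] <- .draw_motif_count(cfg$motifs_per_gene, n_pos)

  gc <- cfg$gc_background
  base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases_raw <- charToRaw("ACGT")
  gen_bg <- function(k) {
    big <- rawToChar(sample(bases_raw, k * L, replace = TRUE,
                            prob = base_probs))
    substring(big, (seq_len(k) - 1L) * L + 1L, seq_len(k) * L)
  }

  pattern <- .pg4_pattern()
  # truth rows accumulate as plain vectors (one data.frame built at the end)
  build_one <- function(i, contig) {
    m <- m_counts[i]
    if (m == 0L) return(list(contig = contig, truth = NULL))
    occupied <- matrix(numeric(0), ncol = 2L) # padded intervals
    tr <- list(start = integer(m), end = integer(m),
               motif_strand = character(m), matched = character(m),
               loops = character(m), distance = integer(m),
               side = character(m), rel_strand = character(m))
    for (j in seq_len(m)) {
      mot <- .sample_motif(cfg)
      len <- nchar(mot$text)
      rel <- sample(names(cfg$strand_probs), 1L, prob = cfg$strand_probs)
      side <- sample(names(cfg$side_probs), 1L, prob = cfg$side_probs)
      motif_strand <- if (rel == "forward") strand[i] else
        c("+" = "-", "-" = "+")[[strand[i]]]
      d_max <- min(cfg$window, tss - len %/% 2L - 15L)
      placed <- FALSE
      for (try in 1:50) {
        d <- if (side == "after") sample.int(d_max + 1L, 1L) - 1L else
          -sample.int(d_max, 1L)
        anchor <- tss + if (strand[i] == "+") d else -d
        start <- anchor - len %/% 2L
        end <- start + len
        pad <- c(start - 12L, end + 12L)
        clash <- nrow(occupied) > 0L &&
          any(pad[1L] < occupied[, 2L] & occupied[, 1L] < pad[2L])
        if (!clash) { placed <- TRUE; break }
      }
      if (!placed)
        stop("could not place motif ", j, " on gene ", gene_id[i],
             " after 50 tries (window too crowded)")
      occupied <- rbind(occupied, pad)
      text_fwd <- if (motif_strand == "+") mot$text else .rc1(mot$text)
      substr(contig, start + 1L, end) <- text_fwd
      # clear 10-bp flanking zones of bases that could extend the match
      hazard <- if (motif_strand == "+") "G" else "C"
      for (zone in list(c(start - 10L, start), c(end, end + 10L))) {
        z1 <- max(zone[1L], 0L) + 1L
        z2 <- min(zone[2L], L)
        if (z1 > z2) next
        zs <- strsplit(substr(contig, z1, z2), "")[[1L]]
        hit <- zs == hazard
        if (any(hit)) {
          zs[hit] <- sample(c("A", "T"), sum(hit), replace = TRUE)
          substr(contig, z1, z2) <- paste(zs, collapse = "")
        }
      }
      tr$start[j] <- start
      tr$end[j] <- end
      tr$motif_strand[j] <- motif_strand
      tr$matched[j] <- mot$text
      tr$loops[j] <- paste(mot$loops, collapse = ",")
      tr$distance[j] <- d
      tr$side[j] <- side
      tr$rel_strand[j] <- rel
    }
    tr$gene <- rep(gene_id[i], m)
    list(contig = contig, truth = tr)
  }

  # vectorized span verification of a batch of contigs against planted truth
  verify_batch <- function(cs, trs) {
    fwd <- gregexpr(pattern, cs, perl = TRUE)
    rcs <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(cs)))
    rev <- gregexpr(pattern, rcs, perl = TRUE)
    spans <- function(m) {
      if (m[1L] == -1L) return(character(0))
      paste(as.integer(m) - 1L, as.integer(m) - 1L + attr(m, "match.length"))
    }
    vapply(seq_along(cs), function(i) {
      tr <- trs[[i]]
      Lc <- nchar(cs[i])
      got_f <- spans(fwd[[i]])
      rc_sp <- rev[[i]]
      got_r <- if (rc_sp[1L] == -1L) character(0) else
        paste(Lc - (as.integer(rc_sp) - 1L + attr(rc_sp, "match.length")),
              Lc - (as.integer(rc_sp) - 1L))
      if (is.null(tr))
        return(length(got_f) == 0L && length(got_r) == 0L)
      plus <- tr$motif_strand == "+"
      setequal(got_f, paste(tr$start[plus], tr$end[plus])) &&
        length(got_f) == sum(plus) &&
        setequal(got_r, paste(tr$start[!plus], tr$end[!plus])) &&
        length(got_r) == sum(!plus)
    }, logical(1))
  }

  contigs <- character(n)
  truths <- vector("list", n)
  pending <- seq_len(n)
  for (attempt in 1:20) {
    if (length(pending) == 0L) break
    bg <- gen_bg(length(pending))
    built <- lapply(seq_along(pending),
                    function(j) build_one(pending[j], bg[j]))
    cs <- vapply(built, `[[`, character(1), "contig")
    trs <- lapply(built, `[[`, "truth")
    ok <- verify_batch(cs, trs)
    contigs[pending[ok]] <- cs[ok]
    truths[pending[ok]] <- trs[ok]
    pending <- pending[!ok]
  }
  if (length(pending) > 0L)
    stop(length(pending), " contig(s) failed span verification after 20 ",
         "resamples; background GC ", gc, " may be too quadruplex-prone")
  names(contigs) <- gene_id
  nonnull <- truths[!vapply(truths, is.null, logical(1))]
  fld <- function(f) unlist(lapply(nonnull, `[[`, f), use.names = FALSE)
  truth <- data.frame(
    seq_id = as.character(fld("gene")), start = as.integer(fld("start")),
    end = as.integer(fld("end")),
    motif_strand = as.character(fld("motif_strand")),
    n_tracts = rep(4L, length(fld("start"))),
    matched = as.character(fld("matched")),
    loops = as.character(fld("loops")),
    gene_id = as.character(fld("gene")),
    distance = as.integer(fld("distance")),
    side = as.character(fld("side")),
    rel_strand = as.character(fld("rel_strand")),
    stringsAsFactors = FALSE)
  truth$subset <- paste0(substr(truth$side, 1L, 1L),
                         substr(truth$rel_strand, 1L, 1L))
  if (nrow(truth) == 0L) truth$subset <- character(0)
  truth <- truth[order(truth$seq_id, truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  anchors <- data.frame(gene_id = gene_id, mrna_id = gene_id,
                        seq_id = gene_id, tss = tss, strand = strand,
                        stringsAsFactors = FALSE)
  list(seqs = contigs, anchors = anchors, truth = truth, config = cfg)
}

# solve the 2x2 margin equations for the count of DE & feature-positive genes
# given n1 feature-positive, n0 feature-negative, d DE genes and odds ratio
.solve_de_overlap <- function(n1, n0, d, or) {
  a_min <- max(0, d - n0)
  a_max <- min(d, n1)
  if (a_min > a_max)
    stop("no feasible 2x2 table: d = ", d, " with margins n1 = ", n1,
         ", n0 = ", n0)
  if (d == 0L) return(0L)
  f <- function(a) a * (n0 - d + a) - or * (n1 - a) * (d - a)
  if (f(a_min) > 0 || f(a_max) < 0)
    stop("odds ratio ", or, " not attainable with margins (n1 = ", n1,
         ", n0 = ", n0, ", d = ", d, ")")
  a <- stats::uniroot(f, c(a_min, a_max), tol = 1e-9)$root
  as.integer(max(a_min, min(a_max, round(a))))
}

# draw the DE & feature-positive overlap count from Fisher's noncentral
# hypergeometric distribution with odds parameter `or`.  Its mean solves the
# same 2x2 margin equations as .solve_de_overlap, and at or = 1 it reduces
# to the central hypergeometric -- the exact null of the downstream
# enrichment test, so null runs of the pipeline see properly dispersed
# overlap counts rather than one frozen table
.sample_de_overlap <- function(n1, n0, d, or) {
  ks <- seq.int(max(0L, d - n0), min(d, n1))
  if (length(ks) == 1L) return(ks)
  lw <- lchoose(n1, ks) + lchoose(n0, d - ks) + ks * log(or)
  sample(ks, 1L, prob = exp(lw - max(lw)))
}

#' Simulate an expression matrix with a planted G4/DE association
#'
#' Baseline per-probe log-intensities are Gaussian; the set of truly
#' differentially expressed genes is drawn so that the odds ratio between
#' motif-bearing status (from the genome truth table) and DE status realizes
#' the configured value: the overlap count is sampled from Fisher's
#' noncentral hypergeometric distribution with odds parameter
#' `g4_de_odds_ratio`, whose mean solves the 2x2 margin equations, and genes
#' are then sampled from each stratum.  At odds ratio 1 the overlap is
#' therefore exactly central-hypergeometric -- the null distribution of the
#' downstream enrichment test.  DE genes receive a `+/- effect_size` shift in
#' the treatment group; every observation gets Gaussian noise.  Probes map
#' one-to-one to genes.
#'
#' @param cfg A `"g4prom_sim_config"`.
#' @param genome Output of [simulate_genome()] under the same config.
#' @return List with `expr` (a `"g4prom_expr"`), `truth` (list with `up`,
#'   `down`, `de`, `unchanged` gene id vectors and the solved overlap count
#'   `n_de_g4`) and `probe_gene` map.
#' @export
simulate_expression <- function(cfg, genome) {
  stopifnot(inherits(cfg, "g4prom_sim_config"))
  set.seed(cfg$seed + 1L)
  genes <- genome$anchors$gene_id
  g4_pos <- unique(genome$truth$gene_id)
  g4_neg <- setdiff(genes, g4_pos)
  d <- round(cfg$de_fraction * length(genes))
  .solve_de_overlap(length(g4_pos), length(g4_neg), d,
                    cfg$g4_de_odds_ratio) # feasibility check (may error)
  a <- .sample_de_overlap(length(g4_pos), length(g4_neg), d,
                          cfg$g4_de_odds_ratio)
  de <- c(if (a > 0L) sample(g4_pos, a),
          if (d - a > 0L) sample(g4_neg, d - a))
  up <- sample(de, length(de) %/% 2L)
  down <- setdiff(de, up)
  n_rep <- cfg$n_samples_per_group
  sample_ids <- paste0(rep(cfg$groups, each = n_rep), "_", seq_len(n_rep))
  groups <- stats::setNames(rep(cfg$groups, each = n_rep), sample_ids)
  np <- length(genes)
  vals <- matrix(stats::rnorm(np, cfg$baseline_mean, cfg$baseline_sd),
                 nrow = np, ncol = 2L * n_rep) +
    matrix(stats::rnorm(np * 2L * n_rep, 0, cfg$noise_sd), nrow = np)
  rownames(vals) <- genes
  colnames(vals) <- sample_ids
  trt <- groups == cfg$groups[2L]
  vals[match(up, genes), trt] <- vals[match(up, genes), trt] +
    cfg$effect_size
  vals[match(down, genes), trt] <- vals[match(down, genes), trt] -
    cfg$effect_size
  list(expr = expression_matrix(vals, groups),
       truth = list(up = up, down = down, de = de,
                    unchanged = setdiff(genes, de), n_de_g4 = a),
       probe_gene = data.frame(probe_id = genes, gene_id = genes,
                               stringsAsFactors = FALSE))
}

#' Write a full simulated dataset to disk
#'
#' Writes FASTA contigs, the TSV annotation, the expression matrix, the
#' sample sheet and both truth tables into a directory.
#'
#' @param cfg A `"g4prom_sim_config"`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the list of generated objects.
#' @export
simulate_dataset <- function(cfg, out_dir) {
  genome <- simulate_genome(cfg)
  expr <- simulate_expression(cfg, genome)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(genome$seqs, file.path(out_dir, "promoters.fasta"))
  write_annotation(genome$anchors, file.path(out_dir, "annotation.tsv"))
  .write_tsv(genome$truth, file.path(out_dir, "motif_truth.tsv"))
  m <- data.frame(probe_id = rownames(expr$expr$values),
                  expr$expr$values, check.names = FALSE,
                  stringsAsFactors = FALSE)
  .write_tsv(m, file.path(out_dir, "expression.tsv"))
  .write_tsv(data.frame(sample_id = names(expr$expr$groups),
                        condition = unname(expr$expr$groups),
                        stringsAsFactors = FALSE),
             file.path(out_dir, "samples.tsv"))
  write_gene_lists(list(truth.up = expr$truth$up, truth.down = expr$truth$down,
                        truth.unchanged = expr$truth$unchanged),
                   file.path(out_dir, "de_truth.tsv"))
  invisible(list(genome = genome, expression = expr))
}
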