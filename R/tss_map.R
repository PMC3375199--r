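#' Assign PG4 motifs to genes by TSS proximity
#'
#' Each motif is anchored at its integer midpoint `floor((start + end) / 2)`
#' on the forward reference.  The signed distance from a gene's TSS is
#' measured in the gene's 5' to 3' orientation (negative = upstream of the
#' TSS); a motif is assignable to a gene iff `|distance| <= window`.  With
#' `mode = "nearest"` only the gene(s) at minimal `|distance|` are kept (ties
#' keep all tied genes, with a message); with `mode = "all"` every in-window
#' gene is kept.
#'
#' Each assignment is classified into one of four positional/strand subsets:
#' \describe{
#'   \item{side}{`"before"` iff `distance < 0`; a motif anchored exactly at
#'     the TSS (distance 0) is `"after"` since the TSS base is transcribed.}
#'   \item{rel_strand}{`"forward"` iff the motif's G-rich run lies on the
#'     gene's annotated sense strand, else `"reverse"`.}
#'   \item{subset}{`af`, `ar`, `bf` or `br` (first letters of side and
#'     relative strand).}
#' }
#'
#' @param motifs Motif data.frame from [scan_pg4()].
#' @param anchors Annotation data.frame from [read_annotation()].
#' @param window Half-width of the promoter window in bp (default 2000).
#' @param mode `"nearest"` (default) or `"all"`.
#' @param anchor_point `"midpoint"` (default) or `"start5"` (the motif's
#'   5'-most base on its own strand).
#' @return List with `assignments` (data.frame: motif columns plus
#'   `gene_id`, `mrna_id`, `distance`, `side`, `rel_strand`, `subset`) and
#'   `unassigned` (motifs with no in-window anchor).
#' @export
assign_motifs <- function(motifs, anchors, window = 2000L,
                          mode = c("nearest", "all"),
                          anchor_point = c("midpoint", "start5")) {
  mode <- match.arg(mode)
  anchor_point <- match.arg(anchor_point)
  stopifnot(nrow(anchors) > 0L, window > 0L)
  if (nrow(motifs) == 0L)
    return(list(assignments = .empty_assignments(motifs),
                unassigned = motifs))
  anchor <- switch(anchor_point,
    midpoint = (motifs$start + motifs$end) %/% 2L,
    start5 = ifelse(motifs$motif_strand == "+", motifs$start,
                    motifs$end - 1L))
  motifs$.anchor <- anchor
  motifs$.key <- seq_len(nrow(motifs))
  # cross motifs with same-contig anchors
  j <- merge(motifs, anchors, by = "seq_id")
  if (nrow(j) > 0L) {
    offset <- j$.anchor - j$tss
    j$distance <- ifelse(j$strand == "+", offset, -offset)
    j <- j[abs(j$distance) <= window, , drop = FALSE]
  } else {
    j$distance <- integer(0)
  }
  n_ties <- 0L
  if (mode == "nearest" && nrow(j) > 0L) {
    keep <- unlist(lapply(split(seq_len(nrow(j)), j$.key), function(idx) {
      d <- abs(j$distance[idx])
      idx[d == min(d)]
    }), use.names = FALSE)
    n_ties <- length(keep) - length(unique(j$.key))
    j <- j[sort(keep), , drop = FALSE]
  }
  if (n_ties > 0L)
    message(n_ties, " nearest-TSS tie(s); all tied anchors kept")
  j$side <- ifelse(j$distance < 0L, "before", "after")
  j$rel_strand <- ifelse(j$motif_strand == j$strand, "forward", "reverse")
  j$subset <- paste0(substr(j$side, 1L, 1L), substr(j$rel_strand, 1L, 1L))
  assigned_keys <- unique(j$.key)
  unassigned <- motifs[!(motifs$.key %in% assigned_keys),
                       setdiff(names(motifs), c(".anchor", ".key")),
                       drop = FALSE]
  cols <- c("seq_id", "start", "end", "motif_strand", "n_tracts", "matched",
            "loops", "gene_id", "mrna_id", "distance", "side", "rel_strand",
            "subset")
  out <- j[order(j$.key), cols, drop = FALSE]
  rownames(out) <- NULL
  rownames(unassigned) <- NULL
  list(assignments = out, unassigned = unassigned)
}

.empty_assignments <- function(motifs) {
  cbind(motifs[0, , drop = FALSE],
        data.frame(gene_id = character(0), mrna_id = character(0),
                   distance = integer(0), side = character(0),
                   rel_strand = character(0), subset = character(0),
                   stringsAsFactors = FALSE))
}

#' Count deduplicated motifs per gene
#'
#' @param assignments Assignment data.frame from [assign_motifs()].
#' @return Named integer vector: gene_id -> number of distinct motifs within
#'   the window.  Genes absent from the result have zero motifs.
#' @export
genes_with_motif <- function(assignments) {
  if (nrow(assignments) == 0L)
    return(stats::setNames(integer(0), character(0)))
  key <- paste(assignments$seq_id, assignments$start, assignments$end,
               assignments$motif_strand, assignments$gene_id)
  a <- assignments[!duplicated(key), , drop = FALSE]
  tab <- table(a$gene_id)
  stats::setNames(as.integer(tab), names(tab))
}

#' Distribution of per-gene motif counts within gene sets
#'
#' For each gene set, the fraction of its motif-bearing genes having exactly
#' `m` motifs in the promoter window, for `m = 1..cap`, plus an overflow
#' bucket for genes with more than `cap` motifs.  Fractions sum to 1 per set
#' (including overflow).
#'
#' @param gene_counts Named integer vector from [genes_with_motif()].
#' @param gene_sets Named list of character vectors of gene ids.
#' @param cap Largest count shown individually (default 16).
#' @return Data.frame with columns `set`, `m` (`1..cap` and `">cap"`),
#'   `n_genes`, `fraction`.
#' @export
count_distribution <- function(gene_counts, gene_sets, cap = 16L) {
  rows <- lapply(names(gene_sets), function(nm) {
    cnt <- gene_counts[names(gene_counts) %in% gene_sets[[nm]]]
    cnt <- cnt[cnt >= 1L]
    m_lab <- c(as.character(seq_len(cap)), paste0(">", cap))
    n <- vapply(seq_len(cap), function(m) sum(cnt == m), integer(1))
    n <- c(n, sum(cnt > cap))
    if (sum(n) == 0L) {
      warning("gene set '", nm, "' has no motif-bearing genes")
      frac <- rep(0, cap + 1L)
    } else {
      frac <- n / sum(n)
    }
    data.frame(set = nm, m = m_lab, n_genes = n, fraction = frac,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write motif assignments as TSV
#'
#' @param assignments Assignment data.frame.
#' @param path Output path.
#' @param params Optional named list recorded in the commented header.
#' @export
write_assignments <- function(assignments, path, params = NULL) {
  .write_tsv(assignments, path, params)
}
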