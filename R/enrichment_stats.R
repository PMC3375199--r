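#' Exact hypergeometric enrichment/depletion test
#'
#' Given a universe of `N` items of which `K` carry a feature, and a sample
#' of `n` items of which `k` carry it, computes the exact tail probabilities
#' `p_enrich = P(X >= k)` and `p_deplete = P(X <= k)` of the hypergeometric
#' distribution (evaluated in log space, so universes of tens of thousands of
#' genes do not underflow), together with the sample and universe percentages
#' and the fold enrichment `(k/n) / (K/N)`.  Vectorized over its arguments.
#'
#' @param N Universe size.
#' @param K Feature-positive items in the universe.
#' @param n Sample size.
#' @param k Feature-positive items in the sample.
#' @return Data.frame with columns `N`, `K`, `n`, `k`, `pct_sample`,
#'   `pct_universe`, `fold`, `p_enrich`, `p_deplete`.
#' @export
hypergeom_test <- function(N, K, n, k) {
  r <- data.frame(N = N, K = K, n = n, k = k)
  with(r, {
    if (any(K < 0 | K > N)) stop("bound violated: 0 <= K <= N")
    if (any(n < 0 | n > N)) stop("bound violated: 0 <= n <= N")
    if (any(k > pmin(n, K))) stop("bound violated: k <= min(n, K)")
    if (any(k < pmax(0, n + K - N))) stop("bound violated: k >= max(0, n+K-N)")
  })
  # upper tail P(X >= k) = P(X > k - 1); lower tail P(X <= k)
  r$pct_sample <- ifelse(r$n > 0, 100 * r$k / r$n, NA_real_)
  r$pct_universe <- ifelse(r$N > 0, 100 * r$K / r$N, NA_real_)
  r$fold <- ifelse(r$K > 0 & r$n > 0, (r$k / r$n) / (r$K / r$N), NA_real_)
  r$p_enrich <- stats::phyper(r$k - 1, r$K, r$N - r$K, r$n,
                              lower.tail = FALSE)
  r$p_deplete <- stats::phyper(r$k, r$K, r$N - r$K, r$n)
  r
}

#' Hypergeometric enrichment of a feature within a gene set
#'
#' Tests whether `sample` genes carry the feature (e.g. "has at least one
#' promoter PG4 motif") more often than expected from the universe.
#'
#' @param sample Character vector of gene ids (must lie within `universe`).
#' @param feature_genes Character vector of feature-positive gene ids.
#' @param universe Character vector of all gene ids under consideration.
#' @return One-row data.frame as from [hypergeom_test()].
#' @export
membership_enrichment <- function(sample, feature_genes, universe) {
  sample <- unique(sample)
  universe <- unique(universe)
  feature_genes <- unique(feature_genes)
  out <- setdiff(sample, universe)
  if (length(out) > 0L)
    stop("sample genes outside the universe: ",
         paste(utils::head(out, 10L), collapse = ", "))
  hypergeom_test(N = length(universe),
                 K = length(intersect(universe, feature_genes)),
                 n = length(sample),
                 k = length(intersect(sample, feature_genes)))
}

#' Positional/strand subset enrichment (af / ar / bf / br)
#'
#' For each of the four subsets, the pooled assignments (set plus reference)
#' form the universe, membership in the subset is the feature, and the set's
#' assignments are the sample; both tails are reported so that both
#' over-representation (`p_enrich`) and under-representation (`p_deplete`)
#' can be read off.
#'
#' @param set_assignments Assignment data.frame of the gene set of interest.
#' @param ref_assignments Assignment data.frame of the reference (e.g.
#'   non-differentially-expressed) set.
#' @return Data.frame with one row per subset (`af`, `ar`, `bf`, `br`).
#' @export
subset_enrichment <- function(set_assignments, ref_assignments) {
  if (nrow(ref_assignments) == 0L) stop("empty reference assignment set")
  subsets <- c("af", "ar", "bf", "br")
  pool <- c(set_assignments$subset, ref_assignments$subset)
  n <- nrow(set_assignments)
  N <- length(pool)
  rows <- lapply(subsets, function(s) {
    cbind(data.frame(subset = s, stringsAsFactors = FALSE),
          hypergeom_test(N = N, K = sum(pool == s), n = n,
                         k = sum(set_assignments$subset == s)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Loop-length-combination enrichment table (7 x 7 x 7 grid)
#'
#' Counts four-tract motifs per `(loop1, loop2, loop3)` length combination in
#' a motif set and a background, and tests each of the 343 cells with the
#' hypergeometric test (`N` = background size, `K` = background cell count,
#' `n` = set size, `k` = set cell count).  Loops of length `max_loop + 1`
#' (a surplus G absorbed from a 4-G run) are routed to the top length bin,
#' with a message giving the routed count.  Cells empty in both set and
#' background are flagged `no_data`.  When the set holds fewer motifs than
#' there are combinations, the table is flagged as too small for significance
#' testing (attribute `significance_tested = FALSE`), mirroring the exclusion
#' of undersized sets from testing; counts and p-values are still returned.
#'
#' @param set_motifs,background_motifs Four-tract motif data.frames
#'   (deduplicated; see [four_tract_subset()] and [deduplicate_motifs()]).
#' @param max_loop Upper loop-length bin (default 7).
#' @return Data.frame with 343 rows: `l1`, `l2`, `l3`, `count_set`,
#'   `count_bg`, `p_enrich`, `p_deplete`, `q` (BH over tested cells),
#'   `no_data`.  Attributes: `n_set`, `n_bg`, `n_routed`,
#'   `significance_tested`.
#' @export
loop_combo_enrichment <- function(set_motifs, background_motifs,
                                  max_loop = 7L) {
  len3 <- function(motifs, who) {
    if (nrow(motifs) == 0L)
      return(matrix(integer(0), ncol = 3L))
    if (any(motifs$n_tracts != 4L))
      stop("non-4-tract motif present in ", who)
    lens <- t(vapply(motif_loops(motifs), nchar, integer(3)))
    lens
  }
  ls <- len3(set_motifs, "set")
  lb <- len3(background_motifs, "background")
  n_routed <- sum(ls > max_loop) + sum(lb > max_loop)
  if (n_routed > 0L)
    message(n_routed, " loop(s) of length ", max_loop + 1L,
            " routed to bin ", max_loop)
  ls <- pmin(ls, max_loop)
  lb <- pmin(lb, max_loop)
  grid <- expand.grid(l1 = seq_len(max_loop), l2 = seq_len(max_loop),
                      l3 = seq_len(max_loop))
  cell_id <- function(m) {
    if (nrow(m) == 0L) return(integer(0))
    (m[, 1L] - 1L) * max_loop^2 + (m[, 2L] - 1L) * max_loop + m[, 3L]
  }
  gid <- (grid$l1 - 1L) * max_loop^2 + (grid$l2 - 1L) * max_loop + grid$l3
  grid$count_set <- as.integer(tabulate(cell_id(ls), nbins = max_loop^3))[gid]
  grid$count_bg <- as.integer(tabulate(cell_id(lb), nbins = max_loop^3))[gid]
  n_set <- nrow(set_motifs)
  n_bg <- nrow(background_motifs)
  ht <- hypergeom_test(N = n_bg, K = grid$count_bg, n = rep(n_set, nrow(grid)),
                       k = pmin(grid$count_set, grid$count_bg))
  # a set cell count exceeding the background cell count violates the
  # sampling-without-replacement model; flag such cells untestable
  testable <- grid$count_set <= grid$count_bg
  grid$p_enrich <- ifelse(testable, ht$p_enrich, NA_real_)
  grid$p_deplete <- ifelse(testable, ht$p_deplete, NA_real_)
  grid$no_data <- grid$count_set == 0L & grid$count_bg == 0L
  grid$q <- NA_real_
  tested <- testable & !grid$no_data
  grid$q[tested] <- stats::p.adjust(grid$p_enrich[tested], "BH")
  attr(grid, "n_set") <- n_set
  attr(grid, "n_bg") <- n_bg
  attr(grid, "n_routed") <- n_routed
  attr(grid, "significance_tested") <- n_set >= max_loop^3
  if (n_set < max_loop^3 && n_set > 0L)
    message("set holds ", n_set, " motifs, fewer than the ", max_loop^3,
            " combinations; flagged as not tested for significance")
  grid
}

#' Write an enrichment table as TSV
#'
#' @param tab Data.frame from any of the enrichment functions.
#' @param path Output path.
#' @param params Optional named list recorded in the commented header.
#' @export
write_enrichment <- function(tab, path, params = NULL) {
  .write_tsv(tab, path, params)
}
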