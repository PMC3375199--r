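#' Average loop length of a motif set
#'
#' Mean over all individual loop lengths pooled across (deduplicated) motifs
#' -- not the mean of per-motif means.  The two coincide when every motif has
#' the same number of loops, as after four-tract filtering.
#'
#' @param motifs Motif data.frame.
#' @return Mean loop length in nt.
#' @export
average_loop_length <- function(motifs) {
  if (nrow(motifs) == 0L) stop("no motifs")
  mean(unlist(lapply(motif_loops(motifs), nchar)))
}

#' Loop base-composition frequency of one motif
#'
#' The fraction of all loop bases that belong to the query base set; 0 means
#' no loop base matches the query, 1 means every loop base does.
#'
#' @param loops Character vector of loop tokens of one motif.
#' @param query One of `"A"`, `"C"`, `"G"`, `"T"`, `"AT"`, `"CT"`, `"GT"`.
#' @return Frequency in `[0, 1]`.
#' @export
composition_frequency <- function(loops, query = c("A", "C", "G", "T",
                                                   "AT", "CT", "GT")) {
  query <- match.arg(query)
  total <- sum(nchar(loops))
  stopifnot("motif with zero total loop length" = total > 0L)
  joined <- paste(loops, collapse = "")
  hits <- sum(nchar(gsub(paste0("[^", query, "]"), "", joined)))
  hits / total
}

#' Per-motif composition frequencies for a motif set
#'
#' @param motifs Four-tract motif data.frame (deduplicated).
#' @param query Query base set, as in [composition_frequency()].
#' @return Numeric vector of per-motif frequencies in `[0, 1]`.
#' @export
loop_composition <- function(motifs, query = "C") {
  vapply(motif_loops(motifs), composition_frequency, numeric(1),
         query = query)
}

#' Gaussian kernel density estimate of composition frequencies
#'
#' Default bandwidth is Silverman's rule of thumb,
#' `0.9 * min(sd, IQR/1.34) * n^(-1/5)` (R's `bw.nrd0`); the density is
#' evaluated on 512 evenly spaced grid points extending three bandwidths
#' beyond the data range.
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @param bandwidth `"silverman"` (default) or a positive number.
#' @return List with `grid`, `density` and `bandwidth`.
#' @export
kde <- function(values, bandwidth = "silverman") {
  if (length(unique(values)) < 2L)
    stop("all values identical; use a histogram instead of a KDE")
  bw <- if (identical(bandwidth, "silverman")) stats::bw.nrd0(values)
        else {
          stopifnot(is.numeric(bandwidth), bandwidth > 0)
          bandwidth
        }
  d <- stats::density(values, bw = bw, kernel = "gaussian", n = 512L,
                      cut = 3)
  list(grid = d$x, density = d$y, bandwidth = bw)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum over the pooled sample points of the gap between the
#' two empirical CDFs.  By default the p-value comes from the asymptotic
#' two-sample Kolmogorov distribution with effective size `|x||y|/(|x|+|y|)`
#' (the samples in promoter-scale analyses number in the thousands);
#' `exact = TRUE` requests the exact small-sample p when `|x||y| <= 10^4` and
#' there are no ties.  With ties the asymptotic p is flagged approximate.
#'
#' @param x,y Numeric vectors with at least 2 values each.
#' @param exact Use the exact p-value when feasible (default `FALSE`).
#' @return List with `D`, `p` and logical `ties`.
#' @export
ks_two_sample <- function(x, y, exact = FALSE) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- exact && !ties && length(x) * length(y) <= 1e4
  kt <- suppressWarnings(stats::ks.test(x, y, exact = use_exact))
  list(D = unname(kt$statistic), p = unname(kt$p.value), ties = ties)
}

#' Fraction of motifs that completely exclude the query bases
#'
#' @param values Numeric vector of per-motif composition frequencies.
#' @return Fraction of values exactly 0.
#' @export
zero_exclusion_fraction <- function(values) {
  if (length(values) == 0L) return(0)
  mean(values == 0)
}
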