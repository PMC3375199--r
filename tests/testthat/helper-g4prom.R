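# shared test helpers: independent oracles and small builders

# random DNA sequence at a given GC fraction
random_seq <- function(len, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# independent regex-engine oracle: 0-based half-open spans of the leftmost
# non-overlapping greedy matches of the canonical PG4 pattern on one strand
oracle_spans <- function(seq, min_loop = 1L, max_loop = 7L,
                         min_tracts = 4L) {
  pat <- sprintf("(?:G{3}[ACGT]{%d,%d}){%d,}G{3}", min_loop, max_loop,
                 min_tracts - 1L)
  m <- gregexpr(pat, seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) - 1L + attr(m, "match.length"))
}

# build a motif data.frame row from a motif string (scanned in isolation)
motif_row <- function(seq_id, start, matched, strand = "+") {
  d <- decompose_pg4(matched)
  data.frame(seq_id = seq_id, start = start, end = start + nchar(matched),
             motif_strand = strand, n_tracts = length(d$stems),
             matched = matched, loops = paste(d$loops, collapse = ","),
             stringsAsFactors = FALSE)
}

# exhaustive-enumeration hypergeometric tails via explicit draw counting
enum_hyper <- function(N, K, n, k) {
  items <- c(rep(1L, K), rep(0L, N - K))
  draws <- utils::combn(N, n)
  hits <- colSums(matrix(items[draws], nrow = n))
  c(p_enrich = mean(hits >= k), p_deplete = mean(hits <= k))
}

# combinatorial-sum hypergeometric tails (choose products, no phyper)
sum_hyper <- function(N, K, n, k) {
  j <- max(0L, n + K - N):min(n, K)
  pmf <- choose(K, j) * choose(N - K, n - j) / choose(N, n)
  c(p_enrich = sum(pmf[j >= k]), p_deplete = sum(pmf[j <= k]))
}

# brute-force two-sample KS statistic: sup of the ECDF gap over pooled points
brute_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# trapezoid integral of a KDE result
kde_integral <- function(k) {
  sum(diff(k$grid) * (utils::head(k$density, -1) + utils::tail(k$density, -1)) / 2)
}

# small expression object: probes x (2 groups x reps)
make_expr <- function(values, n_rep = ncol(values) / 2L,
                      groups = c("ctl", "trt")) {
  ids <- paste0(rep(groups, each = n_rep), "_", seq_len(n_rep))
  colnames(values) <- ids
  if (is.null(rownames(values)))
    rownames(values) <- paste0("p", seq_len(nrow(values)))
  expression_matrix(values, stats::setNames(rep(groups, each = n_rep), ids))
}
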