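test_that("hypergeom_test matches the worked small-case examples exactly", {
  r <- hypergeom_test(10, 5, 4, 4)
  expect_equal(r$p_enrich, 5 / 210, tolerance = 1e-14)
  r0 <- hypergeom_test(10, 5, 4, 0)
  expect_equal(r0$p_deplete, 5 / 210, tolerance = 1e-14)
  expect_equal(r0$p_enrich, 1)
})

test_that("paper-count percentages are reproduced", {
  r <- hypergeom_test(24651, 16607, 2212, 1804)
  expect_equal(round(r$pct_sample, 2), 81.56)
  expect_equal(round(r$pct_universe, 2), 67.37)
})

test_that("bound violations raise errors naming the inequality", {
  expect_error(hypergeom_test(10, 11, 4, 2), "K <= N")
  expect_error(hypergeom_test(10, 5, 11, 2), "n <= N")
  expect_error(hypergeom_test(10, 5, 4, 5), "k <= min")
  expect_error(hypergeom_test(10, 9, 4, 2), "k >= max")
})

test_that("tails equal true exhaustive enumeration for small cases", {
  set.seed(61)
  for (N in 5:8) for (K in 0:N) for (n in 1:N) {
    ks <- max(0L, n + K - N):min(n, K)
    k <- ks[sample.int(length(ks), 1L)]
    got <- hypergeom_test(N, K, n, k)
    ref <- enum_hyper(N, K, n, k)
    expect_equal(got$p_enrich, unname(ref["p_enrich"]), tolerance = 1e-12)
    expect_equal(got$p_deplete, unname(ref["p_deplete"]), tolerance = 1e-12)
  }
})

test_that("tails equal the combinatorial sum for all valid (N <= 12, K, n, k)", {
  for (N in 0:12) for (K in 0:N) for (n in 0:N) {
    ks <- max(0L, n + K - N):min(n, K)
    got <- hypergeom_test(rep(N, length(ks)), K, n, ks)
    ref <- vapply(ks, function(k) sum_hyper(N, K, n, k), numeric(2))
    expect_equal(got$p_enrich, unname(ref["p_enrich", ]), tolerance = 1e-12)
    expect_equal(got$p_deplete, unname(ref["p_deplete", ]), tolerance = 1e-12)
  }
})

test_that("pmf normalizes and p_enrich is monotone in k", {
  set.seed(62)
  for (i in 1:50) {
    N <- sample(2:500, 1L); K <- sample(0:N, 1L); n <- sample(0:N, 1L)
    ks <- max(0L, n + K - N):min(n, K)
    r <- hypergeom_test(rep(N, length(ks)), K, n, ks)
    pmf <- r$p_enrich - c(r$p_enrich[-1L], 0)
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
    expect_true(all(diff(r$p_enrich) <= 1e-15))
    expect_true(all(r$p_enrich + r$p_deplete >= 1 - 1e-12))
  }
})

test_that("membership_enrichment matches the enumeration example and validates", {
  u <- letters[1:10]
  r <- membership_enrichment(c("a", "b", "c", "d"), letters[1:5], u)
  expect_equal(r$k, 4)
  expect_equal(r$p_enrich, 5 / 210, tolerance = 1e-14)

  full <- membership_enrichment(u, letters[1:5], u)
  expect_equal(full$fold, 1)
  expect_equal(full$p_enrich, 1)

  none <- membership_enrichment(c("a", "b"), c("zz"), u)
  expect_equal(c(none$k, none$K), c(0, 0))
  expect_equal(none$p_enrich, 1)

  expect_error(membership_enrichment(c("a", "qq"), letters[1:5], u),
               "outside the universe: qq")
})

test_that("subset_enrichment orders, balances and matches enumeration", {
  mk <- function(subsets) data.frame(subset = subsets,
                                     stringsAsFactors = FALSE)
  ref <- mk(rep(c("af", "ar", "bf", "br"), each = 3L))
  all_af <- mk(rep("af", 4L))
  r <- subset_enrichment(all_af, ref)
  expect_identical(r$subset, c("af", "ar", "bf", "br"))
  expect_lt(r$p_enrich[r$subset == "af"], r$p_enrich[r$subset == "ar"])

  bal <- subset_enrichment(ref, ref)
  expect_equal(bal$fold, rep(1, 4L))

  # tiny case, pool of 8 with 4 af: sample of 4 with 3 af vs enumeration
  s <- mk(c("af", "af", "af", "bf"))
  rf <- mk(c("af", "bf", "bf", "bf"))
  got <- subset_enrichment(s, rf)
  ref_p <- enum_hyper(8, 4, 4, 3)
  expect_equal(got$p_enrich[got$subset == "af"], unname(ref_p["p_enrich"]),
               tolerance = 1e-12)

  expect_error(subset_enrichment(s, rf[0, , drop = FALSE]),
               "empty reference")
})

test_that("loop_combo_enrichment builds the full 343-cell grid", {
  m <- motif_row("c", 0L, "GGGAGGGTGGGCGGG")
  tab <- suppressMessages(loop_combo_enrichment(m, m))
  expect_equal(nrow(tab), 343L)
  expect_equal(nrow(unique(tab[c("l1", "l2", "l3")])), 343L)
  expect_true(all(tab$l1 %in% 1:7 & tab$l2 %in% 1:7 & tab$l3 %in% 1:7))
})

test_that("combo counts conserve motifs and identical sets give fold-1 cells", {
  set.seed(63)
  g <- simulate_genome(sim_config(seed = 8, n_genes = 60))
  m4 <- four_tract_subset(deduplicate_motifs(scan_pg4(g$seqs)))
  tab <- suppressMessages(loop_combo_enrichment(m4, m4))
  expect_equal(sum(tab$count_set), nrow(m4))
  expect_equal(sum(tab$count_bg), nrow(m4))
  nz <- tab[tab$count_set > 0, ]
  ht <- hypergeom_test(nrow(m4), nz$count_bg, nrow(m4), nz$count_set)
  expect_equal(nz$p_enrich, ht$p_enrich)
  # a single loop combination concentrates all counts in one cell
  one <- motif_row("c", 0L, "GGGAGGGTGGGCGGG") # loops 1,1,1
  t1 <- suppressMessages(loop_combo_enrichment(one, rbind(one, one)))
  expect_equal(sum(t1$count_set), 1L)
  expect_equal(t1$count_set[t1$l1 == 1 & t1$l2 == 1 & t1$l3 == 1], 1L)
})

test_that("the scanner never emits loops longer than max_loop", {
  # a 4-G run followed by a 7-nt spacer cannot be inside a match span:
  # the engine starts the match after the surplus G instead
  m <- scan_pg4(c(s = "GGGGAAAAAAAGGGAGGGAGGG"))
  expect_equal(c(m$start, m$end), c(1L, 22L))
  expect_identical(m$loops, "AAAAAAA,A,A")
})

test_that("over-long loops from external tables route to bin 7; >4 tracts error", {
  # externally produced motif tables may carry the paper-rule length-8 loop
  m8 <- data.frame(seq_id = "c", start = 0L, end = 22L, motif_strand = "+",
                   n_tracts = 4L, matched = "GGGGAAAAAAAGGGAGGGAGGG",
                   loops = "GAAAAAAA,A,A", stringsAsFactors = FALSE)
  expect_message(tab <- loop_combo_enrichment(m8, m8), "routed to bin 7")
  expect_equal(tab$count_set[tab$l1 == 7 & tab$l2 == 1 & tab$l3 == 1], 1L)

  m5 <- motif_row("c", 0L, "GGGAGGGAGGGAGGGAGGG")
  expect_error(suppressMessages(loop_combo_enrichment(m5, m5)),
               "non-4-tract")
})

test_that("undersized sets are flagged as not significance-tested", {
  m <- motif_row("c", 0L, "GGGAGGGTGGGCGGG")
  expect_message(tab <- loop_combo_enrichment(m, m), "fewer than the 343")
  expect_false(attr(tab, "significance_tested"))
})
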