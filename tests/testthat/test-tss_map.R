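anchors1 <- function(tss, strand, gene = "g1", seq_id = "c1") {
  data.frame(gene_id = gene, mrna_id = gene, seq_id = seq_id, tss = tss,
             strand = strand, stringsAsFactors = FALSE)
}

test_that("assignment distance, side, rel_strand and subset follow the conventions", {
  # span [10100, 10120), anchor floor((10100 + 10120) / 2) = 10110
  m <- motif_row("c1", 10100L, "GGGAGGGTGGGCGGGAGGGG")
  a <- assign_motifs(m, anchors1(10000L, "+"))$assignments
  expect_equal(a$distance, 110)
  expect_identical(c(a$side, a$rel_strand, a$subset),
                   c("after", "forward", "af"))

  b <- assign_motifs(m, anchors1(10000L, "-"))$assignments
  expect_equal(b$distance, -110)
  expect_identical(c(b$side, b$rel_strand, b$subset),
                   c("before", "reverse", "br"))
})

test_that("window rule excludes |distance| > window", {
  m <- motif_row("c1", 2050L, "GGGAGGGTGGGCGGG")
  m$end <- 2070L
  res <- assign_motifs(m, anchors1(0L, "+"))
  expect_equal(nrow(res$assignments), 0L)
  expect_equal(nrow(res$unassigned), 1L)
  # exactly at the boundary it is kept
  m2 <- m; m2$start <- 1993L; m2$end <- 2008L # anchor 2000
  expect_equal(nrow(assign_motifs(m2, anchors1(0L, "+"))$assignments), 1L)
})

test_that("nearest mode keeps the closest gene; ties keep all with a message", {
  m <- motif_row("c1", 993L, "GGGAGGGTGGGCGGG") # anchor 1000
  two <- rbind(anchors1(1500L, "+", "far"), anchors1(1300L, "+", "near"))
  a <- assign_motifs(m, two)$assignments
  expect_identical(a$gene_id, "near")
  all_mode <- assign_motifs(m, two, mode = "all")$assignments
  expect_setequal(all_mode$gene_id, c("far", "near"))

  tied <- rbind(anchors1(700L, "+", "left"), anchors1(1300L, "+", "right"))
  expect_message(t <- assign_motifs(m, tied)$assignments, "tie")
  expect_setequal(t$gene_id, c("left", "right"))
})

test_that("distance 0 is classified after, and rel_strand tracks the gene strand", {
  m <- motif_row("c1", 993L, "GGGAGGGTGGGCGGG") # anchor 1000
  a <- assign_motifs(m, anchors1(1000L, "+"))$assignments
  expect_equal(a$distance, 0)
  expect_identical(a$subset, "af")
  a2 <- assign_motifs(m, anchors1(1000L, "-"))$assignments
  expect_identical(a2$subset, "ar")
})

test_that("orientation duality: mirroring the reference preserves subset labels", {
  g <- simulate_genome(sim_config(seed = 3, n_genes = 40))
  motifs <- scan_pg4(g$seqs)
  flip <- function(s) ifelse(s == "+", "-", "+")
  L <- nchar(g$seqs[1L])
  a1 <- assign_motifs(motifs, g$anchors, anchor_point = "start5")$assignments
  # reverse-complement the reference: coordinates mirror, strands flip
  mirrored <- scan_pg4(reverse_complement(g$seqs))
  expect_identical(
    sort(paste(mirrored$seq_id, L - mirrored$end, L - mirrored$start,
               flip(mirrored$motif_strand))),
    sort(paste(motifs$seq_id, motifs$start, motifs$end,
               motifs$motif_strand)))
  an2 <- transform(g$anchors, tss = L - 1L - tss, strand = flip(strand))
  a2 <- assign_motifs(mirrored, an2, anchor_point = "start5")$assignments
  key <- function(a, s, e) paste(a$seq_id, s, e, a$gene_id, a$distance,
                                 a$subset)
  expect_setequal(key(a2, L - a2$end, L - a2$start),
                  key(a1, a1$start, a1$end))
  # flipping only the gene strand swaps before/after and forward/reverse
  a3 <- assign_motifs(motifs, transform(g$anchors, strand = flip(strand)),
                      anchor_point = "start5")$assignments
  nz <- a1$distance != 0L # distance 0 stays "after" under either orientation
  expect_identical(a3$side[nz],
                   ifelse(a1$side[nz] == "before", "after", "before"))
  expect_identical(a3$rel_strand,
                   ifelse(a1$rel_strand == "forward", "reverse", "forward"))
})

test_that("mode=all assigns at least as many motif-gene pairs as mode=nearest", {
  g <- simulate_genome(sim_config(seed = 4, n_genes = 40))
  motifs <- scan_pg4(g$seqs)
  n_near <- nrow(assign_motifs(motifs, g$anchors)$assignments)
  n_all <- nrow(assign_motifs(motifs, g$anchors, mode = "all")$assignments)
  expect_gte(n_all, n_near)
})

test_that("genes_with_motif counts deduplicated motifs per gene", {
  m <- rbind(motif_row("c1", 900L, "GGGAGGGTGGGCGGG"),
             motif_row("c1", 1100L, "GGGAGGGTGGGCGGG"),
             motif_row("c1", 1300L, "GGGAGGGTGGGCGGG"))
  a <- assign_motifs(m, anchors1(1000L, "+"))$assignments
  expect_identical(genes_with_motif(a), c(g1 = 3L))
  # the same motif listed twice counts once
  expect_identical(genes_with_motif(rbind(a[1, ], a[1, ])), c(g1 = 1L))
  expect_length(genes_with_motif(a[0, ]), 0L)
})

test_that("count_distribution fractions follow the worked example and sum to 1", {
  counts <- c(g1 = 1L, g2 = 1L, g3 = 2L, g4 = 5L)
  d <- count_distribution(counts, list(all = names(counts)))
  expect_equal(d$fraction[d$m == "1"], 0.5)
  expect_equal(d$fraction[d$m == "2"], 0.25)
  expect_equal(d$fraction[d$m == "5"], 0.25)
  expect_equal(sum(d$fraction), 1)

  one <- count_distribution(c(a = 1L, b = 1L), list(s = c("a", "b")))
  expect_equal(one$fraction[one$m == "1"], 1)

  over <- count_distribution(c(a = 20L), list(s = "a"))
  expect_equal(over$fraction[over$m == ">16"], 1)

  expect_warning(z <- count_distribution(c(a = 1L), list(s = "zzz")),
                 "no motif-bearing genes")
  expect_true(all(z$fraction == 0))
})
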