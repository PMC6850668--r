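test_that("Bray-Curtis distances match hand computations and invariants", {
  counts <- matrix(c(10L, 10L, 0L,
                     5L, 5L, 10L,
                     10L, 10L, 0L,
                     0L, 0L, 7L), nrow = 3,
                   dimnames = list(c("a", "b", "c"), c("S1", "S2", "S3", "S4")))
  d <- bray_curtis_matrix(otu_table(counts))
  # identical composition (S1 vs S3, after proportion transform) -> 0
  expect_equal(d["S1", "S3"], 0)
  # disjoint OTU sets -> 1
  expect_equal(d["S1", "S4"], 1)
  # x = (.5,.5,0), y = (.25,.25,.5): BC = (.25+.25+.5)/2 = 0.5
  expect_equal(d["S1", "S2"], 0.5)
  # matrix invariants
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))

  # proportion mode is invariant to scaling a sample's counts
  counts2 <- counts; counts2[, 1] <- counts2[, 1] * 13L
  expect_equal(bray_curtis_matrix(otu_table(counts2)), d)

  bad <- counts; bad[, 2] <- 0L
  err <- expect_error(bray_curtis_matrix(otu_table(bad)),
                      class = "paircomm_empty_sample")
  expect_match(conditionMessage(err), "S2")
})

perm_toy_dist <- function() {
  # two clusters of 3: within-cluster distance 0.1, between 0.9
  d <- matrix(0.9, 6, 6, dimnames = rep(list(paste0("s", 1:6)), 2))
  d[1:3, 1:3] <- 0.1
  d[4:6, 4:6] <- 0.1
  diag(d) <- 0
  d
}

test_that("pseudo-F equals brute-force sums of squared distances", {
  d <- perm_toy_dist()
  g <- rep(c("A", "B"), each = 3)
  res <- permanova(d, g, n_perm = 99, seed = 1)
  # brute force: SS_total = sum_{i<j} d^2 / N; SS_within by group
  ss <- function(m) { s <- 0; n <- nrow(m)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) s <- s + m[i, j]^2
    s }
  ss_t <- ss(d) / 6
  ss_w <- ss(d[1:3, 1:3]) / 3 + ss(d[4:6, 4:6]) / 3
  f_expected <- ((ss_t - ss_w) / 1) / (ss_w / 4)
  expect_equal(res$pseudo_F, f_expected, tolerance = 1e-10)
  expect_equal(res$r_squared, (ss_t - ss_w) / ss_t, tolerance = 1e-10)
  # exact enumeration over the C(6,3) = 20 label splits: only the true split
  # and its mirror reach the observed F, so the exact p is 2/20 = 0.1 -- the
  # smallest attainable with three samples per group
  res2 <- permanova(d, g, n_perm = 4999, seed = 1)
  expect_lt(abs(res2$p - 0.1), 0.02) # ~4.7 Monte-Carlo sd at 4999 perms

  # four samples per group make the minimal exact p 2/70, comfortably < 0.05
  d8 <- matrix(0.9, 8, 8, dimnames = rep(list(paste0("s", 1:8)), 2))
  d8[1:4, 1:4] <- 0.1; d8[5:8, 5:8] <- 0.1; diag(d8) <- 0
  res8 <- permanova(d8, rep(c("A", "B"), each = 4), n_perm = 999, seed = 1)
  expect_lte(res8$p, 0.05)
})

test_that("pseudo-F and R2 agree with vegan::adonis2", {
  set.seed(31)
  x <- matrix(rexp(80), nrow = 8)
  rownames(x) <- paste0("s", 1:8)
  g <- rep(c("A", "B"), each = 4)
  d <- as.matrix(vegan::vegdist(x, method = "bray"))
  mine <- permanova(d, g, n_perm = 49, seed = 1)
  ref <- vegan::adonis2(stats::as.dist(d) ~ g, permutations = 49)
  expect_equal(mine$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$r_squared, ref$R2[1], tolerance = 1e-10)
})

test_that("PERMANOVA permutations respect strata and degenerate inputs", {
  expect_error(permanova(perm_toy_dist(), rep("A", 6)),
               class = "paircomm_bad_group")

  # equal distances everywhere: no structure, p = 1
  d <- matrix(0.5, 6, 6); diag(d) <- 0
  dimnames(d) <- rep(list(paste0("s", 1:6)), 2)
  res <- permanova(d, rep(c("A", "B"), 3), n_perm = 99, seed = 2)
  expect_equal(res$p, 1)
  expect_true(all(abs(res$null_values - res$pseudo_F) < 1e-12))

  # strata: permutations never move an index across strata
  strata <- rep(c("u", "v"), each = 10)
  for (i in 1:50) {
    perm <- paircomm:::permute_within_strata(20, strata)
    expect_true(all(strata[perm] == strata))
  }
  expect_equal(sort(paircomm:::permute_within_strata(20, strata)), 1:20)
})

test_that("shared-OTU proportion is the Jaccard overlap of presence sets", {
  ids <- c("A", "B", "C", "D")
  dna <- otu_table(matrix(c(1L, 1L, 1L, 0L), 4, dimnames = list(ids, "D1")))
  rna <- otu_table(matrix(c(0L, 2L, 5L, 3L), 4, dimnames = list(ids, "R1")))
  pairs <- data.frame(pair_id = "c1", dna_sample_id = "D1",
                      rna_sample_id = "R1", island = "Bird", pit = "P1",
                      depth_cm = 2, stringsAsFactors = FALSE)
  out <- shared_otu_proportions(pairs, dna, rna)
  expect_equal(out$proportion_shared, 0.5) # {B,C} over {A,B,C,D}
  expect_equal(out$depth_cm, 2)

  # identical presence sets -> 1; disjoint -> 0; both empty -> NA + warning
  rna2 <- otu_table(matrix(c(3L, 4L, 9L, 0L), 4, dimnames = list(ids, "R1")))
  expect_equal(shared_otu_proportions(pairs, dna, rna2)$proportion_shared, 1)
  rna3 <- otu_table(matrix(c(0L, 0L, 0L, 3L), 4, dimnames = list(ids, "R1")))
  expect_equal(shared_otu_proportions(pairs, dna, rna3)$proportion_shared, 0)
  dna0 <- otu_table(matrix(0L, 4, 1, dimnames = list(ids, "D1")))
  rna0 <- otu_table(matrix(0L, 4, 1, dimnames = list(ids, "R1")))
  expect_warning(out0 <- shared_otu_proportions(pairs, dna0, rna0), "empty")
  expect_true(is.na(out0$proportion_shared))
})
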