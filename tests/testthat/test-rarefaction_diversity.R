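test_that("rarefaction preserves totals at target depth and errors on
           shallow samples", {
  counts <- matrix(c(50L, 50L, 100L, 0L), nrow = 2,
                   dimnames = list(c("OTU1", "OTU2"), c("S1", "S2")))
  tab <- otu_table(counts)
  r <- rarefy(tab, rarefaction_plan(depth = 100, seed = 1))
  expect_identical(unclass(r), unclass(tab)) # depth equals every total

  r40 <- rarefy(tab, rarefaction_plan(depth = 40, seed = 1))
  expect_equal(unname(unclass(r40)[, "S2"]), c(40L, 0L)) # single-OTU sample
  expect_true(all(colSums(r40) == 40))

  err <- expect_error(rarefy(tab, rarefaction_plan(depth = 101, seed = 1)),
                      class = "paircomm_too_shallow")
  expect_match(conditionMessage(err), "S1")
})

test_that("rarefied column sums equal the plan depth on every iteration", {
  set.seed(11)
  counts <- matrix(rpois(60, 20), nrow = 10,
                   dimnames = list(sprintf("o%d", 1:10), sprintf("s%d", 1:6)))
  tab <- otu_table(counts)
  plan <- rarefaction_plan(depth = min(colSums(tab)), n_iterations = 200,
                           seed = 4)
  for (it in 1:200) {
    expect_true(all(colSums(rarefy(tab, plan, iteration = it)) == plan$depth))
  }
})

test_that("rarefaction matches the hypergeometric expectation", {
  tab <- otu_table(matrix(c(60L, 40L), 2, dimnames = list(c("a", "b"), "S")))
  plan <- rarefaction_plan(depth = 50, seed = 9)
  draws <- vapply(1:2000, function(it) unclass(rarefy(tab, plan, it))[1, 1],
                  numeric(1))
  # X ~ Hypergeometric(N = 100, K = 60, n = 50): mean 30, var 6.0606
  se <- sqrt(50 * 0.6 * 0.4 * 50 / 99 / 2000)
  expect_lt(abs(mean(draws) - 30), 4 * se)
  # expected richness is non-decreasing in depth
  rich <- function(depth) {
    p <- rarefaction_plan(depth = depth, seed = 2)
    mean(vapply(1:500, function(it) richness(unclass(rarefy(tab, p, it))[, 1]),
                numeric(1)))
  }
  expect_lte(rich(5), rich(60))
})

test_that("richness and Pielou evenness match hand computations", {
  expect_equal(richness(c(5, 0, 1)), 2L)
  expect_equal(richness(numeric(3)), 0L)
  expect_equal(richness(rep(1, 153)), 153L)

  expect_equal(pielou_evenness(c(10, 10, 10)), 1.0)
  # H = -(0.25 ln 0.25 * 2 + 0.5 ln 0.5) = 1.039721, ln 3 = 1.098612
  expect_equal(pielou_evenness(c(10, 10, 20)), 0.946395, tolerance = 1e-6)
  expect_equal(pielou_evenness(100), 0.0)
  expect_error(pielou_evenness(c(0, 0)), class = "paircomm_empty_sample")
})

test_that("k-dominance curves accumulate sorted relative abundances", {
  expect_equal(k_dominance_curve(c(50, 30, 20), 3), c(0.5, 0.8, 1.0))
  expect_equal(k_dominance_curve(rep(10, 10), 10), seq(0.1, 1, by = 0.1))
  expect_equal(k_dominance_curve(c(97, 1, 1, 1), 2), c(0.97, 0.98))
  for (seed in 1:10) {
    set.seed(seed)
    v <- rpois(30, 3)
    v[1] <- v[1] + 1 # ensure non-empty
    curve <- k_dominance_curve(v, 35)
    expect_true(all(diff(curve) >= 0))
    expect_equal(curve[richness(v)], 1)
  }
})

test_that("Delta+ matches hand-enumerated cases and the brute-force oracle", {
  tax <- toy_taxonomy()
  p <- function(ids) setNames(rep(1, length(ids)), ids)
  # one congeneric pair: minimal one-step divergence
  expect_equal(avg_taxonomic_distinctness(p(c("A1", "A2")), tax), 100 / 7)
  # different phyla: maximal divergence
  expect_equal(avg_taxonomic_distinctness(p(c("A1", "B1")), tax), 100)
  # two congeneric pairs in different phyla: (2 * 100/7 + 4 * 100) / 6
  expect_equal(avg_taxonomic_distinctness(p(c("A1", "A2", "B1", "B2")), tax),
               71.43, tolerance = 1e-3)
  # different kingdoms
  tax2 <- tax; tax2$kingdom <- c("Fungi", "Metazoa", "Fungi", "Fungi")
  expect_equal(avg_taxonomic_distinctness(p(c("A1", "A2")), tax2), 100)

  # oracle agreement on random subsets of a simulated taxonomy
  ds <- simulate_paired_dataset(small_sim_params(seed = 6))
  for (seed in 1:15) {
    set.seed(seed)
    ids <- sample(ds$taxonomy$otu_id, sample(2:6, 1))
    expect_equal(avg_taxonomic_distinctness(p(ids), ds$taxonomy),
                 delta_plus_oracle(ids, ds$taxonomy))
  }
})

test_that("Delta+ is presence/absence: invariant to abundances and labels", {
  tax <- toy_taxonomy()
  a <- setNames(c(1, 5, 100, 2), tax$otu_id)
  b <- setNames(c(9, 1, 1, 77), tax$otu_id)
  expect_equal(avg_taxonomic_distinctness(a, tax),
               avg_taxonomic_distinctness(b, tax))
  # relabeling OTUs consistently leaves the value unchanged
  tax3 <- tax; tax3$otu_id <- paste0("Z", tax$otu_id)
  expect_equal(avg_taxonomic_distinctness(setNames(a, tax3$otu_id), tax3),
               avg_taxonomic_distinctness(a, tax))
  # fewer than two present OTUs is flagged undefined
  expect_warning(v <- avg_taxonomic_distinctness(c(A1 = 1), tax))
  expect_true(is.na(v))
  # missing taxonomy: private lineage, maximally distinct, with a warning
  expect_warning(
    v2 <- avg_taxonomic_distinctness(c(A1 = 1, QQ = 1), tax), "QQ")
  expect_equal(v2, 100)
})

test_that("iterated rarefied metrics are seeded, bounded and summarized", {
  ds <- simulate_paired_dataset(small_sim_params(seed = 7))
  pooled <- pool_replicates(ds$table, ds$metadata)
  tab <- otu_table(unclass(pooled$table)[, 1:6])
  plan <- rarefaction_plan(depth = min(colSums(tab)), n_iterations = 30,
                           seed = 21)
  res <- iterate_rarefied_metrics(tab, plan, taxonomy = ds$taxonomy)
  res2 <- iterate_rarefied_metrics(tab, plan, taxonomy = ds$taxonomy)
  expect_identical(res, res2) # determinism under the same seed

  # rarefied richness never exceeds unrarefied richness
  unrar <- apply(unclass(tab), 2, richness)
  expect_true(all(t(res$values[, , "richness"]) <= unrar))
  expect_true(all(res$values[, , "evenness"] >= 0 &
                    res$values[, , "evenness"] <= 1))
  s <- res$summary
  expect_true(all(s$ci_low <= s$mean + 1e-12 & s$mean <= s$ci_high + 1e-12))

  # degenerate: table already at depth -> zero-width confidence sets
  tab1 <- otu_table(matrix(c(5L, 5L), 2, dimnames = list(c("a", "b"), "S")))
  resd <- iterate_rarefied_metrics(tab1, rarefaction_plan(10, 20, seed = 1))
  expect_true(all(resd$summary$ci_low == resd$summary$ci_high))
})
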