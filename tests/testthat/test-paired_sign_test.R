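make_tables <- function(dna_counts, rna_counts, ids = NULL) {
  ids <- ids %||% sprintf("o%d", seq_len(nrow(dna_counts)))
  list(dna = otu_table(matrix(as.integer(dna_counts), nrow(dna_counts),
                              dimnames = list(ids, paste0("D", seq_len(ncol(dna_counts)))))),
       rna = otu_table(matrix(as.integer(rna_counts), nrow(rna_counts),
                              dimnames = list(ids, paste0("R", seq_len(ncol(rna_counts)))))))
}
`%||%` <- function(a, b) if (is.null(a)) b else a
pairs_for <- function(tabs) {
  data.frame(pair_id = paste0("c", seq_len(ncol(tabs$dna))),
             dna_sample_id = colnames(tabs$dna),
             rna_sample_id = colnames(tabs$rna),
             island = "Bird", pit = "P1", depth_cm = 2,
             stringsAsFactors = FALSE)
}

test_that("abundance signs come from summed paired rarefied differences", {
  # equal column totals so the common-depth rarefaction is the identity
  tabs <- make_tables(cbind(c(10, 25, 5, 0)), cbind(c(30, 5, 5, 0)))
  signs <- abundance_signs(tabs$dna, tabs$rna, pairs_for(tabs),
                           rarefaction_plan(1, seed = 1))
  expect_equal(signs$sign[signs$otu_id == "o1"], "higher_in_active")
  expect_equal(signs$sign[signs$otu_id == "o2"], "higher_in_total")
  expect_equal(signs$sign[signs$otu_id == "o3"], "tie")
  # o4 detected in neither pool: excluded by the both-pools default
  expect_false("o4" %in% signs$otu_id)

  # an OTU present only in the DNA pool is excluded by default, kept with
  # the include-all flag
  tabs2 <- make_tables(cbind(c(10, 30)), cbind(c(40, 0)))
  s_def <- abundance_signs(tabs2$dna, tabs2$rna, pairs_for(tabs2),
                           rarefaction_plan(1, seed = 1))
  expect_false("o2" %in% s_def$otu_id)
  s_all <- abundance_signs(tabs2$dna, tabs2$rna, pairs_for(tabs2),
                           rarefaction_plan(1, seed = 1), include_all = TRUE)
  expect_equal(s_all$sign[s_all$otu_id == "o2"], "higher_in_total")

  expect_error(abundance_signs(tabs$dna, tabs$rna, pairs_for(tabs)[0, ],
                               rarefaction_plan(1, seed = 1)),
               class = "paircomm_no_pairs")
})

test_that("exact oracle enumerates the label-arrangement null", {
  signs <- data.frame(otu_id = c("a", "b", "c", "d"),
                      delta = c(1, 1, -1, -1),
                      sign = c("higher_in_active", "higher_in_active",
                               "higher_in_total", "higher_in_total"))
  labels <- data.frame(otu_id = c("a", "b", "c", "d"),
                       label = c("g", "g", "h", "h"))
  out <- exact_sign_test_oracle(signs, labels, "g")
  expect_equal(sort(out$null_values), c(0, 0.5, 0.5, 0.5, 0.5, 1))
  expect_equal(out$observed_proportion, 0)
  # two-tailed: P(null <= 0) = 1/6, doubled
  expect_equal(out$p_two_tailed, 2 / 6)

  # group covering every OTU: single arrangement, p = 1
  lab_all <- data.frame(otu_id = signs$otu_id, label = "g")
  expect_equal(exact_sign_test_oracle(signs, lab_all, "g")$p_two_tailed, 1)

  # input order invariance
  ix <- c(3, 1, 4, 2)
  out2 <- exact_sign_test_oracle(signs[ix, ], labels[ix, ], "g")
  expect_equal(out2$p_two_tailed, out$p_two_tailed)
  expect_equal(sort(out2$null_values), sort(out$null_values))

  expect_error(exact_sign_test_oracle(signs, labels, "g",
                                      max_arrangements = 2),
               class = "paircomm_too_many_arrangements")
})

test_that("Monte-Carlo test agrees with the exact oracle", {
  for (seed in c(2, 5)) {
    inst <- random_sign_instance(6, seed)
    exact <- exact_sign_test_oracle(inst$signs, inst$labels, "g")
    mc <- permutation_paired_sign_test(inst$signs, inst$labels, "g",
                                       permutation_plan(20000, seed = 3))
    p_t <- min(mean(exact$null_values >= exact$observed_proportion),
               mean(exact$null_values <= exact$observed_proportion))
    se <- 2 * sqrt(p_t * (1 - p_t) / 20000)
    expect_lt(abs(mc$p_two_tailed - exact$p_two_tailed), 4 * se + 4 / 20001)
  }
})

test_that("degenerate and extreme sign-test cases behave as specified", {
  n <- 10
  signs <- data.frame(otu_id = sprintf("o%d", 1:n), delta = 1,
                      sign = "higher_in_active")
  labels <- data.frame(otu_id = signs$otu_id, label = "g")
  # all group OTUs higher in active: observed proportion(higher-in-total) = 0
  res <- permutation_paired_sign_test(signs, labels, "g",
                                      permutation_plan(100, seed = 1))
  expect_equal(res$observed_proportion, 0)
  # one group = everything: permutation cannot move the statistic
  expect_true(all(res$null_values == 0))
  expect_equal(res$p_two_tailed, 1)

  # all ties in the group is an error
  signs$sign <- "tie"
  expect_error(permutation_paired_sign_test(signs, labels, "g"),
               class = "paircomm_no_informative")
  expect_error(permutation_paired_sign_test(signs, labels, "nope"),
               class = "paircomm_bad_group")
})

test_that("sign test is deterministic given a seed and bounded", {
  inst <- random_sign_instance(40, seed = 8)
  plan <- permutation_plan(500, seed = 42)
  r1 <- permutation_paired_sign_test(inst$signs, inst$labels, "g", plan)
  r2 <- permutation_paired_sign_test(inst$signs, inst$labels, "g", plan)
  expect_identical(r1, r2)
  expect_true(all(r1$null_values >= 0 & r1$null_values <= 1))
  expect_gt(r1$p_two_tailed, 0)
  expect_lte(r1$p_two_tailed, 1)
  expect_lte(r1$expected_set_95[["low"]], r1$expected_set_95[["high"]])
})

test_that("class-level tests recover a planted class bias and filter small
           classes", {
  hits <- 0L
  for (seed in 1:20) {
    p <- sim_params(n_otus_per_group = c(endemic = 0, cosmopolitan = 340,
                                         bipolar = 0),
                    reads_per_sample = 2000, n_replicates = 2,
                    class_bias = list(class = "Microbotryomycetes",
                                      n_otus = 40, relic_multiplier = 3),
                    seed = seed)
    ds <- simulate_paired_dataset(p)
    pooled <- pool_replicates(ds$table, ds$metadata)
    tab <- filter_singletons(pooled$table)
    meta <- pooled$metadata
    prs <- pair_samples(meta)
    dna <- otu_table(unclass(tab)[, meta$sample_id[meta$pool == "DNA"]])
    rna <- otu_table(unclass(tab)[, meta$sample_id[meta$pool == "RNA"]])
    signs <- abundance_signs(dna, rna, prs, rarefaction_plan(1, seed = seed))
    res <- class_level_tests(signs, ds$taxonomy, rank = "class",
                             plan = permutation_plan(1000, seed = 1),
                             min_group_size = 5)
    row <- res[res$group == "Microbotryomycetes", ]
    if (nrow(row) == 1 && row$p_adjusted < 0.05 &&
        row$observed_proportion > row$null_high95) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 18L)

  # a class smaller than min_group_size is absent from the output
  inst <- random_sign_instance(30, seed = 4)
  tax <- data.frame(otu_id = inst$signs$otu_id, kingdom = "Fungi",
                    phylum = "p", subphylum = "s",
                    class = c(rep("Big", 27), rep("Tiny", 3)),
                    order = "o", family = "f", genus = "g")
  res <- class_level_tests(inst$signs, tax, plan = permutation_plan(50, 1),
                           min_group_size = 5)
  expect_false("Tiny" %in% res$group)
  expect_true("Big" %in% res$group)
})

test_that("sign-flip paired metric test handles symmetry and constants", {
  v <- c(1.2, 3.4, 2.2, 5.0)
  expect_equal(sign_flip_paired_metric_test(v, v)$p_two_tailed, 1)

  dna <- rnorm(27); rna <- dna + 10
  res <- sign_flip_paired_metric_test(dna, rna, permutation_plan(1000, 1))
  expect_lte(res$p_two_tailed, 0.01)
  expect_equal(res$statistic, 10)

  swapped <- sign_flip_paired_metric_test(rna, dna, permutation_plan(1000, 1))
  expect_equal(swapped$statistic, -10)
  expect_equal(swapped$p_two_tailed, res$p_two_tailed)
})
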