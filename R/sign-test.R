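#' Permutation plan for label-randomization tests
#'
#' @param n_perm number of label permutations (default 1000).
#' @param seed master seed.
#' @param two_tailed logical; the tests here are two-tailed by design.
#' @return a `permutation_plan` list.
#' @export
permutation_plan <- function(n_perm = 1000, seed = 1, two_tailed = TRUE) {
  stopifnot(n_perm >= 1)
  structure(list(n_perm = as.integer(n_perm), seed = as.integer(seed),
                 two_tailed = isTRUE(two_tailed)),
            class = "permutation_plan")
}

#' Per-OTU abundance signs between the total (DNA) and active (RNA) pools
#'
#' Both pools are rarefied to the lowest common sequencing depth across all
#' samples of both pools (one seeded draw), then each OTU's read difference
#' is summed over the paired samples:
#' `delta = sum over pairs (RNA reads - DNA reads)`. `delta < 0` means higher
#' abundance in the total community, `delta > 0` higher in the active
#' community, `delta = 0` a tie. By default only OTUs detected (unrarefied
#' count > 0 anywhere) in both nucleic-acid pools are emitted; range labels
#' come from a DNA-based reference, so RNA-only OTUs would lean endemic.
#'
#' @param dna_table,rna_table pooled [otu_table()]s sharing the OTU set.
#' @param pairs pair table from [pair_samples()].
#' @param plan a [rarefaction_plan()]; only its seed is used — the depth is
#'   always the lowest common sample total.
#' @param include_all emit OTUs detected in only one pool as well.
#' @param per_pair_majority if TRUE, the sign is the majority of per-pair
#'   signs instead of the sign of the summed difference (sensitivity flag).
#' @return data.frame `otu_id`, `delta`, `sign`
#'   (`higher_in_total`/`higher_in_active`/`tie`).
#' @export
abundance_signs <- function(dna_table, rna_table, pairs,
                            plan = rarefaction_plan(depth = 1, seed = 1),
                            include_all = FALSE, per_pair_majority = FALSE) {
  if (nrow(pairs) == 0) {
    pc_stop("paircomm_no_pairs", "no valid DNA/RNA pairs")
  }
  otus <- intersect(otu_ids(dna_table), otu_ids(rna_table))
  dna <- dna_table[otus, pairs$dna_sample_id, drop = FALSE]
  rna <- rna_table[otus, pairs$rna_sample_id, drop = FALSE]
  depth <- min(colSums(dna), colSums(rna))
  p <- rarefaction_plan(depth = depth, n_iterations = 1, seed = plan$seed)
  dna_r <- rarefy(otu_table(dna), p)
  rna_r <- rarefy(otu_table(rna), p)
  if (per_pair_majority) {
    per_pair <- sign(rna_r - dna_r)
    delta <- rowSums(per_pair)
  } else {
    delta <- rowSums(rna_r) - rowSums(dna_r)
  }
  keep <- if (include_all) {
    rep(TRUE, length(otus))
  } else {
    rowSums(dna) > 0 & rowSums(rna) > 0
  }
  sgn <- ifelse(delta < 0, "higher_in_total",
                ifelse(delta > 0, "higher_in_active", "tie"))
  data.frame(otu_id = otus, delta = as.numeric(delta), sign = sgn,
             stringsAsFactors = FALSE)[keep, , drop = FALSE]
}

# Statistic: proportion of the group's (non-tie) OTUs with higher abundance
# in the total community. `in_total` is the logical sign vector over non-tie
# OTUs; `in_group` a logical group-membership vector of the same length.
sign_stat <- function(in_total, in_group) {
  sum(in_total & in_group) / sum(in_group)
}

# Drop ties and align labels to signs; shared by the Monte-Carlo test and the
# exact oracle so both test exactly the same statistic.
prepare_signs <- function(signs, labels, group) {
  lab <- labels$label[match(signs$otu_id, labels$otu_id)]
  keep <- signs$sign != "tie" & !is.na(lab)
  n_ties <- sum(signs$sign == "tie" & !is.na(lab))
  list(in_total = signs$sign[keep] == "higher_in_total",
       labels = lab[keep], n_ties = n_ties)
}

#' Permutational paired sign test for one OTU group
#'
#' The test statistic is the proportion of the group's OTUs with higher
#' overall abundance in the total community (ties excluded). The null
#' distribution is built by randomly permuting the complete label vector
#' across all (non-tie) OTUs, preserving group sizes, and recomputing the
#' statistic; the 95% expected set is the empirical 2.5–97.5 percentile range
#' of the null values and the two-tailed p doubles the smaller smoothed tail.
#'
#' @param signs output of [abundance_signs()].
#' @param labels data.frame `otu_id`, `label` (e.g. from [classify_all()]).
#' @param group the label to test.
#' @param plan a [permutation_plan()].
#' @return a `sign_test_result` list: `group`, `n_otus`, `n_ties`,
#'   `observed_proportion`, `null_values`, `expected_set_95`, `p_two_tailed`.
#' @export
permutation_paired_sign_test <- function(signs, labels, group,
                                         plan = permutation_plan()) {
  if (!group %in% labels$label) {
    pc_stop("paircomm_bad_group", "group '%s' not present among labels", group)
  }
  prep <- prepare_signs(signs, labels, group)
  in_group <- prep$labels == group
  if (sum(in_group) == 0) {
    pc_stop("paircomm_no_informative",
            "no informative (non-tie) OTUs in group '%s'", group)
  }
  obs <- sign_stat(prep$in_total, in_group)
  null_values <- with_seed(plan$seed, paste0("signtest/", group), {
    vapply(seq_len(plan$n_perm), function(i) {
      sign_stat(prep$in_total, sample(in_group))
    }, numeric(1))
  })
  structure(list(group = group,
                 n_otus = sum(in_group),
                 n_ties = prep$n_ties,
                 observed_proportion = obs,
                 null_values = null_values,
                 expected_set_95 = expected_set_95(null_values),
                 p_two_tailed = perm_p_two_tailed(obs, null_values)),
            class = "sign_test_result")
}

#' @export
print.sign_test_result <- function(x, ...) {
  cat(sprintf(
    "Permutational paired sign test: group '%s'\n  n = %d non-tie OTUs (%d ties)\n  observed proportion higher in total = %.3f\n  95%% expected set = %.3f-%.3f\n  two-tailed p = %.4g (%d permutations)\n",
    x$group, x$n_otus, x$n_ties, x$observed_proportion,
    x$expected_set_95[["low"]], x$expected_set_95[["high"]],
    x$p_two_tailed, length(x$null_values)))
  invisible(x)
}

#' Exact enumeration oracle for the paired sign test
#'
#' Enumerates every distinct assignment of the label multiset to the non-tie
#' OTUs. Because the statistic depends only on which OTUs carry the tested
#' group label, the enumeration runs over the `choose(n, n_group)` group
#' position sets, each of which is equally likely under label permutation.
#' The two-tailed p doubles the smaller exact tail (no smoothing) and is
#' capped at 1.
#'
#' @inheritParams permutation_paired_sign_test
#' @param max_arrangements guard on `choose(n, n_group)` (default 1e6).
#' @return list `p_two_tailed`, `observed_proportion`, `null_values` (one per
#'   arrangement).
#' @export
exact_sign_test_oracle <- function(signs, labels, group,
                                   max_arrangements = 1e6) {
  prep <- prepare_signs(signs, labels, group)
  in_group <- prep$labels == group
  n <- length(in_group)
  k <- sum(in_group)
  if (k == 0) {
    pc_stop("paircomm_no_informative",
            "no informative (non-tie) OTUs in group '%s'", group)
  }
  if (choose(n, k) > max_arrangements) {
    pc_stop("paircomm_too_many_arrangements",
            "choose(%d, %d) exceeds the enumeration bound", n, k)
  }
  obs <- sign_stat(prep$in_total, in_group)
  sets <- utils::combn(n, k)
  null_values <- apply(sets, 2, function(ix) sum(prep$in_total[ix]) / k)
  up <- mean(null_values >= obs)
  dn <- mean(null_values <= obs)
  list(p_two_tailed = min(1, 2 * min(up, dn)),
       observed_proportion = obs,
       null_values = null_values)
}

#' Sign tests across all groups of a label vector
#'
#' Runs the permutational paired sign test for every label value, using one
#' shared sequence of label-vector shuffles so the per-group null
#' distributions are mutually consistent: randomize the complete label
#' vector once, then read off each group's statistic.
#'
#' @inheritParams permutation_paired_sign_test
#' @param min_group_size smallest number of non-tie OTUs for a group to be
#'   tested.
#' @param adjust multiple-testing adjustment passed to [stats::p.adjust()]
#'   (default `"none"`; class-level tests use `"BH"`).
#' @return data.frame: `group`, `n_otus`, `n_ties`, `observed_proportion`,
#'   `null_low95`, `null_high95`, `p_raw`, `p_adjusted`, plus the full
#'   null matrix as attribute `"null_values"`.
#' @export
sign_tests_by_group <- function(signs, labels, plan = permutation_plan(),
                                min_group_size = 1, adjust = "none") {
  prep <- prepare_signs(signs, labels, NULL)
  lab <- prep$labels
  groups <- names(which(table(lab) >= min_group_size))
  if (length(groups) == 0) {
    return(data.frame(group = character(), n_otus = integer(),
                      n_ties = integer(), observed_proportion = numeric(),
                      null_low95 = numeric(), null_high95 = numeric(),
                      p_raw = numeric(), p_adjusted = numeric()))
  }
  # one shuffle per iteration, evaluated for every group
  nulls <- with_seed(plan$seed, "signtest/groups", {
    vapply(seq_len(plan$n_perm), function(i) {
      perm <- sample(lab)
      vapply(groups, function(g) sign_stat(prep$in_total, perm == g),
             numeric(1))
    }, numeric(length(groups)))
  })
  nulls <- matrix(nulls, nrow = length(groups),
                  dimnames = list(groups, NULL))
  res <- do.call(rbind, lapply(groups, function(g) {
    obs <- sign_stat(prep$in_total, lab == g)
    es <- expected_set_95(nulls[g, ])
    data.frame(group = g, n_otus = sum(lab == g),
               n_ties = prep$n_ties,
               observed_proportion = obs,
               null_low95 = es[["low"]], null_high95 = es[["high"]],
               p_raw = perm_p_two_tailed(obs, nulls[g, ]),
               stringsAsFactors = FALSE)
  }))
  res$p_adjusted <- stats::p.adjust(res$p_raw, method = adjust)
  attr(res, "null_values") <- nulls
  res
}

#' Class-level sign tests
#'
#' Applies the permutational paired sign test to taxonomic groups at a chosen
#' rank (classes by default), testing whether any taxon's OTUs are
#' consistently more abundant in one nucleic-acid pool. P-values are
#' Benjamini–Hochberg adjusted across taxa; raw p-values are always reported.
#'
#' @inheritParams permutation_paired_sign_test
#' @param taxonomy taxonomy data.frame.
#' @param rank rank column to group by (default `"class"`).
#' @param min_group_size smallest number of non-tie OTUs for a taxon to be
#'   tested (default 5).
#' @return as [sign_tests_by_group()].
#' @export
class_level_tests <- function(signs, taxonomy, rank = "class",
                              plan = permutation_plan(), min_group_size = 5) {
  if (!rank %in% names(taxonomy)) {
    pc_stop("paircomm_metadata_mismatch", "rank '%s' not in taxonomy", rank)
  }
  labels <- data.frame(otu_id = taxonomy$otu_id, label = taxonomy[[rank]],
                       stringsAsFactors = FALSE)
  sign_tests_by_group(signs, labels, plan = plan,
                      min_group_size = min_group_size, adjust = "BH")
}

#' Sign-flip permutation test for a paired metric difference
#'
#' A nonparametric substitute for mixed-model comparisons of per-pair
#' diversity metrics: the statistic is the mean paired difference
#' (RNA - DNA) and the null is built by randomly flipping the sign of each
#' pair's difference. Two-tailed smoothed p as in
#' [permutation_paired_sign_test()]. This is not a mixed-effects model and
#' does not account for island/pit random effects beyond the pairing itself.
#'
#' @param values_dna,values_rna equal-length per-pair metric vectors.
#' @param plan a [permutation_plan()].
#' @return list `statistic` (mean difference), `p_two_tailed`, `null_values`.
#' @export
sign_flip_paired_metric_test <- function(values_dna, values_rna,
                                         plan = permutation_plan()) {
  stopifnot(length(values_dna) == length(values_rna),
            length(values_dna) >= 2)
  d <- values_rna - values_dna
  obs <- mean(d)
  if (all(d == 0)) {
    return(list(statistic = 0, p_two_tailed = 1,
                null_values = rep(0, plan$n_perm)))
  }
  null_values <- with_seed(plan$seed, "signflip", {
    vapply(seq_len(plan$n_perm), function(i) {
      mean(d * sample(c(-1, 1), length(d), replace = TRUE))
    }, numeric(1))
  })
  list(statistic = obs,
       p_two_tailed = perm_p_two_tailed(obs, null_values),
       null_values = null_values)
}
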