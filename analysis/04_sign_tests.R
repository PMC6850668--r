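# The headline analysis: permutational paired sign tests of whether endemic,
# cosmopolitan and bipolar fungi differ in abundance between the total (DNA)
# and active (RNA) communities, plus the same test across taxonomic classes.

source("analysis/00_common.R")

d <- load_pooled()
labels <- read.delim(file.path(TAB_DIR, "range_labels.tsv"))

signs <- abundance_signs(
  d$dna, d$rna, d$pairs,
  plan = rarefaction_plan(1, seed = derive_seed(MASTER_SEED, "analysis/signs")))
message(sprintf("abundance signs for %d OTUs detected in both pools (%s)",
                nrow(signs),
                paste(names(table(signs$sign)), table(signs$sign),
                      collapse = ", ")))
tsv(signs, "abundance_signs.tsv")

pplan <- permutation_plan(n_perm = 1000,
                          seed = derive_seed(MASTER_SEED, "analysis/perm"))
range_tests <- sign_tests_by_group(signs, labels, plan = pplan)
tsv(range_tests, "sign_tests_range.tsv")
message("range-group sign tests (proportion higher in TOTAL community):")
for (i in seq_len(nrow(range_tests))) {
  r <- range_tests[i, ]
  verdict <- if (r$observed_proportion < r$null_low95) {
    "below the 95% expected set -> more abundant in the ACTIVE pool"
  } else if (r$observed_proportion > r$null_high95) {
    "above the 95% expected set -> more abundant in the TOTAL pool"
  } else "inside the 95% expected set"
  message(sprintf("  %-13s obs %.3f (null %.3f-%.3f, p = %.3g): %s",
                  r$group, r$observed_proportion, r$null_low95,
                  r$null_high95, r$p_raw, verdict))
}

class_tests <- class_level_tests(signs, d$raw$taxonomy, rank = "class",
                                 plan = pplan, min_group_size = 5)
tsv(class_tests, "sign_tests_class.tsv")
sig <- class_tests[class_tests$p_adjusted < 0.05, ]
message(sprintf("%d of %d testable classes differ between pools (BH < 0.05)%s",
                nrow(sig), nrow(class_tests),
                if (nrow(sig)) paste0(": ", paste(sig$group, collapse = ", "))
                else ""))
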