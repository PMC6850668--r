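# Iterated-rarefaction diversity of the pooled communities: richness,
# Pielou evenness and average taxonomic distinctness per sample over 1000
# rarefaction draws, sign-flip paired comparisons between pools, and
# k-dominance curves per island.

source("analysis/00_common.R")

d <- load_pooled()
depth <- min(colSums(d$table))
message(sprintf("rarefying %d pooled samples to the lowest common depth %d",
                ncol(d$table), depth))
plan <- rarefaction_plan(depth = depth, n_iterations = 1000,
                         seed = derive_seed(MASTER_SEED, "analysis/diversity"))
div <- iterate_rarefied_metrics(d$table, plan, taxonomy = d$raw$taxonomy)
tsv(div$summary, "diversity_metrics.tsv")

# paired DNA/RNA comparison of per-sample metric means
pplan <- permutation_plan(n_perm = 1000,
                          seed = derive_seed(MASTER_SEED, "analysis/metric_tests"))
tests <- do.call(rbind, lapply(unique(div$summary$metric), function(m) {
  s <- div$summary[div$summary$metric == m, ]
  v <- setNames(s$mean, s$sample_id)
  res <- sign_flip_paired_metric_test(v[d$pairs$dna_sample_id],
                                      v[d$pairs$rna_sample_id], plan = pplan)
  data.frame(metric = m, mean_dna = mean(v[d$pairs$dna_sample_id]),
             mean_rna = mean(v[d$pairs$rna_sample_id]),
             mean_paired_diff = res$statistic, p = res$p_two_tailed)
}))
tsv(tests, "diversity_pair_tests.tsv")
message("paired metric comparisons (RNA - DNA):")
for (i in seq_len(nrow(tests))) {
  message(sprintf("  %-24s DNA %8.3f  RNA %8.3f  diff %+8.3f  p = %.3g",
                  tests$metric[i], tests$mean_dna[i], tests$mean_rna[i],
                  tests$mean_paired_diff[i], tests$p[i]))
}

# dominance structure of the island-level communities
combos <- unique(d$metadata[, c("island", "pool")])
kdom <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
  sel <- d$metadata$island == combos$island[i] &
    d$metadata$pool == combos$pool[i]
  v <- rowSums(d$table[, d$metadata$sample_id[sel], drop = FALSE])
  data.frame(island = combos$island[i], pool = combos$pool[i], k = 1:10,
             cumulative_proportion = k_dominance_curve(v, 10))
}))
tsv(kdom, "k_dominance.tsv")
top1 <- kdom[kdom$k == 1, ]
message("most-dominant-OTU share per island (k = 1):")
for (i in seq_len(nrow(top1))) {
  message(sprintf("  %-7s %s  %.3f", top1$island[i], top1$pool[i],
                  top1$cumulative_proportion[i]))
}
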