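# Community composition: Bray-Curtis distances on proportion-transformed
# replicate-level counts, PERMANOVA of pool identity (DNA vs RNA) overall
# and per island (permutations restricted to each soil-core cell), and the
# proportion of OTUs shared between the pools of each pair across depths.

source("analysis/00_common.R")

d <- load_pooled()
bc <- bray_curtis_matrix(d$raw$table, transform = "proportion")
meta <- d$raw$metadata[match(rownames(bc), d$raw$metadata$sample_id), ]
cell <- as.character(interaction(meta$island, meta$pit, meta$depth_cm))

scopes <- c(list(all = rep(TRUE, nrow(bc))),
            setNames(lapply(unique(meta$island), function(i) meta$island == i),
                     unique(meta$island)))
perm <- do.call(rbind, lapply(names(scopes), function(sc) {
  ix <- scopes[[sc]]
  r <- permanova(bc[ix, ix], meta$pool[ix], n_perm = 999,
                 strata = cell[ix],
                 seed = derive_seed(MASTER_SEED, paste0("analysis/perm/", sc)))
  data.frame(scope = sc, pseudo_F = r$pseudo_F, r_squared = r$r_squared,
             p = r$p, n_perm = r$n_perm)
}))
tsv(perm, "permanova.tsv")
message("PERMANOVA of pool identity on Bray-Curtis distances:")
for (i in seq_len(nrow(perm))) {
  message(sprintf("  %-7s r2 = %.3f, pseudo-F = %.2f, p = %.3g",
                  perm$scope[i], perm$r_squared[i], perm$pseudo_F[i],
                  perm$p[i]))
}

shared <- shared_otu_proportions(d$pairs, d$dna, d$rna)
tsv(shared, "shared_proportion.tsv")
by_depth <- aggregate(proportion_shared ~ depth_cm, shared, mean)
message("mean proportion of OTUs shared between pools, by depth:")
for (i in seq_len(nrow(by_depth))) {
  message(sprintf("  %g cm: %.3f", by_depth$depth_cm[i],
                  by_depth$proportion_shared[i]))
}
# nonparametric depth trend: shallowest vs deepest per (island, pit)
sh <- shared[shared$depth_cm == min(shared$depth_cm), ]
dp <- shared[shared$depth_cm == max(shared$depth_cm), ]
key <- function(x) paste(x$island, x$pit)
dp <- dp[match(key(sh), key(dp)), ]
tr <- sign_flip_paired_metric_test(
  sh$proportion_shared, dp$proportion_shared,
  plan = permutation_plan(1000, seed = derive_seed(MASTER_SEED,
                                                   "analysis/depth_trend")))
message(sprintf(
  "  depth trend (deepest - shallowest): mean diff %+0.3f, p = %.3g",
  tr$statistic, tr$p_two_tailed))
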