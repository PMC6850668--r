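# small fixtures built in code; all randomness is explicitly seeded

toy_counts <- function() {
  matrix(c(5L, 0L, 1L,
           2L, 3L, 0L), nrow = 3,
         dimnames = list(c("OTU1", "OTU2", "OTU3"), c("S1", "S2")))
}

toy_metadata <- function(ids = c("S1", "S2")) {
  data.frame(sample_id = ids, island = "Bird", pit = "P1",
             depth_cm = c(2, 2), pool = c("DNA", "RNA"), replicate = 1L,
             stringsAsFactors = FALSE)
}

# a taxonomy with explicit lineages for hand-checkable distinctness cases
toy_taxonomy <- function() {
  data.frame(
    otu_id  = c("A1", "A2", "B1", "B2"),
    kingdom = "Fungi",
    phylum  = c("Ascomycota", "Ascomycota", "Basidiomycota", "Basidiomycota"),
    subphylum = c("Pezizomycotina", "Pezizomycotina",
                  "Agaricomycotina", "Agaricomycotina"),
    class   = c("Leotiomycetes", "Leotiomycetes",
                "Agaricomycetes", "Agaricomycetes"),
    order   = c("Helotiales", "Helotiales", "Agaricales", "Agaricales"),
    family  = c("Helotiaceae", "Helotiaceae",
                "Psathyrellaceae", "Psathyrellaceae"),
    genus   = c("Hymenoscyphus", "Hymenoscyphus", "Coprinopsis", "Coprinopsis"),
    stringsAsFactors = FALSE)
}

# brute-force Delta+ oracle: explicit double loop over pairs, rank-by-rank
# lineage comparison; independent of the prefix-grouping implementation
delta_plus_oracle <- function(present_ids, taxonomy) {
  ranks <- c("kingdom", "phylum", "subphylum", "class", "order", "family",
             "genus")
  lin <- taxonomy[match(present_ids, taxonomy$otu_id), ranks]
  s <- length(present_ids)
  total <- 0
  for (i in seq_len(s - 1)) {
    for (j in (i + 1):s) {
      shared <- 0
      for (k in seq_along(ranks)) {
        if (lin[i, k] == lin[j, k]) shared <- k else break
      }
      steps <- min(7, 8 - shared)
      total <- total + steps * 100 / 7
    }
  }
  total / choose(s, 2)
}

# random sign/label instances for oracle-equivalence sweeps
random_sign_instance <- function(n, seed) {
  set.seed(seed)
  delta <- sample(c(-2L, -1L, 1L, 2L), n, replace = TRUE)
  signs <- data.frame(
    otu_id = sprintf("o%d", seq_len(n)),
    delta = delta,
    sign = ifelse(delta < 0, "higher_in_total", "higher_in_active"),
    stringsAsFactors = FALSE)
  k <- sample(seq_len(n - 1), 1)
  labels <- data.frame(otu_id = signs$otu_id,
                       label = sample(rep(c("g", "other"), c(k, n - k))),
                       stringsAsFactors = FALSE)
  list(signs = signs, labels = labels)
}

small_sim_params <- function(seed = 1, reads_per_sample = 500, ...) {
  sim_params(n_otus_per_group = c(endemic = 30, cosmopolitan = 60,
                                  bipolar = 10),
             reads_per_sample = reads_per_sample, n_replicates = 2,
             seed = seed, ...)
}
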