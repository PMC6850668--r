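# Shared settings for the analysis drivers. Each script can be run as
#   Rscript analysis/NN_*.R [--seed <int>]
# from the repository root; outputs accumulate under results/.

suppressPackageStartupMessages(library(paircomm))

.args <- commandArgs(trailingOnly = TRUE)
.i <- which(.args == "--seed")
MASTER_SEED <- if (length(.i) == 1 && .i < length(.args)) {
  as.integer(.args[.i + 1])
} else 20190222L

DATA_DIR <- "results/data"
TAB_DIR <- "results/tables"
for (d in c(DATA_DIR, TAB_DIR)) {
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
}

tsv <- function(df, name) {
  path <- file.path(TAB_DIR, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("  wrote ", path)
  invisible(path)
}

# the planted scenario studied throughout: endemic fungi three-fold more
# active (RNA-enriched), cosmopolitan fungi with a three-fold relic-DNA
# load; bipolar fungi unbiased
scenario_params <- function(seed) {
  sim_params(
    activity_multiplier = c(endemic = 3, cosmopolitan = 1, bipolar = 1),
    relic_dna_multiplier = c(endemic = 1, cosmopolitan = 3, bipolar = 1),
    seed = seed)
}

load_pooled <- function() {
  ds <- read_paired_dataset(file.path(DATA_DIR, "otu_table.tsv"),
                            file.path(DATA_DIR, "metadata.tsv"),
                            file.path(DATA_DIR, "taxonomy.tsv"))
  pooled <- pool_replicates(ds$table, ds$metadata)
  tab <- filter_singletons(pooled$table)
  meta <- pooled$metadata
  list(raw = ds, table = tab, metadata = meta, pairs = pair_samples(meta),
       dna = otu_table(unclass(tab)[, meta$sample_id[meta$pool == "DNA"],
                                    drop = FALSE]),
       rna = otu_table(unclass(tab)[, meta$sample_id[meta$pool == "RNA"],
                                    drop = FALSE]))
}
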