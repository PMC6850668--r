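# Generate the study dataset: paired DNA/RNA OTU tables for 3 islands x
# 3 pits x 3 depths with 5 replicate extractions per soil tube, plus
# taxonomy and global occurrence records, under the planted scenario
# (endemic taxa more active, cosmopolitan taxa relic-laden).

source("analysis/00_common.R")

message("simulating paired dataset (seed ", MASTER_SEED, ")")
params <- scenario_params(derive_seed(MASTER_SEED, "analysis/simulate"))
ds <- simulate_paired_dataset(params)
occ <- simulate_occurrence_records(
  ds$truth, seed = derive_seed(MASTER_SEED, "analysis/occurrences"))

write_otu_table(ds$table, file.path(DATA_DIR, "otu_table.tsv"))
for (x in list(list(ds$metadata, "metadata.tsv"),
               list(ds$taxonomy, "taxonomy.tsv"),
               list(occ, "occurrences.tsv"),
               list(data.frame(otu_id = ds$truth$otu_id,
                               true_group = ds$truth$group),
                    "true_groups.tsv"))) {
  write.table(x[[1]], file.path(DATA_DIR, x[[2]]), sep = "\t", quote = FALSE,
              row.names = FALSE)
}

message(sprintf(
  "  %d OTUs x %d samples at %d reads each; groups: %s",
  nrow(ds$table), ncol(ds$table), params$reads_per_sample,
  paste(names(table(ds$truth$group)), table(ds$truth$group),
        collapse = ", ")))
message("  data written under ", DATA_DIR)
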