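# Assign each study OTU a biogeographic range label (endemic, cosmopolitan,
# bipolar) from its occurrence latitudes, and tabulate labels per genus.

source("analysis/00_common.R")

d <- load_pooled()
occ <- read_occurrences(file.path(DATA_DIR, "occurrences.tsv"))
cl <- classify_all(occ, otu_ids(d$table), taxonomy = d$raw$taxonomy)

message("range classification of ", nrow(cl$labels), " study OTUs:")
for (g in names(cl$summary)) {
  message(sprintf("  %-13s %d", g, cl$summary[[g]]))
}

tsv(cl$labels, "range_labels.tsv")
tsv(cl$genus_summary, "range_genus_summary.tsv")

truth <- read.delim(file.path(DATA_DIR, "true_groups.tsv"))
agree <- mean(cl$labels$label ==
                truth$true_group[match(cl$labels$otu_id, truth$otu_id)])
message(sprintf("  agreement with planted truth: %.1f%%", 100 * agree))
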