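#' Pipeline configuration
#'
#' A config holds either paths to the three input tables (`input`) or a
#' simulation block (`simulate`, a [sim_params()] or the list of its
#' arguments) — exactly one of the two — plus the analysis settings.
#'
#' @param input NULL, or list with `otu_table`, `metadata`, `occurrences`
#'   and optionally `taxonomy` paths.
#' @param simulate NULL, or a [sim_params()] / argument list for it.
#' @param n_iterations rarefaction iterations for the diversity stage.
#' @param n_perm permutations for sign tests and PERMANOVA.
#' @param range_rules a [range_rule_config()].
#' @param seed master seed; every stage derives its own stream from it.
#' @param output_dir directory the report bundle is written to.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, simulate = NULL,
                            n_iterations = 1000, n_perm = 1000,
                            range_rules = range_rule_config(),
                            seed = 1, output_dir = "paircomm_results") {
  if (is.null(input) == is.null(simulate)) {
    pc_stop("paircomm_bad_config",
            "exactly one of 'input' and 'simulate' must be given")
  }
  if (!is.null(simulate) && !inherits(simulate, "sim_params")) {
    simulate <- do.call(sim_params, simulate)
  }
  if (!is.null(input)) {
    miss <- setdiff(c("otu_table", "metadata", "occurrences"), names(input))
    if (length(miss)) {
      pc_stop("paircomm_bad_config", "input block lacks: %s",
              paste(miss, collapse = ", "))
    }
  }
  structure(list(input = input, simulate = simulate,
                 n_iterations = as.integer(n_iterations),
                 n_perm = as.integer(n_perm), range_rules = range_rules,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the
#' `range_rules` and `simulate` blocks are argument lists for
#' [range_rule_config()] and [sim_params()].
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    pc_stop("paircomm_missing_file", "file not found: %s", path)
  }
  y <- yaml::read_yaml(path)
  if (!is.null(y$range_rules)) {
    y$range_rules <- do.call(range_rule_config, y$range_rules)
  }
  do.call(pipeline_config, y)
}

write_tsv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full total-vs-active community analysis
#'
#' Stages: read or simulate the dataset; pool replicates; filter singleton
#' OTUs; pair DNA/RNA samples; classify OTU ranges; iterated-rarefaction
#' diversity metrics with paired sign-flip comparisons; per-OTU abundance
#' signs and the permutational paired sign tests (range groups and taxonomic
#' classes); Bray-Curtis distances with a pool-factor PERMANOVA (overall,
#' stratified by soil core, and per island); per-pair shared-OTU
#' proportions; k-dominance curves per island and pool. All tables are
#' written as TSV into `config$output_dir` together with a `manifest.json`
#' recording the seeds and settings; a failing stage leaves a `FAILED`
#' marker naming the stage.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with every stage's result tables.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- "setup"
  on.exit({
    writeLines(paste("failed at stage:", stage),
               file.path(config$output_dir, "FAILED"))
  })

  stage <- "load"
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    sim$seed <- derive_seed(config$seed, "stage/simulate")
    ds <- simulate_paired_dataset(sim)
    occurrences <- simulate_occurrence_records(
      ds$truth, seed = derive_seed(config$seed, "stage/occurrences"),
      config = config$range_rules)
    say("simulated %d OTUs x %d samples", nrow(ds$table), ncol(ds$table))
  } else {
    ds <- read_paired_dataset(config$input$otu_table, config$input$metadata,
                              config$input$taxonomy)
    occurrences <- read_occurrences(config$input$occurrences)
    say("read %d OTUs x %d samples", nrow(ds$table), ncol(ds$table))
  }

  stage <- "pool_and_filter"
  pooled <- pool_replicates(ds$table, ds$metadata)
  tab <- filter_singletons(pooled$table)
  meta <- pooled$metadata
  say("pooled to %d samples; %d OTUs after singleton filter",
      ncol(tab), nrow(tab))

  stage <- "pair"
  pairs <- pair_samples(meta)
  dna <- otu_table(tab[, meta$sample_id[meta$pool == "DNA"], drop = FALSE])
  rna <- otu_table(tab[, meta$sample_id[meta$pool == "RNA"], drop = FALSE])

  stage <- "classify_ranges"
  ranges <- classify_all(occurrences, otu_ids(tab),
                         config = config$range_rules, taxonomy = ds$taxonomy)
  say("range labels: %s",
      paste(names(ranges$summary), ranges$summary, collapse = ", "))

  stage <- "diversity"
  depth <- min(colSums(tab))
  rplan <- rarefaction_plan(depth = depth,
                            n_iterations = config$n_iterations,
                            seed = derive_seed(config$seed, "stage/diversity"))
  div <- iterate_rarefied_metrics(tab, rplan, taxonomy = ds$taxonomy)
  metric_tests <- diversity_pair_tests(div, pairs, config)

  stage <- "k_dominance"
  kdom <- k_dominance_by_island(tab, meta, k_max = 10)

  stage <- "abundance_signs"
  splan <- rarefaction_plan(depth = 1, seed = derive_seed(config$seed,
                                                          "stage/signs"))
  signs <- abundance_signs(dna, rna, pairs, plan = splan)
  scatter <- paired_reads_table(dna, rna, pairs, ranges$labels, splan)

  stage <- "sign_tests"
  pplan <- permutation_plan(n_perm = config$n_perm,
                            seed = derive_seed(config$seed, "stage/perm"))
  range_tests <- sign_tests_by_group(signs, ranges$labels, plan = pplan,
                                     min_group_size = 1, adjust = "none")
  class_tests <- if (!is.null(ds$taxonomy)) {
    class_level_tests(signs, ds$taxonomy, rank = "class", plan = pplan,
                      min_group_size = 5)
  }

  stage <- "composition"
  bc <- bray_curtis_matrix(ds$table, transform = "proportion")
  rep_meta <- ds$metadata[match(colnames(bc), ds$metadata$sample_id), ]
  cell <- interaction(rep_meta$island, rep_meta$pit, rep_meta$depth_cm)
  perm_rows <- list(
    all = permanova(bc, rep_meta$pool, n_perm = config$n_perm,
                    strata = as.character(cell),
                    seed = derive_seed(config$seed, "stage/permanova")))
  for (isl in unique(rep_meta$island)) {
    ix <- rep_meta$island == isl
    perm_rows[[isl]] <- permanova(bc[ix, ix], rep_meta$pool[ix],
                                  n_perm = config$n_perm,
                                  strata = as.character(cell[ix]),
                                  seed = derive_seed(config$seed,
                                                     paste0("stage/permanova/", isl)))
  }
  permanova_tab <- data.frame(
    scope = names(perm_rows),
    pseudo_F = vapply(perm_rows, `[[`, numeric(1), "pseudo_F"),
    r_squared = vapply(perm_rows, `[[`, numeric(1), "r_squared"),
    p = vapply(perm_rows, `[[`, numeric(1), "p"),
    n_perm = vapply(perm_rows, `[[`, numeric(1), "n_perm"),
    row.names = NULL, stringsAsFactors = FALSE)
  shared <- shared_otu_proportions(pairs, dna, rna)

  stage <- "write"
  out <- config$output_dir
  write_otu_table(tab, file.path(out, "otu_table_pooled.tsv"))
  write_tsv(meta, out, "metadata_pooled.tsv")
  write_tsv(pairs, out, "pairs.tsv")
  write_tsv(ranges$labels, out, "range_labels.tsv")
  if (!is.null(ranges$genus_summary)) {
    write_tsv(ranges$genus_summary, out, "range_genus_summary.tsv")
  }
  write_tsv(div$summary, out, "diversity_metrics.tsv")
  write_tsv(metric_tests, out, "diversity_pair_tests.tsv")
  write_tsv(kdom, out, "k_dominance.tsv")
  write_tsv(signs, out, "abundance_signs.tsv")
  write_tsv(scatter, out, "paired_reads_scatter.tsv")
  write_tsv(range_tests, out, "sign_tests_range.tsv")
  if (!is.null(class_tests)) write_tsv(class_tests, out, "sign_tests_class.tsv")
  write_tsv(data.frame(sample_id = rownames(bc), round(bc, 10),
                       check.names = FALSE), out, "bray_curtis.tsv")
  write_tsv(permanova_tab, out, "permanova.tsv")
  write_tsv(shared, out, "shared_proportion.tsv")
  manifest <- list(
    package = "paircomm",
    version = as.character(utils::packageVersion("paircomm")),
    master_seed = config$seed,
    stage_seeds = list(
      simulate = derive_seed(config$seed, "stage/simulate"),
      occurrences = derive_seed(config$seed, "stage/occurrences"),
      diversity = derive_seed(config$seed, "stage/diversity"),
      signs = derive_seed(config$seed, "stage/signs"),
      perm = derive_seed(config$seed, "stage/perm"),
      permanova = derive_seed(config$seed, "stage/permanova")),
    n_iterations = config$n_iterations,
    n_perm = config$n_perm,
    rarefaction_depth = depth,
    range_rules = unclass(config$range_rules),
    mode = if (is.null(config$simulate)) "input" else "simulate")
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  on.exit() # success: clear the FAILED writer
  say("report bundle written to %s", out)
  invisible(list(table = tab, metadata = meta, pairs = pairs,
                 ranges = ranges, diversity = div,
                 metric_tests = metric_tests, k_dominance = kdom,
                 signs = signs, range_tests = range_tests,
                 class_tests = class_tests, bray_curtis = bc,
                 permanova = permanova_tab, shared = shared,
                 manifest = manifest))
}

# per-pair sign-flip tests of the iterated-metric means (RNA - DNA)
diversity_pair_tests <- function(div, pairs, config) {
  pplan <- permutation_plan(n_perm = config$n_perm,
                            seed = derive_seed(config$seed,
                                               "stage/metric_tests"))
  metrics <- unique(div$summary$metric)
  do.call(rbind, lapply(metrics, function(m) {
    s <- div$summary[div$summary$metric == m, ]
    v <- stats::setNames(s$mean, s$sample_id)
    res <- sign_flip_paired_metric_test(v[pairs$dna_sample_id],
                                        v[pairs$rna_sample_id], plan = pplan)
    data.frame(metric = m,
               mean_dna = mean(v[pairs$dna_sample_id]),
               mean_rna = mean(v[pairs$rna_sample_id]),
               mean_paired_diff = res$statistic,
               p_two_tailed = res$p_two_tailed, stringsAsFactors = FALSE)
  }))
}

# island x pool k-dominance of the island-pooled communities
k_dominance_by_island <- function(tab, meta, k_max = 10) {
  combos <- unique(meta[, c("island", "pool")])
  do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    ix <- meta$island == combos$island[i] & meta$pool == combos$pool[i]
    v <- rowSums(tab[, meta$sample_id[ix], drop = FALSE])
    data.frame(island = combos$island[i], pool = combos$pool[i],
               k = seq_len(k_max),
               cumulative_proportion = k_dominance_curve(v, k_max),
               stringsAsFactors = FALSE)
  }))
}

# per-(OTU, pair) rarefied read counts with range labels: the table behind a
# paired-abundance scatter of total vs active reads
paired_reads_table <- function(dna, rna, pairs, labels, plan) {
  otus <- intersect(otu_ids(dna), otu_ids(rna))
  d <- dna[otus, pairs$dna_sample_id, drop = FALSE]
  r <- rna[otus, pairs$rna_sample_id, drop = FALSE]
  depth <- min(colSums(d), colSums(r))
  p <- rarefaction_plan(depth = depth, n_iterations = 1, seed = plan$seed)
  d <- rarefy(otu_table(d), p)
  r <- rarefy(otu_table(r), p)
  keep <- d > 0 | r > 0
  ix <- which(keep, arr.ind = TRUE)
  data.frame(otu_id = otus[ix[, 1]], pair_id = pairs$pair_id[ix[, 2]],
             reads_dna = d[keep], reads_rna = r[keep],
             label = labels$label[match(otus[ix[, 1]], labels$otu_id)],
             stringsAsFactors = FALSE)
}
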