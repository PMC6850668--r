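#' Rarefaction plan
#'
#' @param depth target reads per sample; must not exceed the smallest sample
#'   total of the table being rarefied.
#' @param n_iterations number of independent rarefaction draws for iterated
#'   metrics (default 1000).
#' @param seed master seed; per-(iteration, sample) substreams are derived
#'   with [derive_seed()] so results do not depend on iteration order.
#' @return a `rarefaction_plan` list.
#' @export
rarefaction_plan <- function(depth, n_iterations = 1000, seed = 1) {
  stopifnot(depth >= 1, n_iterations >= 1)
  structure(list(depth = as.integer(depth),
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed)),
            class = "rarefaction_plan")
}

# Draw `depth` reads without replacement from one sample's counts
# (multivariate hypergeometric). RNG state is the caller's responsibility.
rarefy_column <- function(counts, depth) {
  total <- sum(counts)
  if (total == depth) return(counts)
  picked <- sample.int(total, depth)
  breaks <- cumsum(counts)
  tabulate(findInterval(picked, c(0, breaks), left.open = TRUE),
           nbins = length(counts))
}

#' Rarefy an OTU table to a fixed depth
#'
#' Each sample is subsampled without replacement to exactly `plan$depth`
#' reads. A sample already at the target depth passes through unchanged.
#' Each sample draws from its own seeded substream, so the result for one
#' sample does not depend on which other samples are present.
#'
#' @param table an [otu_table()].
#' @param plan a [rarefaction_plan()].
#' @param iteration integer tag mixed into the substream labels; used by
#'   [iterate_rarefied_metrics()] to give each iteration an independent draw.
#' @return the rarefied [otu_table()]; every column sums to `plan$depth`.
#' @export
rarefy <- function(table, plan, iteration = 1L) {
  totals <- colSums(table)
  shallow <- totals < plan$depth
  if (any(shallow)) {
    pc_stop("paircomm_too_shallow",
            "sample(s) shallower than rarefaction depth %d: %s", plan$depth,
            paste(colnames(table)[shallow], collapse = ", "))
  }
  out <- table
  for (j in seq_len(ncol(table))) {
    out[, j] <- with_seed(plan$seed,
                          sprintf("rarefy/%d/%s", iteration, colnames(table)[j]),
                          rarefy_column(table[, j], plan$depth))
  }
  otu_table(unclass(out))
}

#' Per-sample community metrics
#'
#' `richness()` counts OTUs with positive counts. `pielou_evenness()` is
#' Shannon entropy (natural log) of the relative abundances divided by
#' `log(richness)`, with the single-species community defined as 0.
#' `k_dominance_curve()` gives the cumulative relative abundance of the `k`
#' most abundant OTUs for `k = 1..k_max`.
#'
#' @param sample non-negative count vector.
#' @return `richness()` an integer; `pielou_evenness()` a number in
#'   \eqn{[0,1]}; `k_dominance_curve()` a numeric vector of length `k_max`.
#' @examples
#' richness(c(5, 0, 1))          # 2
#' pielou_evenness(c(10, 10, 20))
#' k_dominance_curve(c(50, 30, 20), 3)
#' @export
richness <- function(sample) {
  sum(sample > 0)
}

#' @rdname richness
#' @export
pielou_evenness <- function(sample) {
  sample <- sample[sample > 0]
  if (length(sample) == 0) {
    pc_stop("paircomm_empty_sample", "evenness of an all-zero sample is undefined")
  }
  s <- length(sample)
  if (s == 1) return(0)
  p <- sample / sum(sample)
  h <- -sum(p * log(p))
  h / log(s)
}

#' @rdname richness
#' @param k_max largest k to report.
#' @export
k_dominance_curve <- function(sample, k_max) {
  total <- sum(sample)
  if (total <= 0) {
    pc_stop("paircomm_empty_sample", "k-dominance of an empty sample is undefined")
  }
  p <- sort(sample / total, decreasing = TRUE)
  cum <- cumsum(p)
  # beyond the observed richness the curve stays at 1
  out <- pmin(cum[pmin(seq_len(k_max), length(cum))], 1)
  out[seq_len(k_max) >= length(cum)] <- 1
  out
}

# ---- average taxonomic distinctness ----------------------------------------

# Pair weight convention: with the 7 ranks kingdom..genus, two distinct OTUs
# whose lineages share their deepest rank at level s (kingdom = 1, genus = 7,
# s = 0 when they share nothing) are min(7, 8 - s) equal steps apart, scaled
# so maximally distant pairs weigh 100. Congeneric OTUs are 1 step (100/7);
# OTUs differing at phylum or kingdom are both maximally distant (100).
omega_steps <- function(shared_level, n_ranks = 7L) {
  pmin(n_ranks, n_ranks + 1L - shared_level) * (100 / n_ranks)
}

# lineage matrix: rows OTUs (by id), columns tax_ranks; missing OTUs get a
# unique private lineage (maximal distinctness) with a warning.
lineage_matrix <- function(otu_ids, taxonomy) {
  m <- matrix("", length(otu_ids), length(tax_ranks),
              dimnames = list(otu_ids, tax_ranks))
  idx <- match(otu_ids, taxonomy$otu_id)
  missing <- is.na(idx)
  if (any(missing)) {
    pc_warn("no taxonomy for OTU(s) %s; treated as private lineages",
            paste(otu_ids[missing], collapse = ", "))
  }
  for (k in seq_along(tax_ranks)) {
    m[, k] <- ifelse(missing, paste0("private__", otu_ids),
                     taxonomy[[tax_ranks[k]]][idx])
  }
  m
}

#' Average taxonomic distinctness (presence/absence form)
#'
#' The mean, over all unordered pairs of OTUs present in the sample, of the
#' taxonomic path weight between them: equal step lengths over the seven
#' ranks, scaled so that maximally distant pairs weigh 100. This is the
#' Clarke–Warwick presence/absence average taxonomic distinctness
#' \eqn{\Delta^+}.
#'
#' @param sample named non-negative count vector (names are OTU ids).
#' @param taxonomy taxonomy data.frame (see [read_taxonomy()]).
#' @return \eqn{\Delta^+} in \eqn{(0, 100]}, or `NA` (with a warning) when
#'   fewer than two OTUs are present.
#' @export
avg_taxonomic_distinctness <- function(sample, taxonomy) {
  present <- names(sample)[sample > 0]
  s <- length(present)
  if (s < 2) {
    pc_warn("taxonomic distinctness undefined for < 2 present OTUs")
    return(NA_real_)
  }
  lin <- lineage_matrix(present, taxonomy)
  # count pairs sharing at least the first k ranks, via group sizes of each
  # k-rank lineage prefix; deepest-shared-level pair counts by differencing
  n_pairs_at_least <- numeric(length(tax_ranks) + 1L)
  n_pairs_at_least[1] <- choose(s, 2) # every pair shares >= 0 ranks
  prefix <- rep("", s)
  for (k in seq_along(tax_ranks)) {
    prefix <- paste(prefix, lin[, k], sep = "\r")
    sizes <- table(prefix)
    n_pairs_at_least[k + 1L] <- sum(choose(sizes, 2))
  }
  exactly <- n_pairs_at_least[seq_along(tax_ranks)] -
    n_pairs_at_least[seq_along(tax_ranks) + 1L]
  exactly <- c(exactly, n_pairs_at_least[length(tax_ranks) + 1L])
  sum(exactly * omega_steps(0:length(tax_ranks))) / choose(s, 2)
}

#' Iterate rarefaction and summarize per-sample metrics
#'
#' For each of `plan$n_iterations` independent rarefaction draws, computes
#' richness, Pielou evenness and (when taxonomy is given) average taxonomic
#' distinctness for every sample; reports the per-iteration mean and the
#' empirical 2.5–97.5 percentile range across iterations.
#'
#' @param table an [otu_table()].
#' @param plan a [rarefaction_plan()].
#' @param taxonomy optional taxonomy data.frame; when NULL the
#'   taxonomic-distinctness metric is skipped.
#' @return a list with `summary` (data.frame `sample_id`, `metric`, `mean`,
#'   `ci_low`, `ci_high`) and `values` (array iterations x samples x metrics).
#' @export
iterate_rarefied_metrics <- function(table, plan, taxonomy = NULL) {
  metrics <- c("richness", "evenness",
               if (!is.null(taxonomy)) "taxonomic_distinctness")
  vals <- array(NA_real_,
                dim = c(plan$n_iterations, ncol(table), length(metrics)),
                dimnames = list(NULL, colnames(table), metrics))
  for (it in seq_len(plan$n_iterations)) {
    r <- rarefy(table, plan, iteration = it)
    vals[it, , "richness"] <- apply(r, 2, richness)
    vals[it, , "evenness"] <- apply(r, 2, pielou_evenness)
    if (!is.null(taxonomy)) {
      vals[it, , "taxonomic_distinctness"] <-
        apply(r, 2, avg_taxonomic_distinctness, taxonomy = taxonomy)
    }
  }
  rows <- expand.grid(sample_id = colnames(table), metric = metrics,
                      stringsAsFactors = FALSE)
  summ <- cbind(rows, t(mapply(function(sid, met) {
    v <- vals[, sid, met]
    ci <- expected_set_95(v[!is.na(v)])
    c(mean = mean(v, na.rm = TRUE), ci_low = ci[["low"]],
      ci_high = ci[["high"]])
  }, rows$sample_id, rows$metric)))
  rownames(summ) <- NULL
  list(summary = summ, values = vals)
}
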