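#' Bray-Curtis distance matrix
#'
#' Distances are computed on proportion-transformed counts by default (each
#' sample divided by its total, so the distance is invariant to sequencing
#' depth), or on a single seeded rarefaction draw.
#'
#' @param table an [otu_table()].
#' @param transform `"proportion"` (default) or `"rarefied"`.
#' @param plan a [rarefaction_plan()], required when `transform =
#'   "rarefied"`.
#' @return a symmetric numeric matrix in \eqn{[0,1]} with zero diagonal and
#'   sample ids as dimnames.
#' @export
bray_curtis_matrix <- function(table, transform = c("proportion", "rarefied"),
                               plan = NULL) {
  transform <- match.arg(transform)
  totals <- colSums(table)
  if (any(totals == 0)) {
    pc_stop("paircomm_empty_sample", "zero-total sample(s): %s",
            paste(colnames(table)[totals == 0], collapse = ", "))
  }
  x <- if (transform == "proportion") {
    sweep(t(unclass(table)), 1, totals, "/")
  } else {
    if (is.null(plan)) {
      pc_stop("paircomm_bad_plan", "rarefied transform needs a rarefaction plan")
    }
    t(unclass(rarefy(table, plan)))
  }
  d <- as.matrix(vegan::vegdist(x, method = "bray"))
  dimnames(d) <- list(colnames(table), colnames(table))
  d
}

# sums of squares for a one-factor partition of a distance matrix:
# SS_total = sum_{i<j} d_ij^2 / N; SS_within = sum over groups of the same
# quantity restricted to each group; pseudo-F and R^2 follow.
permanova_stat <- function(d2, grouping) {
  n <- nrow(d2)
  groups <- unique(grouping)
  a <- length(groups)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- sum(vapply(groups, function(g) {
    ix <- grouping == g
    sub <- d2[ix, ix, drop = FALSE]
    sum(sub[upper.tri(sub)]) / sum(ix)
  }, numeric(1)))
  ss_between <- ss_total - ss_within
  f <- (ss_between / (a - 1)) / (ss_within / (n - a))
  c(pseudo_F = f, r_squared = ss_between / ss_total)
}

#' One-factor permutational MANOVA (PERMANOVA)
#'
#' Partitions a distance matrix by a single grouping factor,
#' Anderson's distance-based pseudo-F:
#' \deqn{F = \frac{SS_B/(a-1)}{SS_W/(N-a)}}
#' with \eqn{SS} terms computed from squared inter-point distances.
#' Significance is assessed by permuting the grouping vector; when `strata`
#' is given, labels are shuffled only within strata (e.g. within each
#' soil-core cell). The p-value is `(b + 1) / (n_perm + 1)` where `b` counts
#' permuted statistics at least as large as the observed one.
#'
#' @param dist symmetric distance matrix (or `dist` object).
#' @param grouping per-sample factor with at least two levels.
#' @param n_perm number of permutations (default 999).
#' @param strata optional per-sample blocking factor.
#' @param seed integer seed.
#' @return list `pseudo_F`, `r_squared`, `p`, `n_perm`, `null_values`.
#' @export
permanova <- function(dist, grouping, n_perm = 999, strata = NULL, seed = 1) {
  d <- as.matrix(dist)
  grouping <- as.character(grouping)
  if (length(unique(grouping)) < 2) {
    pc_stop("paircomm_bad_group", "PERMANOVA needs at least two groups")
  }
  stopifnot(length(grouping) == nrow(d))
  d2 <- d^2
  obs <- permanova_stat(d2, grouping)
  null_values <- with_seed(seed, "permanova", {
    vapply(seq_len(n_perm), function(i) {
      perm <- permute_within_strata(length(grouping), strata)
      permanova_stat(d2, grouping[perm])[["pseudo_F"]]
    }, numeric(1))
  })
  list(pseudo_F = obs[["pseudo_F"]],
       r_squared = obs[["r_squared"]],
       p = (sum(null_values >= obs[["pseudo_F"]]) + 1) / (n_perm + 1),
       n_perm = n_perm,
       null_values = null_values)
}

# a random permutation of 1..n that never moves an index across strata
permute_within_strata <- function(n, strata = NULL) {
  if (is.null(strata)) return(sample.int(n))
  perm <- seq_len(n)
  for (s in unique(strata)) {
    ix <- which(strata == s)
    perm[ix] <- ix[sample.int(length(ix))]
  }
  perm
}

#' Proportion of OTUs shared between the two pools of a pair
#'
#' Jaccard overlap of the presence sets: OTUs present in both samples over
#' OTUs present in either, computed on the (unrarefied) pooled tables by
#' default.
#'
#' @param pairs pair table from [pair_samples()].
#' @param dna_table,rna_table pooled [otu_table()]s.
#' @return data.frame `pair_id`, `island`, `pit`, `depth_cm`,
#'   `proportion_shared` (`NA`, with a warning, when both samples are empty).
#' @export
shared_otu_proportions <- function(pairs, dna_table, rna_table) {
  otus <- intersect(otu_ids(dna_table), otu_ids(rna_table))
  prop <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- dna_table[otus, pairs$dna_sample_id[i]] > 0
    b <- rna_table[otus, pairs$rna_sample_id[i]] > 0
    union_n <- sum(a | b)
    if (union_n == 0) {
      pc_warn("pair %s has two empty samples", pairs$pair_id[i])
      return(NA_real_)
    }
    sum(a & b) / union_n
  }, numeric(1))
  data.frame(pair_id = pairs$pair_id, island = pairs$island, pit = pairs$pit,
             depth_cm = pairs$depth_cm, proportion_shared = prop,
             stringsAsFactors = FALSE)
}
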