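#' Parameters for the paired DNA/RNA community simulator
#'
#' The generator emulates the post-clustering products of a paired
#' total/active soil-fungal survey: a nested design of islands, pits and
#' depths, five replicate extractions per soil tube, lognormal latent
#' abundances with strong dominance, and group-specific RNA:DNA biases.
#' `activity_multiplier` scales an OTU group's expected abundance in the RNA
#' pool (active growth); `relic_dna_multiplier` scales its DNA-pool
#' abundance (spore / relic-DNA load). Both default to 1, i.e. no planted
#' difference between pools.
#'
#' @param n_otus_per_group named integer vector, OTUs per range group
#'   (default 100 endemic, 200 cosmopolitan, 30 bipolar — the study's scale
#'   of hundreds of OTUs with a small bipolar contingent).
#' @param lognormal_mu,lognormal_sigma log-mean and log-sd of the latent OTU
#'   abundance distribution (sigma 2 gives the observed dominance, with one
#'   OTU able to carry tens of percent of a community's reads).
#' @param activity_multiplier named positive vector per group.
#' @param relic_dna_multiplier named positive vector per group.
#' @param depth_decay_shared per-cm probability scale in \eqn{[0,1]} with
#'   which an OTU becomes unshared (silenced in one random pool) in a cell;
#'   the unsharing probability at depth z cm is `1 - (1 - p)^z`.
#' @param islands,pits number of islands and pits per island.
#' @param depths sampling depths in cm (default 2, 4, 8).
#' @param reads_per_sample fixed sequencing depth per replicate sample.
#' @param n_replicates replicate extractions per soil tube (default 5).
#' @param sigma_island,sigma_pit,sigma_replicate log-sd of the multiplicative
#'   lognormal perturbations of OTU weights at each design level.
#' @param class_bias optional list `list(class = <name>, n_otus = <int>,
#'   relic_multiplier = <x>, activity_multiplier = <x>)` planting a
#'   taxonomic-class-level pool bias for class-level test checks.
#' @param fraction_unidentified fraction of OTUs whose genus (and family,
#'   half the time) is an `unidentified__` token.
#' @param seed master seed; all sampling is derived from it.
#' @return a validated `sim_params` list.
#' @export
sim_params <- function(n_otus_per_group = c(endemic = 100, cosmopolitan = 200,
                                            bipolar = 30),
                       lognormal_mu = 0, lognormal_sigma = 2,
                       activity_multiplier = c(endemic = 1, cosmopolitan = 1,
                                               bipolar = 1),
                       relic_dna_multiplier = c(endemic = 1, cosmopolitan = 1,
                                                bipolar = 1),
                       depth_decay_shared = 0.01,
                       islands = 3, pits = 3, depths = c(2, 4, 8),
                       reads_per_sample = 5000, n_replicates = 5,
                       sigma_island = 0.5, sigma_pit = 0.25,
                       sigma_replicate = 0.25,
                       class_bias = NULL,
                       fraction_unidentified = 0.15,
                       seed = 1) {
  groups <- c("endemic", "cosmopolitan", "bipolar")
  p <- as.list(environment())
  if (!all(groups %in% names(p$n_otus_per_group)) ||
      any(p$n_otus_per_group < 0)) {
    pc_stop("paircomm_bad_params",
            "n_otus_per_group needs non-negative endemic/cosmopolitan/bipolar")
  }
  for (nm in c("activity_multiplier", "relic_dna_multiplier")) {
    if (!all(groups %in% names(p[[nm]])) || any(p[[nm]] <= 0)) {
      pc_stop("paircomm_bad_params", "%s needs positive values per group", nm)
    }
  }
  if (depth_decay_shared < 0 || depth_decay_shared > 1) {
    pc_stop("paircomm_bad_params", "depth_decay_shared must lie in [0,1]")
  }
  if (islands < 1 || pits < 1 || length(depths) < 1 || n_replicates < 1 ||
      reads_per_sample < 1) {
    pc_stop("paircomm_bad_params", "design sizes must be at least 1")
  }
  if (!is.null(class_bias) &&
      (is.null(class_bias$class) || is.null(class_bias$n_otus))) {
    pc_stop("paircomm_bad_params", "class_bias needs $class and $n_otus")
  }
  structure(p, class = "sim_params")
}

# template hierarchy used to assign lineages; a handful of classes across
# three phyla, enough structure for distinctness and class-level tests
sim_taxonomy_template <- function() {
  t <- rbind(
    c("Ascomycota", "Pezizomycotina", "Leotiomycetes", "Helotiales", "Helotiaceae"),
    c("Ascomycota", "Pezizomycotina", "Eurotiomycetes", "Eurotiales", "Trichocomaceae"),
    c("Ascomycota", "Pezizomycotina", "Sordariomycetes", "Hypocreales", "Nectriaceae"),
    c("Ascomycota", "Pezizomycotina", "Lecanoromycetes", "Lecanorales", "Parmeliaceae"),
    c("Basidiomycota", "Pucciniomycotina", "Microbotryomycetes", "Sporidiobolales", "Sporidiobolaceae"),
    c("Basidiomycota", "Agaricomycotina", "Agaricomycetes", "Agaricales", "Psathyrellaceae"),
    c("Basidiomycota", "Agaricomycotina", "Tremellomycetes", "Filobasidiales", "Filobasidiaceae"),
    c("Chytridiomycota", "Chytridiomycotina", "Chytridiomycetes", "Rhizophydiales", "Rhizophydiaceae"))
  colnames(t) <- c("phylum", "subphylum", "class", "order", "family")
  as.data.frame(t, stringsAsFactors = FALSE)
}

#' Simulate a paired DNA/RNA OTU dataset with planted structure
#'
#' Latent abundances are lognormal per OTU; expected pool weights multiply
#' the latent abundance by the group's relic (DNA) or activity (RNA)
#' multiplier and by shared lognormal island/pit perturbations, so the two
#' pools of a cell are correlated as in a paired design. Deeper cells
#' unshare OTUs between pools at a rate set by `depth_decay_shared`. Each
#' replicate sample is drawn multinomially at exactly `reads_per_sample`
#' reads.
#'
#' @param params a [sim_params()].
#' @return list `table` ([otu_table()], all replicate samples of both
#'   pools), `metadata`, `taxonomy` and `truth` (per-OTU true group labels,
#'   latent abundances and the echoed params).
#' @export
simulate_paired_dataset <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  groups <- c("endemic", "cosmopolitan", "bipolar")
  ng <- params$n_otus_per_group[groups]
  n <- sum(ng)
  if (n < 1) pc_stop("paircomm_bad_params", "no OTUs requested")
  otu_id <- sprintf("OTU%04d", seq_len(n))
  group <- rep(groups, times = ng)

  latent <- with_seed(params$seed, "sim/latent",
                      stats::rlnorm(n, params$lognormal_mu,
                                    params$lognormal_sigma))
  taxonomy <- with_seed(params$seed, "sim/taxonomy",
                        sim_assign_taxonomy(otu_id, params))
  bias_ix <- attr(taxonomy, "class_bias_otus")

  act <- params$activity_multiplier[group]
  rel <- params$relic_dna_multiplier[group]
  if (!is.null(bias_ix)) {
    cb <- params$class_bias
    rel[bias_ix] <- rel[bias_ix] * (cb$relic_multiplier %||% 1)
    act[bias_ix] <- act[bias_ix] * (cb$activity_multiplier %||% 1)
  }

  islands <- c("Bird", "Signy", "Leonie", sprintf("Island%d", seq_len(97)))
  islands <- islands[seq_len(params$islands)]
  design <- expand.grid(replicate = seq_len(params$n_replicates),
                        pool = c("DNA", "RNA"),
                        depth_cm = params$depths,
                        pit = sprintf("P%d", seq_len(params$pits)),
                        island = islands,
                        stringsAsFactors = FALSE)
  design <- design[, rev(names(design))]
  design$sample_id <- sprintf("%s.%s.D%g.%s.R%d", design$island, design$pit,
                              design$depth_cm, design$pool, design$replicate)

  counts <- matrix(0L, n, nrow(design),
                   dimnames = list(otu_id, design$sample_id))
  for (isl in islands) {
    e_isl <- with_seed(params$seed, paste0("sim/island/", isl),
                       stats::rlnorm(n, 0, params$sigma_island))
    for (pit in unique(design$pit)) {
      e_pit <- with_seed(params$seed, paste0("sim/pit/", isl, "/", pit),
                         stats::rlnorm(n, 0, params$sigma_pit))
      for (z in params$depths) {
        cell <- paste(isl, pit, z, sep = "/")
        base <- latent * e_isl * e_pit
        w_dna <- base * rel
        w_rna <- base * act
        # depth-dependent unsharing: silence the OTU in one random pool
        p_un <- 1 - (1 - params$depth_decay_shared)^z
        un <- with_seed(params$seed, paste0("sim/unshare/", cell), {
          u <- stats::runif(n) < p_un
          which_pool <- sample(c("DNA", "RNA"), n, replace = TRUE)
          list(u = u, pool = which_pool)
        })
        w_dna[un$u & un$pool == "DNA"] <- 0
        w_rna[un$u & un$pool == "RNA"] <- 0
        sel <- design$island == isl & design$pit == pit & design$depth_cm == z
        for (i in which(sel)) {
          w <- if (design$pool[i] == "DNA") w_dna else w_rna
          counts[, i] <- with_seed(params$seed,
                                   paste0("sim/draw/", design$sample_id[i]), {
            e_rep <- stats::rlnorm(n, 0, params$sigma_replicate)
            as.integer(stats::rmultinom(1, params$reads_per_sample,
                                        prob = w * e_rep))
          })
        }
      }
    }
  }
  meta <- design[, c("sample_id", "island", "pit", "depth_cm", "pool",
                     "replicate")]
  rownames(meta) <- NULL
  truth <- list(otu_id = otu_id, group = group, latent_abundance = latent,
                class_bias_otus = otu_id[bias_ix], params = params)
  list(table = otu_table(counts), metadata = meta,
       taxonomy = as.data.frame(taxonomy), truth = truth)
}

sim_assign_taxonomy <- function(otu_id, params) {
  n <- length(otu_id)
  tpl <- sim_taxonomy_template()
  row <- sample.int(nrow(tpl), n, replace = TRUE)
  bias_ix <- NULL
  if (!is.null(params$class_bias)) {
    cb <- params$class_bias
    if (!cb$class %in% tpl$class) {
      pc_stop("paircomm_bad_params", "class_bias class '%s' not in template",
              cb$class)
    }
    bias_ix <- sample.int(n, min(cb$n_otus, n))
    row[bias_ix] <- which(tpl$class == cb$class)[1]
    # keep the biased class otherwise rare so the planted effect dominates it
    other <- setdiff(seq_len(n), bias_ix)
    clash <- other[tpl$class[row[other]] == cb$class]
    row[clash] <- sample(which(tpl$class != cb$class), length(clash),
                         replace = TRUE)
  }
  tax <- data.frame(otu_id = otu_id, kingdom = "Fungi", tpl[row, ],
                    genus = paste0(substr(tpl$family[row], 1, 5), "genus",
                                   (seq_len(n) %% 3) + 1),
                    stringsAsFactors = FALSE, row.names = NULL)
  unid <- stats::runif(n) < params$fraction_unidentified
  tax$genus[unid] <- "unidentified__genus"
  deep <- unid & stats::runif(n) < 0.5
  tax$family[deep] <- "unidentified__family"
  structure(tax[, c("otu_id", tax_ranks)], class_bias_otus = bias_ix)
}

#' Simulate occurrence records consistent with the true range labels
#'
#' Endemic OTUs receive only study-site (Antarctic) records; cosmopolitan
#' OTUs additionally receive mid-latitude records in `(-60, 66.56]`; bipolar
#' OTUs additionally receive Arctic records strictly north of 66.56 and no
#' mid-latitude ones. By construction [classify_all()] recovers the true
#' labels exactly.
#'
#' @param truth the `truth` element of [simulate_paired_dataset()].
#' @param seed integer seed.
#' @param config the [range_rule_config()] the records should agree with.
#' @return an occurrence data.frame (`otu_id`, `latitude`, `is_study_site`).
#' @export
simulate_occurrence_records <- function(truth, seed = 1,
                                        config = range_rule_config()) {
  with_seed(seed, "sim/occurrences", {
    recs <- lapply(seq_along(truth$otu_id), function(i) {
      id <- truth$otu_id[i]
      n_study <- sample.int(3, 1)
      lat <- stats::runif(n_study, -68, -54)
      study <- data.frame(otu_id = id, latitude = lat, is_study_site = 1L)
      extra <- switch(truth$group[i],
        endemic = NULL,
        cosmopolitan = data.frame(
          otu_id = id,
          latitude = stats::runif(sample.int(3, 1),
                                  config$antarctic_boundary + 1e-6,
                                  config$arctic_boundary),
          is_study_site = 0L),
        bipolar = data.frame(
          otu_id = id,
          latitude = stats::runif(sample.int(2, 1),
                                  config$arctic_boundary + 1e-6, 90),
          is_study_site = 0L))
      rbind(study, extra)
    })
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    out
  })
}
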