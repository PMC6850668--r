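---
title: "Comparing total (DNA) and active (RNA) soil fungal communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing total (DNA) and active (RNA) soil fungal communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paircomm)
```

## The scientific problem

DNA extracted from soil profiles the *total* fungal community: active
mycelium, but also dormant spores, dead hyphae and extracellular "relic"
DNA, which is long-lived and can make up a large share of what is
sequenced. The precursor rRNA ITS transcript is short-lived and
predominantly present in metabolically active tissue, so RNA profiles the
*active* community. When DNA and RNA are co-extracted from the same soil
samples, each OTU can be asked a paired question: is it relatively more
abundant in the total or in the active profile?

`paircomm` implements that comparison for a nested survey design —
islands, soil pits within islands, depths within pits, replicate
extractions within each soil tube — and links it to biogeography: each OTU
is classified as **endemic** (found only in the focal Antarctic region),
**cosmopolitan** (found at sites elsewhere in the world) or **bipolar**
(found at high latitudes of both hemispheres but nowhere in between). The
ecological hypothesis under test is that endemic taxa, adapted to local
conditions, should be relatively enriched in the active community, while
cosmopolitan taxa — widely dispersed, often as metabolically quiescent
spores — should be enriched in the total community.

## Range classification

An OTU's occurrence records are latitudes (decimal degrees, positive
north), each flagged as a study site or not. The rules, in order:

* **endemic** — no record "elsewhere", i.e. no non-study record north of
  the Antarctic boundary (default −60°, the Antarctic Treaty line);
* **bipolar** — at least one record strictly north of the Arctic circle
  (66.56°N) and none in between;
* **cosmopolitan** — everything else. Bipolar takes precedence, and the
  three labels are mutually exclusive and exhaustive.

Two design choices deserve comment. First, "north of the Arctic circle"
is read as a strict inequality: a record at exactly 66.56° counts as
mid-latitude and voids bipolarity. Second, study membership is carried by
an explicit `is_study_site` flag rather than by latitude alone, because a
sub-Antarctic study island can lie north of any defensible latitude cut
(Bird Island is at 54.0°S); endemism is membership in the study dataset
without outside occurrences, not a latitude threshold. Study OTUs that are
entirely absent from the occurrence table are endemic by definition. The
boundary separating "Antarctica" from "in between" for the bipolar rule is
not canonical, so it is configurable (`range_rule_config()`).

## The permutational paired sign test

This is the package's central statistic. After pooling replicates and
rarefying both pools to the lowest common sequencing depth, each OTU gets

\[ \delta_i = \sum_{\text{pairs } j} \big( r_{ij} - d_{ij} \big), \]

the summed difference between its rarefied RNA and DNA reads over all
DNA/RNA sample pairs. The sign of \(\delta_i\) marks the OTU as higher in
the active (\(\delta_i > 0\)) or total (\(\delta_i < 0\)) community; zero
is a tie. For an OTU group \(G\) (a range class, or a taxonomic class) the
test statistic is the proportion of its non-tie OTUs with higher abundance
in the total community:

\[ T_G = \frac{\#\{i \in G : \delta_i < 0\}}{\#\{i \in G : \delta_i \ne 0\}}. \]

Every OTU is weighted equally, which is what makes this robust to the
handful of extremely abundant taxa that dominate read counts. The null
distribution is generated by randomly permuting the complete label vector
across OTUs — preserving group sizes — and recomputing \(T_G\); the "95%
expected set" is the empirical 2.5–97.5 percentile range of the null
values, and the two-tailed p-value doubles the smaller tail with add-one
smoothing, \(p = \min\!\big(1, 2\,(b+1)/(n_{\mathrm{perm}}+1)\big)\), so the
smallest reportable p at 1000 permutations is 2/1001.

Decisions made where the procedure was underdetermined:

* **Ties** are removed before the labels are permuted — the standard sign
  test treatment. This keeps the statistic's denominator fixed across
  permutations and avoids permutations in which a group would contain only
  ties; tie counts are reported alongside each result.
* **"Higher overall abundance"** is the sign of the summed rarefied
  difference across all pairs. A per-pair majority-vote variant is
  available behind `per_pair_majority = TRUE` for sensitivity analysis.
* By default only OTUs detected in **both** nucleic-acid pools enter the
  test: range labels derive from a DNA-based reference, so OTUs seen only
  in RNA would lean endemic for circular reasons. `include_all = TRUE`
  lifts the filter.
* When several groups are tested at once (`sign_tests_by_group()`,
  `class_level_tests()`), each permutation shuffles the label vector once
  and every group is evaluated on the same shuffle, so the per-group nulls
  are mutually consistent. Class-level p-values are Benjamini–Hochberg
  adjusted; raw p-values are always reported.

`exact_sign_test_oracle()` enumerates every distinct assignment of the
label multiset (equivalently the \(\binom{n}{|G|}\) group position sets)
and returns the exact two-tailed p. It exists to verify the Monte-Carlo
test and is used that way in the test suite; it is not the production
path.

For paired per-sample metrics (richness, evenness, distinctness) the
package deliberately does **not** fit the mixed-effects models such data
often receive. `sign_flip_paired_metric_test()` is a documented
nonparametric substitute: the statistic is the mean paired difference and
the null flips the sign of each pair's difference at random. It respects
the pairing but not island/pit random-effect structure beyond it.

## Rarefaction and diversity metrics

Rarefaction is sampling without replacement (multivariate hypergeometric)
to a fixed depth, the ecological standard; a sample already at the target
depth passes through unchanged. Each (iteration, sample) combination draws
from its own RNG substream derived by hashing the labels with
`derive_seed()`, so results are independent of iteration and column order.
Metrics are iterated over rarefaction draws (1000 by default) and
summarized by their mean and empirical 2.5–97.5 percentile range — the
package's reading of a "95% confidence range" across iterated rarefied
matrices.

* **Richness** is the count of OTUs with positive rarefied counts.
* **Evenness** is Pielou's \(J = H / \ln S\) (Shannon entropy over its
  maximum), the standard evenness bounded in \([0,1]\); a one-species
  community is defined as \(J = 0\).
* **Average taxonomic distinctness** is the presence/absence form
  \(\Delta^+\): the mean over all unordered pairs of present OTUs of a
  path-length weight \(\omega\) across the seven ranks kingdom…genus, with
  equal step lengths scaled so maximally distant pairs weigh 100.
  Concretely, a pair whose deepest shared rank is level \(s\)
  (kingdom = 1, …, genus = 7; \(s = 0\) when nothing is shared) weighs
  \(\omega = \min(7,\, 8 - s) \cdot 100/7\): congeneric OTUs weigh
  \(100/7 \approx 14.29\), and pairs differing at phylum or kingdom are
  both maximally distant at 100. Unidentified ranks are the literal tokens
  `unidentified__<rank>` and compare as ordinary names; an OTU missing
  from the taxonomy entirely is given a private lineage (maximally
  distinct from everything) with a warning. \(\Delta^+\) is undefined for
  fewer than two present OTUs and returned as `NA` with a warning.
* **k-dominance curves** accumulate the sorted relative abundances of the
  \(k\) most abundant OTUs; they are non-decreasing and reach 1 at the
  observed richness.

The abundance-weighted taxonomic diversity \(\Delta\) is not computed:
the presence/absence form is the one the comparisons need, and an
abundance-weighted variant would largely restate the evenness results.

## Composition

Bray–Curtis dissimilarity is computed on proportion-transformed counts
(each sample divided by its total), making it invariant to sequencing
depth; a rarefied mode exists for sensitivity analysis. The PERMANOVA is
deliberately one-factor: the pseudo-F

\[ F = \frac{SS_B/(a-1)}{SS_W/(N-a)}, \qquad
   SS_T = \tfrac{1}{N}\sum_{i<j} d_{ij}^2, \quad
   SS_W = \sum_g \tfrac{1}{n_g} \sum_{i<j \in g} d_{ij}^2 \]

with significance by permuting the grouping vector, optionally within
strata (e.g. within each island × pit × depth cell, so only the DNA/RNA
labels of a soil core exchange). \(R^2 = SS_B/SS_T\). The p-value counts
permuted statistics at least as large as the observed one, with add-one
smoothing. Following the original analysis design, the pipeline runs this
at replicate level — the distance matrix over all unpooled samples — which
is why its sample size is the full replicate count.

The proportion of fungi shared between the two pools of a pair is read as
the Jaccard overlap of presence sets, \(|A \cap B| / |A \cup B|\), on the
unrarefied pooled tables; the per-pair table carries island, pit and depth
so any regression tool can model the depth trend, and the analysis
drivers include a nonparametric shallow-vs-deep sign-flip check rather
than a GLMM.

## The synthetic-data generator

Real paired surveys of this kind cannot be reconstructed at desk scale,
so the generator is a first-class module that emulates the
*post-clustering* products of one: OTU tables, metadata, taxonomy and
occurrence records with known ("planted") structure.

Per OTU \(i\) with group \(g_i\), a latent abundance \(a_i \sim
\mathrm{lognormal}(\mu, \sigma)\) is perturbed by multiplicative lognormal
island and pit effects shared between pools (this is what makes the design
genuinely paired), then weighted by \(\theta_{g_i}\)
(`activity_multiplier`) in the RNA pool and \(\rho_{g_i}\)
(`relic_dna_multiplier`) in the DNA pool. Each replicate sample draws its
counts from one multinomial at exactly `reads_per_sample` reads —
fixed-depth sampling rather than Poisson, so rarefaction is exercised on
exact column sums. With soil depth \(z\), each OTU is silenced in one
random pool of a cell with probability \(1 - (1-p)^z\)
(`depth_decay_shared`), which plants the decline of cross-pool sharing
with depth.

Defaults are chosen once to mirror the scale of the motivating study:
100 endemic, 200 cosmopolitan and 30 bipolar OTUs; 3 islands × 3 pits ×
depths {2, 4, 8} cm; 5 replicate extractions per tube; 5000 reads per
sample; \(\sigma = 2\), which reproduces the strong dominance seen in
real k-dominance curves (a single OTU can carry tens of percent of a
community's reads); island and pit effect log-sds of 0.5 and 0.25; and
multipliers of 1 (no pool bias) so the default world is the null.
`simulate_occurrence_records()` emits study-site records for every OTU,
mid-latitude records in (−60°, 66.56°] for cosmopolitan OTUs and
strictly-Arctic records for bipolar OTUs, so classification recovers the
true labels exactly — a round-trip the tests exploit.

What the generator does *not* emulate: sequence-level error, chimeras,
ITS length variation and copy-number bias, taxon-specific PCR efficiency,
or the real study's variance components. Passing tests therefore show
that the pipeline's statistics behave correctly on data with this
structure — calibrated type-I error, recovery of planted effects,
deterministic reproducibility — not that any particular biological
conclusion transfers to field data.

## Numerical choices and problem sizes

* All stochastic stages derive their seeds from one master seed by a
  polynomial hash of a stage label modulo \(2^{31}-1\) (`derive_seed()`),
  so adding or reordering stages does not shift downstream streams, and
  two runs with one seed are byte-identical.
* Percentile sets use the default quantile definition (type 7);
  two-tailed p-values double the smaller smoothed tail and cap at 1.
* Degenerate inputs are defined, not crashed: single-species evenness is
  0; \(\Delta^+\) below two OTUs is `NA` with a warning; an all-tie group
  or a single PERMANOVA group is a classed error; a sample shallower than
  the rarefaction depth is an error naming the sample.
* The test suite works at deliberately modest problem sizes chosen as a
  matter of design — e.g. 50 oracle-equivalence instances at 50 000
  permutations, 500 null calibration replicates at 150 OTUs, 20
  planted-effect recovery seeds at the full default design, 10 000
  rarefaction draws for the hypergeometric check — sizes at which the
  Monte-Carlo error bounds quoted in each test are meaningful.

## Known limitations

* The sign test treats OTUs as exchangeable units; phylogenetic
  correlation between OTUs is not modelled, so labels that cluster on the
  tree can inflate apparent group effects in real data.
* The one-factor PERMANOVA does not do sequential multi-factor
  partitioning, and the sign-flip metric test is not a substitute for a
  mixed model when island- or pit-level inference is the goal.
* Proportion-based comparisons are compositional: planting an enrichment
  in one group necessarily depresses the relative abundance of the
  others, and the test reads that depression as a genuine shift — visible
  in simulations as unbiased groups drifting away from 0.5.
* Occurrence-based range labels inherit every bias of the underlying
  occurrence database; the classifier only formalizes the rules.
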