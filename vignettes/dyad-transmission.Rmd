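---
title: "Dyad-level analysis of microbial transmission: methods and design"
author: "dyadtrans authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dyad-level analysis of microbial transmission: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadtrans)
```

# The scientific problem

Whether children acquire their oral (or gut) microbiota because of shared
genes or shared environment is hard to study with twin designs: both mono-
and dizygotic twins share genes *and* households. A cleaner contrast is
between **biological** and **adoptive** mother-child dyads: if host genetics
governed transmission fidelity, biological children should resemble their
mothers more than adopted children do. Species-level profiles are too coarse
for this question — most humans share a core set of oral species — so the
discriminating signal lives at **strain** resolution (here, amplicon
sequence variants of a hypervariable marker, one sample per subject), where
communities are highly personalised.

`dyadtrans` implements the statistical machinery this design needs:

1. count-table hygiene (depth filtering, singleton removal, rarefaction);
2. membership- and abundance-based dissimilarities (Bray-Curtis, Jaccard)
   and Shannon alpha diversity;
3. a **dependency-aware permutation test** comparing true dyads with
   unrelated cross-family pairings;
4. shared-taxon fraction estimation, rank-sum and Spearman comparisons,
   confounder regression, per-species tests with Benjamini-Hochberg
   correction;
5. a **family-structured synthetic cohort generator** so that every stage
   is verifiable without access to any particular study's raw data.

# The permutation test

For a design with $n$ dyads, let $d(m_i, c_j)$ be the dissimilarity between
mother $i$ and child $j$. The set of *unrelated* pairings is every
cross-family combination $\{(i,j): \mathrm{fam}(i) \neq \mathrm{fam}(j)\}$.
Comparing the $n$ paired values against all $n(n-1)$ unrelated values with a
rank-sum or t test is invalid: each sample occurs in $n-1$ unrelated
pairings, so those observations are strongly dependent.

The test statistic is instead

$$ T = \operatorname{median}\big(d(\text{random unrelated subset of size }
n)\big) \;-\; \operatorname{median}\big(d(\text{true pairs})\big), $$

with the subset size matched to $n$ so that the test has power comparable to
a rank-sum test on independent groups. The null distribution is obtained by
randomly permuting the child-to-mother assignment $B$ times (default
$B = 1000$); for each permutation the permuted pairings play the role of
"paired", a fresh unrelated subset is drawn from the universe *excluding the
permuted pairings*, and $T$ is recomputed identically. The two-sided p value
is the proportion of permutations with $|T_b| \ge |T_{\mathrm{obs}}|$.

Design choices worth recording:

* **Subset refresh.** The unrelated subset is redrawn for the observed
  statistic and within every permutation. Drawing it once and conditioning
  the whole null on that single subset is a defensible alternative reading;
  it is available via `fixedSubset = TRUE`, but redrawing avoids
  conditioning the null on one arbitrary draw and is the default.
* **Subset universe.** Each permutation draws from the design's
  cross-family universe minus any pair occupied by the current permuted
  assignment. With this convention the Monte-Carlo test converges to the
  exhaustive enumeration over all $n!$ assignments (see below); drawing from
  the full grid complement instead does not.
* **Permutation scheme.** Uniform permutations of side B; the identity is
  not excluded, and p is the plain proportion over the $B$ draws, matching
  the convention that a permutation test reports the empirical proportion.
  A `(b+1)/(B+1)` estimator is available (`estimator = "plus_one"`) but off
  by default.
* **Exhaustive mode.** For $n \le 8$, `exhaustive = TRUE` enumerates all
  $n!$ assignments and replaces the random subset by the full remaining
  universe, making the result deterministic. This is the oracle the
  Monte-Carlo path is tested against.
* **Medians** use the standard midpoint convention for even counts.
* **Same-family exclusion.** The unrelated universe excludes *any*
  same-family pair, not merely the focal dyads, so extended families cannot
  leak siblings or spouses into "unrelated" pairings.

# Dissimilarities, diversity, shared fractions

"Bray-Curtis based on community membership" is Bray-Curtis applied to 0/1
vectors, which equals the Sørensen dissimilarity
$1 - 2|A \cap B| / (|A| + |B|)$; the abundance variant is the same metric on
per-sample proportions (`basis = "relative_abundance"`), not a different
metric. Jaccard ($1 - |A \cap B| / |A \cup B|$) is defined on membership
only and is rejected on other bases; on binary data the two satisfy
$J = 2B/(1+B)$, which the test suite checks to $10^{-12}$. Shannon diversity
uses the natural log by default (`base` is exposed). Matrix-level
computation is delegated to `vegan::vegdist`, with the scalar closed forms
serving as the independent oracle in the tests.

Shared-taxon fractions report the union-based count fraction
$|A \cap B| / |A \cup B|$ as the primary quantity — the denominator is not
uniquely determined by convention, so the per-member fractions
$|A \cap B|/|A|$ and $|A \cap B|/|B|$ are returned alongside — plus an
abundance-weighted version: the mean over the two samples of the summed
relative abundance of shared taxa.

# Table operations

* **Filter order is fixed**: low-depth samples first (default threshold
  5000 reads, strictly below), then taxa detected in fewer than 2 samples.
  The two filters are order-dependent in principle, so the pipeline pins
  this order for reproducibility.
* **Rarefaction** is without-replacement subsampling (`vegan::rrarefy`),
  seeded, with `depth = "row_min"` resolving to the minimum column sum of
  the table at hand (per table, not per group). Rarefaction precedes
  presence/absence conversion and distance computation; it can be disabled
  in the pipeline config (`rarefy: false`).
* Species tables are strain tables collapsed through an explicit
  strain-to-species map; column sums are conserved exactly.

# The synthetic cohort generator

No generative model is prescribed for data of this kind, so the generator is
the package's own construction, built to emulate the downstream statistical
structure such analyses assume. Strain identities are categorical — no
sequences are simulated — because every statistic downstream consumes only
the count table.

* **Adults.** A pool of `nSpeciesPool = 120` species with a two-tier
  occupancy profile: 40 "core" species carried with probability 0.95 and 80
  rarer species at 0.20, emulating a widely shared core plus a personalised
  tail. Within each carried species an adult holds each of
  `strainsPerSpecies = 8` strains with probability `strainOccupancy = 0.3`
  (at least one), giving highly personalised strain repertoires.
* **Children.** Each maternal strain is transmitted with probability
  `tau` (default 0.25, plus `geneticEffect` — default 0 — for biological
  dyads only); an independent environmental draw, scaled by
  `envRate = 0.65`, adds strains from the general pool; the union is then
  thinned by the age-dependent retention
  $\mathrm{richnessMax} \cdot a/(a + \mathrm{ageHalf})$ with
  `ageHalf = 1.5` years, so infant communities are sparse and converge to
  adult richness and diversity over the first years of life. Child ages
  default to Uniform(0.25, 6) years.
* **Couples and siblings.** Fathers combine an independent adult draw with
  maternal strains shared at `householdRho = 0.5` (cohabitation); siblings
  are a second child draw from the same mother.
* **Counts.** Relative abundances are symmetric Dirichlet
  ($\alpha = 0.5$) over the repertoire, tilted by
  $\mathrm{occupancy}^{\mathrm{abundanceCoupling}}$
  (default exponent 2) so core species dominate communities — membership
  statistics are insensitive to the abundance law, but abundance-based
  variants need realistic unevenness and core dominance. Read counts are
  multinomial at a per-sample depth of `readDepth = 25000` perturbed by a
  log-normal factor ($\sigma = 0.3$, floored at one read), which makes the
  5000-read filter exercisable.

The default configuration — 100 families, half labelled adoptive, with
`geneticEffect = 0` — was calibrated once, analytically and against single
simulated cohorts, to bracket the descriptive landscape typical of such
cohorts (union-based shared fractions of roughly 45%/40% of species and
15%/8% of strains for related/unrelated pairs) and then frozen. `household
rho` has no empirical anchor (no study decomposes household versus vertical
transmission quantitatively); 0.5 is a plausibility choice, not an estimate.

What the generator deliberately does **not** model: read-level errors,
chimeras or PCR artifacts beyond singleton ASVs, longitudinal sampling,
phylogenetic structure among strains, and niche differentiation (one niche
label is stamped per run). Passing tests therefore demonstrate the
statistical machinery is correct under a plausible family-structured model —
not that any particular biological cohort satisfies that model.

# Validation strategy and numerical choices

The test suite validates each claim at the scale that makes it decidable on
one CPU in minutes; the sizes below are the package's own choices.

* **Oracle equivalence.** On a 3-dyad design with hand-built distances
  (paired 0.1, cross-family 0.9) the exhaustive enumeration over all 6
  assignments gives p = 1/6 exactly; the Monte-Carlo path must agree within
  $2/\sqrt{B}$ for $B \in \{1000, 10000\}$.
* **Type-I calibration.** 500 null datasets (30 dyads each, default
  generator, dyad assignment shuffled so the pairing label is exchangeable
  by construction) must give a rejection rate in $[0.03, 0.07]$ at
  $\alpha = 0.05$ and a p distribution passing Kolmogorov-Smirnov against
  uniform at the 1% level.
* **Power and recovery.** The true dyad shared-strain fraction must
  increase strictly over $\tau \in \{0, 0.25, 0.5, 0.75, 1\}$ (200 dyads
  per point), and at $\tau = 0.5$ with 40 dyads the median permutation p
  (7 replicates, $B = 1000$) must fall below 0.05.
* **Cohort emulation.** 100 default-cohort replicates must reproduce the
  qualitative findings such a design should show when genetics plays no
  role: no biological-vs-adoptive difference in >90% of runs, related dyads
  significantly closer than unrelated pairings, species-level sharing above
  strain-level sharing in every run, and a negative age-distance
  correlation.

Degenerate inputs are defined errors, not silent results: two all-zero
samples have no dissimilarity; a zero-sum sample has no relative abundances;
a constant vector has no rank correlation; rarefaction below a sample's
depth names the offending sample. Ties in medians use midpoints; rank-sum
tests switch from exact enumeration to the tie-corrected normal
approximation exactly when ties or group sizes above 10 appear; Spearman p
values use the asymptotic t approximation with midranks throughout.

# Reproducibility

Every randomised operation takes an explicit integer seed and restores the
caller's RNG state (`withr::with_seed`), so identical seeds give
byte-identical tables, distance matrices and test results. The pipeline
spawns per-stage seeds deterministically from one global seed, records them
in its JSON run summary together with the package version, and logs
per-stage attrition (samples and taxa in/removed/out). Benjamini-Hochberg
correction is applied only where a family of related hypotheses is actually
tested — the per-species comparisons — not to the main dyad tests.

# Known limitations

* The permutation scheme treats one side of the design as permutable
  against the other; designs with several children per family are reduced
  to one index child per relation (siblings enter through the `sibling`
  relation instead).
* Exhaustive enumeration is capped at 8 dyads ($8! = 40320$ assignments).
* The generator's age model moves richness, not composition: infants lose
  strains uniformly at random, whereas real succession is ordered.
* Jaccard on relative abundances is intentionally unsupported; the
  abundance-based comparison is Bray-Curtis.
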