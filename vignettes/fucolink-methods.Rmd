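---
title: "Methods: degrader scoring, 16S-MAG linking and community statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: degrader scoring, 16S-MAG linking and community statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fucolink)
```

# The problem

Diet-intervention mouse studies of brown-seaweed polysaccharides
(fucoidans) routinely produce three kinds of evidence about the gut
microbiome: metagenome-assembled genomes (MAGs) with functional gene
annotations, 16S rRNA amplicon profiles with taxonomy, and host
phenotypes such as bodyweight across diet groups (low-fat Control,
high-fat Model, high-fat + polysaccharide). fucolink implements the
downstream inference that joins these layers into a single per-MAG
report: which MAGs look like fucoidan degraders, which 16S sequences
identify them, how their abundance behaves across groups, and how it
tracks bodyweight.

# Degrader scoring by Jensen-Shannon divergence

The functional signature used here is a genome's *gene-class
distribution*: the relative abundance of functional gene categories
among its (classified) genes, built by `build_profile()` with one
count per gene. Known fucoidan-degrading bacteria -- the reference
panel, in the motivating design twelve strains including eight
*Lentimonas* spp. -- have closely similar gene-class distributions, so
a candidate genome is scored by the minimum Jensen-Shannon divergence
(JSD) between its distribution and each panel member:

$$\mathrm{JSD}(P, Q) = H(M) - \tfrac{1}{2}H(P) - \tfrac{1}{2}H(Q),
\qquad M = \tfrac{1}{2}(P + Q),$$

with $H$ the Shannon entropy. A MAG is called a potential degrader
when its minimum JSD is **strictly below 0.0558**.

Numerical choices, all surfaced as arguments and recorded in the
report header:

* **Log base 2** by default, so JSD lies in $[0,1]$. The threshold's
  scale convention is not standard across tools, so the base is a
  visible knob rather than a silent assumption; the 0.0558 default is
  interpreted on the base-2 scale.
* **No pseudocounts.** $0\log 0 = 0$, and since $M > 0$ wherever $P$
  or $Q$ is positive, exact JSD needs no smoothing. Profiles must be
  normalised within $10^{-6}$; mismatched category universes are an
  error, with `align_category_universe()` providing the zero-filled
  union.
* **Strict inequalities** for every cutoff (`<` 0.0558, `>` 300 bp,
  `>` 99 %), matching the wording conventions of the tables such
  reports are written for. A value exactly at a boundary never
  qualifies.
* **Ties** for the best reference are broken by panel order, for
  determinism.
* Genes without a category carry no class signal and are dropped by
  default; `include_unclassified = TRUE` pools them into a reserved
  label instead, preserving the alternative reading. Each gene counts
  once regardless of length, because the signature is a distribution
  over genes, not base pairs.

The threshold itself is treated as given, not derived:
`calibrate_threshold()` reports panel-internal JSD percentiles so a
user can judge where a cutoff sits, but the package makes no claim
about how any published value was chosen.

# Linking 16S sequences to MAGs

16S representative sequences are compared against the genes annotated
from each MAG. A sequence and a MAG are considered to come from the
same strain only when the best local alignment between them has
**alignment length > 300 bp and identity > 99 %**, both strict.
`read_hits()` ingests precomputed 12-column tabular alignment output;
`align_local()` provides an internal Smith-Waterman aligner
(match +2, mismatch -3, gap open 5, gap extend 2, both strands) so
the whole chain runs on desk-scale fixtures without an external
search engine. Identity is matches / alignment columns and length
counts alignment columns including gaps, the dominant tabular-output
convention.

Before filtering, hits are reduced to the best per (MAG, query) pair
-- highest identity, then longest alignment, then first seen -- so a
multi-HSP hit is not double counted. Nothing in the filter forces a
bijection: if several queries identify one MAG (or one query several
MAGs), all qualifying pairs are reported and flagged `multi_link`,
leaving the interpretation to the analyst.

# Community statistics

* **Richness.** `chao1()` implements the bias-corrected form
  $S_{obs} + F_1(F_1-1)/(2(F_2+1))$; `ace()` the classic
  abundance-based coverage estimator with rare cutoff 10 and the
  $\gamma^2$ coefficient-of-variation term floored at 0. Both refuse
  proportions: the estimators are functions of rare *counts*
  (singletons, doubletons), which relative abundances destroy. When
  every rare individual is a singleton the ACE coverage estimate is
  0 and the function falls back to Chao1 with a warning. The variant
  names are stated in output headers because different software
  computes different variants. No rarefaction is applied by default;
  counts are used as given.
* **Ordination.** `pca_ordination()` is a column-mean-centred,
  unscaled SVD of the sample-by-feature table. Component signs are
  fixed by making each loading vector's largest-magnitude element
  positive, so reruns and sample permutations give reproducible
  scores. A Hellinger transform is available as an opt-in flag for
  compositional data; the default is the plain PCA of relative
  abundances that such studies conventionally show.
* **Group differences.** `group_test()` runs per-feature one-way
  ANOVA followed by Tukey HSD over all group pairs, at alpha 0.05
  **uncorrected** by default -- the convention of the figure panels
  this mirrors -- with a Benjamini-Hochberg toggle for stricter use.
  Zero-variance features are flagged degenerate rather than raising.

# Bodyweight association

`spearman_cor()` computes Spearman's rho on mid-ranks. With group
sizes of 4-6 mice, pooled n is around 12 and per-group n is far below
where the asymptotic t approximation is trustworthy, so for
$n \le 9$ the two-sided p-value is **exact**: the observed $|\rho|$
is compared against all $n!$ permutations of one rank vector
(enumeration stays under a second at $n = 9$; the cached permutation
table is the only state). Above that the usual
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ approximation takes over, and each
result records which method produced it. Correlations are pooled
across diet groups -- one rho per MAG, the shape of a key-species
table -- with a per-group option left to the caller by subsetting.
Stars follow the usual convention (* < 0.05, ** < 0.01, *** < 0.001),
uncorrected by default with a BH toggle.

# The synthetic-data generators

All inputs can be simulated with known ground truth, deterministically
from one seed (`simulation_config()` + `simulate_dataset()`); every
generator draws from a substream derived from the master seed, so any
subset of outputs is individually reproducible.

* **Panel**: one smooth base distribution (Dirichlet with
  concentration 5 per category), each of the 12 panel strains a
  Dirichlet draw around it at concentration 5000. This reproduces a
  panel whose members' distributions are "quite similar": pairwise
  JSD about 0.002-0.006, verified at generation time and resampled
  (bounded retries) if any pair reaches the threshold.
* **MAGs**: 60 MAGs of which 10 planted degraders, each a Dirichlet
  perturbation of a random panel member at scale `degrader_noise`
  (default 0.003, putting planted minimum JSD around 0.02-0.04 --
  the range key degrader MAGs occupy in practice); background MAGs
  drawn around an independent rough base (Dirichlet(1) base,
  concentration 50), landing at minimum JSD around 0.2-0.35. The two
  ranges are disjoint around 0.0558 by construction, which is what
  makes planted-flag recovery a meaningful regression test.
* **Abundance and bodyweight**: three groups of 4 samples.
  Bodyweight is group mean + Gaussian noise (means 32, 45, 38 g for
  Control, Model, SjC; only the ordering Model > SjC > Control
  matters downstream). Feature log-abundances are baseline + a
  planted Model-group shift (`effect_size`, default 2) on 8
  differential features + a planted bodyweight coefficient
  (`assoc_strength`, default 0.8) on 6 associated features + Gaussian
  noise (sd 0.5, a typical biological coefficient of variation),
  then closed to compositions by softmax; a multinomial count table
  at depth 50,000 accompanies the proportions for the richness
  estimators. At `assoc_strength = 1` with zero noise the planted
  monotonicity survives closure exactly (the softmax derivative keeps
  the planted sign), giving $|\rho| = 1$ limit cases. Setting both
  effects to 0 gives an exact null in which groups and bodyweight
  carry no information, used to verify ~5 % false-positive rates.
* **Sequences**: five 16S query / MAG gene pairs planting an exact
  430 bp copy (pass), a 310 bp copy with 2 mismatches (pass,
  99.35 %), a 66 bp exact copy (length fail), a 400 bp copy with 8
  mismatches (identity fail, 98.0 %), and a 100 bp copy with 3
  mismatches (both fail). Mismatches are placed well inside the
  segment so the optimal local alignment provably spans it; an
  exact-copy-with-mismatches scheme is used rather than an
  evolutionary model because identity and length are the only
  quantities the filter reads.

What the generators do *not* emulate: read-level error, assembly and
binning artefacts, compositional correlation structure between taxa,
overdispersion beyond log-normal noise, or phylogenetic signal.
Passing tests therefore demonstrate that the inference chain is
correct and calibrated on data satisfying its assumptions -- not that
those assumptions hold in any particular real dataset.

# The integrated pipeline

`run_pipeline()` chains the stages and writes every intermediate
table as TSV, so each stage is independently re-runnable and
inspectable -- the way such multi-tool analyses are actually
conducted. The integrated report has one row per MAG in the abundance
table, sorted by $|\rho|$ descending: rho with stars, minimum JSD and
the degrader call, and the linked 16S representative (taxonomy,
identity, alignment length; NA when no accepted hit exists). Its
header embeds every decision knob -- threshold, log base, filter
cutoffs, alpha, pooling, seed -- because several of them are
conventions that silently differ between analyses; a report that does
not state them cannot be reproduced. `render_table1()` formats a
selection of rows in the published key-species layout; the selection
is an explicit argument because no objective criterion defines "key".
Invariants (degrader rows satisfy the threshold, linked rows satisfy
the filter) are asserted before anything is written, and two runs on
identical inputs produce byte-identical reports.

# Problem sizes and test design

The test suite and the acceptance script run entirely on simulated
data at the study's own scale: 12-strain panel, 60 MAGs, 3 x 4
samples. Property tests use 300-1000 random cases under fixed seeds;
the null-calibration check uses 200 replicate simulations (12,000
feature-level tests per statistic), enough to estimate a ~5 % rate to
within about half a percentage point. Estimators are verified against
independently coded oracles (a literal ACE transcription, brute-force
permutation enumeration for Spearman p, an affine-gap dynamic-
programming scorer for the aligner) and against vegan's
implementations where they overlap.

# Known limitations

* The aggregate published counts that require the original
  sequencing data (e.g. how many of 335 real MAGs pass the threshold)
  are out of reach by design; the package reproduces the decision
  rules and their printed worked examples, not the raw-data results.
* The JSD threshold is consumed, not derived; its provenance is not
  modelled.
* The category granularity of gene-class profiles is the caller's
  choice; labels are opaque strings and no ontology is imposed.
* The internal aligner is quadratic and meant for fixtures; genuine
  searches should come in as tabular hits.
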