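---
title: "Models and methods behind mitolineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitolineage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitolineage)
```

`mitolineage` packages an end-to-end intraspecific diversity analysis for
fission yeast mitogenomes and the nuclear *K*-region: circular-contig
canonicalization, segregating-site matrices, distance phylogenetics with
clade assignment, ancestry-mixture and mosaic-scan recombination analysis,
intron presence–absence analytics, and calibrated strict-clock dating. This
vignette explains the models, the tunable parameters, the numerical choices,
and what the simulation-based tests do and do not demonstrate.

## The two-lineage model and the simulator

The analyses assume that the sampled mitogenome types descend from two
long-separated lineages (clades), each containing two subclades, with a
linked but independently assorting nuclear locus (the *K*-region) evolving
on the same population history at its own rate. The simulator
(`simulation_config()`, `generate_population()`) realizes exactly this
structure:

* a root genome drawn uniformly over A/C/G/T;
* a clade split `t_split` generations before present (default
  `3.13e7`, the divergence the dating module is designed to estimate);
* within each clade, a star split into subclades at `subclade_splits`
  (default `t_split/10`), and a star radiation of tips within each subclade
  at `tip_radiation_frac` times the subclade split;
* per-branch substitution counts drawn Poisson with mean `mu * L * t` and
  placed at uniform positions with a Jukes–Cantor choice among the three
  alternative bases (multiple hits are allowed; at the ~1% divergence this
  package targets they shift expected pairwise differences by under 1%, and
  the tests use the closed form `L * 3/4 * (1 - exp(-4/3 * 2 t mu))`);
* the K-region evolving on the same tree at `k_rate_multiplier * mu`
  (default 1.27, the calibrated heterochromatin excess);
* intron presence evolving at 8 fixed sites by per-branch Bernoulli
  gain/loss (defaults 0.15/0.15, chosen to produce the widespread
  presence–absence polymorphism the intron module analyzes), with the
  mutually exclusive b/b′ variants at the *cox1*-I1b site labelled by clade;
* optional planted inter-clade recombination: the recipient's segment is
  overwritten with the donor clade's consensus, and recorded in the truth
  tables.

Two modeling choices deserve emphasis. First, the default subclade tip
radiations are asymmetric: subclades named `*-D` ("diverse") radiate at 0.6
of the subclade split time and all others at 0.1, so a low-diversity
"similar" subclade and a high-diversity "diverse" subclade exist by
construction — the contrast the subclade-labelling rule in
`assign_clades()` relies on. The generations are a design choice, not an
estimate: no within-subclade coalescent model is implied by the data this
package emulates, so a star with a fixed depth fraction is the simplest
structure carrying the needed signal. Second, introns are modelled at the
annotation level: presence flags over fixed reserved intervals, without
physically inserting or deleting intron sequence. Every downstream analysis
masks intron columns before use, and keeping the alignment gap-free makes
the substitutions-only baseline exact. Consequently the simulator does not
exercise gap projection through indel-containing alignments; that logic is
tested separately with hand-built gapped alignments.

What passing simulation tests show: the pipeline recovers clades, subclades,
planted recombinants, intron truth matrices and split times under the
model's own assumptions. What they do not show: robustness to real-data
features absent from the model — alignment error, indel polymorphism beyond
introns, rate variation among sites and lineages, selection, ancestral
polymorphism (see *Dating*), or assembly artifacts.

## Circular-contig canonicalization

Assemblers emit circular-mapping contigs as linear strings with an arbitrary
start and strand and a duplicated stretch at the end.
`find_terminal_overlap()` returns the longest suffix length `k >=
min_overlap` whose ungapped match to the prefix has at most
`max_mismatch_frac * k` mismatches. Defaults `min_overlap = 50` and
`max_mismatch_frac = 0.01` tolerate polish-level noise; there is no
published threshold for this step, so both are exposed. Candidates are
seeded by matching the first `min_overlap` bases within the trailing half
(allowing `seed_mismatch` mismatches, default `max(2,
ceiling(min_overlap * max_mismatch_frac))`) and verified in full; this is
exact unless more than `seed_mismatch` of the overlap's mismatches fall in
its first `min_overlap` bases, which at the supported mismatch densities is
the rare corner the brute-force comparison tests also avoid.
`rotate_to_anchor()` requires a unique (near-)exact anchor hit — by
convention the first 100 bp of the reference genome — on one strand,
searching the doubled sequence so matches may wrap; two hits raise an
ambiguity error rather than a silent pick. `canonicalize()` composes trim
and rotation and is idempotent. Coordinates are 1-based inclusive
throughout the package.

## Segregating-site matrices

`mask_alignment()` masks a column when it falls inside any taxon's intron
interval (intervals are given in each taxon's own ungapped coordinates and
projected through that taxon's gaps), when any row holds `N`, or — by
default — when any row holds a gap. Masking by *any* taxon's intron means a
presence–absence polymorphism removes the site for all taxa, keeping the
variant matrix strictly non-intronic. Columns polymorphic only by gaps are
therefore dropped, and indel-containing columns never enter the SNV set
even when gap columns are retained.

`extract_biallelic_snvs()` keeps columns with exactly two residue states;
`merge_snvs_to_mnvs()` merges neighboring SNVs closer than `window`
(default 15) that induce the identical allelic partition of the taxa,
chaining transitively: the pairwise rule is stated for neighbors, and chain
closure is its natural transitive completion (merged chains are visible via
`n_sites`). Spacing is measured in kept-column (gap-stripped) ordinals by
default — the alignment the variants are called from — with reference
coordinates available via `coord = "reference"`; which convention the
original analysis used is not documented, so both are provided and the
default is stated here. Merging is idempotent and its output partitions the
input SNVs; both properties are tested against a brute-force closure
oracle.

`classify_pairwise_differences()` reports maximal runs of disagreeing
columns as single differences, categorized by run shape, with indels
anchored on the preceding reference base (`C -> CC` style, as in GenBank
difference tables). `identify_reference_errors()` applies the rule that a
reference-vs-focal difference is a reference error precisely when the focal
allele is shared by every other assembled type; missing data yields
"unresolved", never a silent call. Amino-acid effects in the packaged
difference table rely on translation with genetic code 4 (UGA encodes
tryptophan in these mitochondria).

## Phylogenetics and clade assignment

Distances are p-distances (mismatches over mutually ungapped kept sites).
Trees are classic neighbor joining via `ape::nj()` with negative branch
estimates clamped to zero (count attached as an attribute), midpoint-rooted
via `phangorn::midpoint()`. NJ is exact on additive matrices, which the
tests verify on random trees of up to 8 taxa; likelihood-based tree
inference with rate heterogeneity is deliberately out of scope.
`bootstrap_support()` resamples kept columns with replacement and reports
the percentage of replicates containing each original internal bipartition.

`assign_clades()` takes the two children of the rooted tree's deepest split
(after excluding taxa flagged mosaic) as the clades; the clade holding the
reference taxon is `REF`. Within each clade the deepest split defines two
subclades: `REF-A` holds the reference taxon; on the other side the
lower mean within-subclade p-distance earns `NONREF-S` ("similar") and the
remainder `NONREF-D` ("diverse") — mirroring how a paraphyletic diverse
remainder is labelled in practice. Mosaic taxa are reported with their
nearest clade by mean distance but never define clades.

## Ancestry mixture and mosaic scanning

`admixture_em()` fits the haploid binary ancestry model
`P(g_ts = 1) = sum_k q_tk f_ks` by EM: responsibilities per taxon-site,
then closed-form updates of `q` (row means of responsibilities) and `f`
(responsibility-weighted allele frequencies). The log-likelihood is
non-decreasing by construction; frequencies are clamped to
`[1e-9, 1 - 1e-9]` for numerical safety, which caps any spurious
log-likelihood drift below the `1e-6` relative convergence tolerance. Ten
random restarts are the default (matching common practice of replicate
clustering runs), best likelihood kept, component order anchored to the
reference taxon's majority component. K = 1 reduces to the per-site
Bernoulli fit, a closed form the tests check.

`mosaic_scan()` formalizes heatmap inspection. Clade-informative sites are
sites where each clade's consensus reaches within-clade frequency
`freq_threshold` (default 0.8) and the consensuses differ. For each taxon,
maximal runs of at least `min_run` (default 3) consecutive informative
sites matching the opposite clade are scored
`p = (n_informative - r + 1) * bg^r`, a scan-statistic upper bound on
observing an all-opposite run of length `r` anywhere given the taxon's
background opposite-match rate `bg`, then Bonferroni-corrected across all
taxon-by-run candidates. The thresholds are exposed flags; the defaults
hold the false-positive rate on recombination-free simulations at zero
while detecting planted double-segment recombinants in over 90% of runs.
The score is this package's formalization of a qualitative visual
criterion, not a published statistic.

## Intron analytics

The presence matrix distinguishes `absent`, `present`, and the b/b′
variants at the *cox1*-I1b site (mutually exclusive; both at once is an
error). Pattern counting treats b and b′ as distinct states. All exact
tests use the two-sided Fisher convention "sum the probabilities of all
margin-consistent tables no more probable than the observed one" — the
convention of `stats::fisher.test()`, validated in the test suite against
full hypergeometric enumeration over every 2×2 table with total up to 60
(deduplicated by the 8 table symmetries). Degenerate margins report p = 1
with a flag rather than erroring. The LAGLIDADG scan uses a permissive
family pattern with position 8 unconstrained (`laglidadg_acidity()`,
pattern configurable since no canonical regex exists); any count that
depends on the motif definition is sensitive to that pattern. Acidity means
D or E at motif position 8, the residue required for homing endonuclease
catalysis; reading-frame checks of intron ORFs are offset arithmetic mod 3.

## Calibration and dating

The calibration compares SNV densities between two pure-lineage strains:
`ratio = (n_K/L_K) / (n_FF/L_FF)` over the 6.53-kb K-region versus 1.465 Mb
of feature-free nuclear sequence (70 and 12,321 SNVs respectively for the
canonical strain pair), interpreted as a mutation-rate excess of the
heterochromatic K-region. `calibrate_rate()` multiplies the genome-wide
rate (2.00e-10 substitutions/site/generation) by the ratio rounded to two
decimals by default — reproducing the conventional printed value 2.54e-10
exactly — with the unrounded product available by flag.

`strict_clock_divergence()` estimates the split time as
`T = d_net / (2 mu_region)` with
`d_net = d_between - (d_within_1 + d_within_2)/2`. Net divergence is
preferred over the raw between-clade distance because, under ancestral
polymorphism, raw distance estimates the mean coalescence time rather than
the split; both are reported. On this package's simulator — which has no
ancestral polymorphism — the net estimator runs a few percent low (it
subtracts post-split within-clade diversity) while the raw estimator is
unbiased; recovery tests accordingly allow a 15% envelope around the truth.
This is a deliberate simplification of Bayesian tree dating and all outputs
label it as such. Confidence intervals are percentile site bootstraps.
Year conversions use a 365.25-day year, so 12 generations/day gives 4,383
generations/year (and, e.g., a 3.13e7-generation split corresponds to 7,141
years at that rate or 78,250 years at 400 generations/year).
`mixing_analysis()` declares a strain inter-clade mixed when its mitogenome
clade and K-region group memberships disagree (exclusive-or on the
low-diversity lineage), excluding strains without a K-region
correspondence.

## Numerical choices, degenerate inputs, problem sizes

* Ties in midpoint rooting and NJ agglomeration follow the conventions of
  phangorn and ape; negative NJ branch lengths are clamped to zero.
* Degenerate inputs error early with informative messages: contigs shorter
  than twice the minimum overlap, ambiguous anchors, intervals out of
  bounds, unsorted variant input, star trees, single-clade assignments,
  zero baseline SNV counts, non-positive rates.
* The test suite sizes simulations to finish in minutes on one CPU: 20-kb
  genomes and ~20 types for pipeline recovery, 100 seeds for the
  closed-form divergence check, 50 seeds for mosaic detection and
  split-time recovery, 1,000 cases for canonicalization and MNV-closure
  property sweeps. These sizes are the package's choices for routine
  verification; all are parameters in the test code.

## Known limitations

* The simulator omits indels (the `indel_rate` field is reserved),
  demography, selection, migration and read-level noise; assemblies are
  taken as given.
* The mosaic scan needs a reasonable density of clade-informative sites;
  very recent splits or tiny clades starve it (it errors rather than
  guessing).
* The EM mixture, like all such models, has label-switching and local
  optima; restarts mitigate but do not eliminate the latter.
* The strict-clock estimator inherits the clock assumption; lineage-specific
  rate variation biases it in ways the bootstrap CI does not capture.
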