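---
title: "Inferring sex-biased admixture: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring sex-biased admixture: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdmix)
```

herdmix studies how sex-biased admixture leaves complementary signatures
in four compartments of the genome: the autosomes, the X chromosome, the
mitochondrial genome and the Y chromosome. The motivating system is the
admixture history of southern African Khoe-San descendant groups, where
an old East African pastoralist contribution (on the order of a thousand
years ago) was later overlaid by colonial-era West African, European and
Southeast Asian admixture. This vignette documents the models, the
tunable parameters, the synthetic-data generator, and the numerical and
design choices a user should know about.

## The admixture likelihood and its EM estimators

Ancestry fractions are estimated under the standard admixture model. For
individual $i$ with ancestry vector $q_i$ on the $K$-simplex, source
allele frequencies $f_{kj}$, alternate-allele count $g_{ij}$ and ploidy
$c_{ij}$ (2, or 1 on the male X):

$$\log L(q_i, F) = \sum_j g_{ij}\log\Big(\sum_k q_{ik} f_{kj}\Big)
 + (c_{ij}-g_{ij})\log\Big(\sum_k q_{ik}(1-f_{kj})\Big).$$

`supervised_q()` maximizes over $Q$ with $F$ fixed from reference
panels; `unsupervised_qf()` alternates EM updates of $Q$ and $F$
(the classic allele-copy responsibility updates), with replicate random
starts and best-likelihood selection. Assumptions worth stating: loci
are treated as independent (so an LD-pruned marker set is recommended
for unsupervised fits; `ld_prune()` implements the sliding-window
greedy r² scheme with defaults 200 SNPs / step 25 / r² 0.4), missing
genotypes are simply skipped (complete-case per SNP), and allele
frequencies are clamped to $[10^{-6}, 1-10^{-6}]$ so the likelihood is
always finite. EM is plain (no quasi-Newton acceleration): it is
monotone in the log-likelihood, which the tests assert every iteration.
Defaults: `tol = 1e-6` on the largest $Q$ (and $F$) move, `max_iter =
2000`. Unsupervised cluster labels are arbitrary; `align_clusters()`
does greedy matching by frequency correlation, for evaluation only.

A haploid male X call enters the likelihood with one allele copy.
Estimates are invariant to recoding a haploid 1 as a pseudo-diploid 2
with ploidy 2 (the per-copy information is identical); the invariance is
tested, and it is why the VCF reader refuses heterozygous male X calls
(they are set missing and counted, since a haploid chromosome cannot be
heterozygous).

## Quality control

`filter_missingness()` removes SNPs above a 5% missing-call fraction and
then individuals above 5%; SNPs go first so one bad assay does not
remove samples. `hwe_exact_filter()` computes the exact two-sided
Hardy-Weinberg test (recurrence over heterozygote counts, no mid-p) per
SNP within each sampling site and removes a SNP only when it fails
(p < 0.005) in *every* evaluable site — a SNP out of equilibrium
everywhere is a likely genotyping artifact, while failure at one site
may be real structure. Sites with fewer than five genotyped diploids at
a SNP are skipped for that SNP. `drop_ambiguous()` removes A/T and C/G
SNPs whose strand cannot be verified when merging datasets.
`ibs_relatedness()` screens cryptic relatedness with a kinship-like
proportion: one minus the ratio of the observed mean absolute genotype
difference to its expectation under independence at the sample allele
frequencies — duplicates score 1, first-degree pairs about 0.5,
unrelated pairs about 0. The flag cuts (0.45 first degree, 0.20 second
degree) are configurable defaults, chosen to sit between those
theoretical levels; the member of a flagged pair with more missingness
(ties: the later id) is excluded. `merge_panels()` intersects marker
sets, complements counts where ref/alt are swapped, and drops allele
conflicts. `polarize_ancestral()` applies the two-of-three great-ape
majority rule and requires the majority allele to be one of the two
human alleles. QC order is missingness → HWE → ambiguous removal, and
every filter is idempotent (tested).

## The X/autosome ratio procedure

The X spends two thirds of its history in females, so for a single
admixture pulse with female share $p_f$ of a source's contribution the
X-to-autosome ratio of that source's mean ancestry fraction is
$r = \tfrac{2}{3}(1+p_f)$: 2/3 for an all-male pulse, 1 for balanced,
4/3 for all-female. `xa_ratios()` implements the comparison fairly:
nine autosomal surrogates of X-like genetic length (chromosomes 1–7
trimmed to their first 180 cM; 10 and 12 whole, being already about
180 cM — a strict mode trims those two as well, since the source
descriptions differ on this point), each down-sampled to exactly the
X's SNP count, each run through supervised estimation separately, with
the ratio formed against each surrogate independently and then averaged
(the mean of ratios; the ratio of means is also reported).
Uncertainty is a bootstrap over individuals (default `n_boot = 100`),
reported as SD; error bars of two SDs are the conventional display.
Ancestries whose point estimate is below `min_ancestry = 0.02` on
either side are flagged `not-evaluated` rather than ratioed — a tiny
component can vanish from one chromosome by chance and produce wild
ratios. `infer_sex_fractions()` inverts $r$ to $p_f = 3r/2 - 1$ and
flags ratios outside $[2/3, 4/3]$: a ratio below the all-male floor is
evidence of *ongoing* male-biased gene flow, which a single pulse
cannot produce.

One honest caveat: the bootstrap-over-individuals SD captures cohort
sampling but not the single realization of the X chromosome's own
transmission history. In simulation we measured the across-replicate SD
of the ratio to be close to the bootstrap SD under recent pulses in
large pools, so the two-SD yardstick is approximately calibrated there,
but for small ancestry components over many generations the X drifts
appreciably (see the preset's pool-size note below).

## Coancestry curves and admixture dating

Local-ancestry tracts (from the simulator's truth, or from
`call_local_ancestry()`, a deliberately simple window-argmax caller with
optional 3-window majority smoothing) are sampled on a regular 0.2 cM
grid, and for an ordered ancestry pair $(A,B)$ the curve
$v(d) = \hat P(A \text{ at } x,\, B \text{ at } y)/(\hat p_A \hat p_B)$
is accumulated over all intra-haplotype pairs at distance
$d \in [0.5, 30]$ cM in 0.5 cM bins (grid sampling keeps the estimator
oracle-checkable by exhaustive enumeration; distances below 0.5 cM are
excluded as background LD; a covariance normalization is available
behind a flag). After a pulse, $v(d)$ approaches its asymptote
exponentially, and the rate counts the meioses that could separate the
pair.

`fit_exponential()` fits $v(d) = a\,e^{-\lambda u(d)} + c$ by weighted
least squares (weights = pair counts), profiling $\lambda$ by Brent
search over several brackets with the linear $(a, c)$ subproblem solved
exactly. Two deliberate choices, both recorded in the fit object and
reversible by arguments:

* **Distance coordinate.** The probability that two loci at map
  distance $d$ stay on one parental haplotype through a meiosis is
  $1 - r(d)$ with $r$ the Haldane recombination fraction
  $\tfrac12(1 - e^{-2d})$, so the default coordinate is the
  per-meiosis log-survival $u(d) = -\log(1 - r(d))$. Fitting in raw
  $d/100$ (the usual small-distance approximation,
  `map_function = "linear"`) underestimates $\lambda$ by several
  percent when the fit extends to 30 cM.
* **Meiosis offset.** The first post-admixture meiosis recombines two
  chromosomes of the *same* unadmixed founder and cannot switch
  ancestry, so $\lambda$ counts switching meioses — one fewer than
  generations since the pulse. The reported date is
  `generations = lambda + 1` (`meiosis_offset = 0` reports the raw
  rate). In forward simulations with a pulse 30 generations before
  sampling this estimator is unbiased to within a few tenths of a
  generation.

Confidence intervals come from `bootstrap_dates()`: individuals are
resampled with replacement (default 100 times), curves rebuilt from
per-individual pair-count caches, and the percentile interval reported.
Years use a fixed 30-year generation time (configurable).
`diagnose_curve_shape()` classifies curves as `classic-decay`,
`non-monotone` (a hump suggests multiple admixture events at different
times) or `flat` — the non-monotone case is exactly the situation in
which a single-pulse date should not be trusted.

## The forward-time simulator

`simulate_admixture()` is a discrete-generation, constant-pool-size,
sex-structured forward simulator on a centimorgan map: Poisson
crossovers (Haldane, no interference), X recombining in females only and
passed intact father-to-daughter, Y patrilineal, mtDNA matrilineal,
fresh migrants entering as unadmixed single-source individuals according
to a per-generation, per-sex schedule (`admixture_schedule()`), founders
carrying single-source chromosomes. It returns true tracts (tiling each
haplotype exactly), true ancestry fractions (exactly the tract-length
averages), uniparental labels with their parental provenance, and
deterministic output under a seed. `emit_genotypes()` lays
Balding-Nichols source frequencies (`make_source_freqs()`) over the
tracts. `expected_fractions()` gives the drift-free recursion for
autosomal, X, matriline and patriline expectations used throughout the
tests.

What the generator emulates: realistic chromosome-scale tract structure,
sex-linked transmission, pulse-then-dilution histories, and marker
panels of SNP-array-like density. What it does not: mutation, selection,
crossover interference, recombination hotspots, phasing error, array
ascertainment, and reference-panel misspecification (the supervised
panels are the true source frequencies). Passing recovery tests on this
generator therefore demonstrates correctness of the estimators under
the model's assumptions, not robustness to the ways real cohort data
violate them.

`hessequa_preset()` encodes the study scenario: a San foundation with a
strongly male-biased East African pulse 32 generations before present
(93% male — the observed X/A ratios for this ancestry sit at or below
the all-male single-pulse floor, so the pulse is modeled near the male
extreme), and a colonial three-source pulse 6–7 generations back
(West African and Southeast Asian sex-balanced, European 80% male,
within the male-biased range reported for colonial European admixture).
Expected final fractions: ~34% San, ~3.3% East African, ~25% West
African, ~26% European, ~12% Southeast Asian; EAF X/A ≈ 0.78,
San X/A ≈ 1.13. The preset recommends a mating pool of 20,000: at a
pool of 2,000 the X-linked content of a 3% component drifts over 32
generations with an SD comparable to the bootstrap SD of the ratio
itself (measured across seeds), which would confound the sex-bias
signature the preset exists to demonstrate; 20,000 is modest for human
groups on this timescale and brings that drift to a few percent.

## Uniparental tallies

`assign_ancestry()` maps haplogroup names to continental ancestries by
longest string prefix (`default_haplogroup_map()` ships the cohort's
assignments: L0d and Y-A1b San; mtDNA L4b/L5a and Y-E1b1b East African;
L0a/L1b/L2a/L3d/L3e and Y-E1b1a West African; B/E/M/U7a Asian; H/J and
Y-R/I European; U2a1a unclassified). Plain prefixes are sufficient for
continental bins but cannot express within-clade exceptions beyond
longer prefixes — a documented limitation; no phylotree traversal is
attempted. `tally_haplogroups()` uses the full call count of a marker
system as denominator, keeps fractions as exact rationals, and rounds
percentages half-up to one decimal only for presentation. The bundled
`hessequa_haplogroups_synthetic.tsv` is a synthetic per-individual
reconstruction from published summary counts; the published counts for
two minor categories (West African, Asian mtDNA) do not reconcile with
the stated denominator of 87 (they sum to 88 and match percentages near
86), so the reconstruction preserves the total of 87 and the
acceptance-relevant categories (58 San-lineage, 2 East African,
2 European mtDNA; 4 San and 5 East African of 58 Y) at the cost of one
West African individual; derived West African/Asian percentages differ
accordingly from the published ones.

## Pipeline, determinism and problem sizes

`run_pipeline()` chains sim → qc → admix → xa → date → uniparental →
popstats from a single config (list or YAML), fans one top-level seed
out to per-stage seeds by fixed offsets, writes per-stage TSV tables plus
a checksum manifest of the product tables, and is byte-reproducible
under a fixed config (tested by comparing manifests of two runs).

Problem sizes used in the shipped tests and acceptance script, chosen
as the smallest at which the statistical properties are comfortably
resolved: X/A recovery at 500 individuals and ~20,000 SNPs over
chromosomes 1–7, 10, 12 and X; date recovery at 100 diploids (200
haplotypes) × 35 chromosomes of 180 cM with a pulse 30 generations
back, 20 replicate seeds, 100 bootstrap resamples; unit tests run on
cohorts of 40–500 with hundreds of SNPs. The full suite and the
acceptance script each run in minutes on a single core.

## Known limitations

* The local-ancestry caller is a windowed argmax, adequate for
  well-separated panels at the simulated densities; it is not a
  substitute for HMM-based callers on real, noisily phased data.
* Single-pulse algebra underlies `infer_sex_fractions()`; continuous or
  multi-pulse sex-ratio models are out of scope beyond the floor and
  ceiling flags.
* Unsupervised K=2+ fits on a *homogeneous* admixed cohort without
  source-pure individuals are weakly identified — a property of the
  model, not the optimizer; supervised estimation is the primary path.
* The exact HWE filter applies to diploid autosomal calls; male X calls
  never enter it.
* Percent agreement of bootstrap SDs with across-replicate SDs was
  verified in the regimes exercised here; for very small ancestry
  components over long histories the X's own drift exceeds what an
  individual bootstrap can see.
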