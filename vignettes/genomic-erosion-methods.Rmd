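---
title: "Methods: quantifying post-bottleneck genomic erosion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying post-bottleneck genomic erosion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`poperosion` implements the post-VCF stages of a population-genomic
erosion analysis for a small, formerly bottlenecked population: hard site
filtering and LD pruning, relatedness screening, diversity statistics,
runs of homozygosity (ROH) with inbreeding and age dating, drift-LD
effective-size estimation, and outgroup-polarized genetic-load
accounting.  Upstream read processing, mapping and variant calling are
out of scope: the package starts from called genotypes (a VCF or the
built-in simulator) and per-variant impact annotations produced by an
effect predictor.

The motivating setting is a wolf-like population that crashed to a few
tens of breeders roughly 12–18 generations before sampling and has since
recovered numerically.  Every default in the package describes that
world; all of them are plain function arguments.

# Site filtering and LD pruning

`filter_config()` reproduces the common VCFtools idiom: biallelic SNPs
only, minor-allele frequency ≥ 0.05 (computed on non-missing alleles),
≥ 90 % present calls, site QUAL ≥ 30, per-call depth ≥ 5 (masked to
missing *before* the missingness test — the masking order is not stated
by the conventions we follow, so we fixed and documented it), and mean
site depth ≥ 5.  Filtering is sequential and idempotent, and the report
attributes each removed site to the first criterion it failed.

`ld_prune()` deviates deliberately from the stepped window scan of the
`--indep-pairwise 10 5 0.5` tool dialect: a scan that advances by a fixed
number of sites cannot guarantee that *no* retained pair within a window
violates the r² ceiling, which is exactly the post-condition our test
suite (and any downstream analysis assuming pruned data) checks.  We
instead remove violating pairs globally — all same-chromosome pairs
closer than `window_kb`, processed in decreasing r² order, dropping the
lower-MAF member (ties: the larger position).  The result is
deterministic, step-independent, and satisfies the exhaustive
post-condition by construction.  `step_sites` is retained in the
configuration for interface compatibility.

# Relatedness screening

`pair_counts()` collects, over pairwise-complete sites, the opposite
homozygote count (IBS0), the double-heterozygote count, and each
member's heterozygote total.  From these, `king_phi()` computes the
KING-robust kinship `(n_hethet − 2·n_ibs0)/(n_het_i + n_het_j)`,
`king_r0()` the ratio `n_ibs0/n_hethet`, and `king_r1()` the ratio of
double-heterozygous to genotype-*discordant* sites
(`n_het_i + n_het_j − 2·n_hethet + n_ibs0`).

The R1 denominator deserves a note: with the discordance denominator a
true parent–offspring pair has expectation exactly 0.5 at every allele
frequency (double hets occur at rate `pq` and discordant genotypes at
rate `2pq` for such pairs), which is what makes the conventional
`R1 ≥ 0.5` screening threshold meaningful.  The superficially similar
"het-union" denominator (`n_het_i + n_het_j − n_hethet`) would put
parent–offspring pairs at 1/3 and defeat the threshold; we verified both
algebraically and on simulated pedigree pairs.

`flag_related()` flags a pair only when all three conditions hold
(φ ≥ 0.20, R0 ≤ 0.1, R1 ≥ 0.5) and emits an *advisory* flag when exactly
two hold — the borderline situation in which a cautious analyst may
still exclude an individual.  Flagged pairs are reported, never silently
dropped; exclusion is a pipeline toggle.

# Diversity

Observed heterozygosity is het calls over a caller-chosen denominator:
by default the sample's non-missing calls at the assessed sites, or an
externally supplied `callable_total` so that a variants-only table can be
normalized by a genome-wide callable-site count (whether a published Ho
denominator counts all sites or only QC-passing ones is usually
unstated; the argument makes the choice explicit).  Windowed nucleotide
diversity uses the unbiased per-site estimator
`2c(n−c)/(n(n−1))` summed over variant sites in non-overlapping 100 kb
windows and divided by the *full* window length — the convention of the
common windowed-π tools, in which monomorphic sequence dilutes π.  The
alternative (dividing by variant sites only) would inflate all values by
orders of magnitude; the choice is therefore documented rather than
configurable-by-accident.

# Runs of homozygosity

`call_roh()` is a window-based caller in the PLINK `--homozyg` family,
implemented from its documented definitions: 50-SNP windows are accepted
when they contain ≤ 1 heterozygous and ≤ 5 missing calls; a SNP is
ROH-eligible when at least 5 % of the windows *actually covering it*
are accepted (ends of chromosomes have fewer covering windows, not
phantom ones); maximal eligible runs are split at inter-SNP gaps above
1 Mb and then reported if they are ≥ 100 kb long, contain ≥ 100 SNPs and
average ≤ 50 kb per SNP.  Segment endpoints are the outermost eligible
SNP positions.  The test suite holds the caller to an independent
literal-definition reimplementation on hundreds of randomized fixtures.
Note the "100 kb" parameter is a *minimum segment length*, not a window
size, matching the actual semantics of the flag it mirrors.

`summarize_roh()` reports NROH, SROH, `FROH = SROH / genome_length`
(default genome length 2,222,501,653 bp, the autosomal total covered by
SNPs in the canid reference context this package was written for), and
the short (100 kb–1 Mb) / intermediate (1–10 Mb) / long (> 10 Mb)
decomposition.  Because both published class bounds are written with
strict inequalities, a segment of exactly 1 Mb or 10 Mb is ambiguous; we
assign boundary lengths to the longer class.

ROH age dating uses the expected IBD-length relation `L = 100/(2t)` cM
with a constant recombination map (default 1.3459 cM/Mb, the canid
genome-wide average): `roh_age()` returns the unrounded time,
presentation rounding is the caller's.  `bottleneck_window_fraction()`
converts a bottleneck interval (plus five post-bottleneck generations,
during which the crash-era haplotypes are still being broken into
just-sub-crash lengths) into a length band and reports the pooled SROH
fraction inside it.  `generations_to_years()` anchors generations to
calendar years; a reference year of 2010 with 3–4-year generations
reproduces the usual mid-20th-century dating of the crash.

# Effective population size from drift LD

The published analyses behind this pipeline use GONE and currentNe; we
do not reimplement a genetic-algorithm fit or a neural-network
correction.  Instead the module provides the documented closed-form
relations those tools build on:

* `ne_unlinked()`: for unlinked (inter-chromosomal) loci,
  `E[r²] ≈ 1/(3Ne) + floor`, inverted as `Ne = 1/(3(r̄² − floor))`.
* `ne_trajectory()`: for loosely linked loci at recombination fraction
  `c`, the Sved relation `E[r²] ≈ 1/(1 + 4Ne c) + floor`, inverted per
  log-spaced `c` bin, with the time depth `t ≈ 1/(2c)` generations.

The *sampling floor* matters at small n.  The conventional correction is
`1/n`; but the exact null expectation of a squared Pearson correlation
between independent dosage vectors over n samples is `1/(n−1)` (the
permutation variance of r is exactly `1/(n−1)` for any data).  At n = 12
the difference (0.0076) exceeds the entire drift signal of a population
of 50 (0.0067), so the floor choice decides whether the estimator can
work at all in the regime this package targets.  Both corrections are
exposed (`correction = "1/n"` default for continuity with the classical
formula, `"1/(n-1)"` used by the pipeline and recommended below n ≈ 30);
simulation recovery of a true N = 50 from 12 individuals is part of the
acceptance suite and only succeeds with the exact floor.  Residual
small-sample attenuation of the drift component (order `2/n`) remains
un-corrected; estimates at n ≈ 12 are accurate to a few tens of percent,
which is the honest resolution of desk-scale drift LD.

# Genetic load

`polarize()` assigns ancestral/derived states from up to two outgroup
allele calls with the rule hierarchy: agreement → that allele; a single
usable outgroup → its allele; a ref/alt split → a seeded random
tie-break (tagged `tie_random`, one RNG draw consumed per site so the
tie pattern cannot shift other sites' picks); nothing usable →
`unresolved`, dropped.  This is a behavioural stand-in for
maximum-likelihood unfolded-SFS polarization, which reduces, after its
probability maximization, to exactly "take the most probable state,
break ties at random".  Confidence tags keep the simplification
auditable.  `orient_derived()` then retains only sites whose derived
state is the alternate allele, so dosage counts derived copies directly.

`classify_impact()` maps impact strings to load categories, splitting
MODERATE on the SIFT score at 0.05 (≥ 0.05 tolerated, < 0.05
deleterious; the boundary value is tolerated, matching the published
inclusive inequality).  `load_counts()` tabulates per individual and
category the heterozygous (masked), derived-homozygous (realized) and
total genotype counts plus the derived-allele frequency
`(masked + 2·realized)/(2·callable)`; missing calls leave both the
numerator and denominator.  `masked + realized = total` holds exactly by
construction and is asserted on every run.  `compare_groups()` provides
the exact two-tailed Mann–Whitney test by full enumeration over midranks
(the small-sample regime of the published group comparisons); above
2×10⁶ assignments it errors rather than silently approximating.

# The synthetic world

`simulate_population()` is a forward-in-time diploid Wright–Fisher
simulator: viability selection with dominance, random mating (two
distinct parents per offspring), per-generation Poisson crossovers at
the constant recombination rate, infinite-sites mutation, arbitrary
stepwise Ne trajectories, two diverged outgroup lineages, and appended
parent–offspring pairs with recorded truth.  Standing variation is
initialized at equilibrium — neutral sites from the 1/i frequency
spectrum, selected sites down-weighted by the stationary-density factor
`exp(−4Nhs p)` — and a burn-in (default `min(2N, 150)` generations)
lets the LD structure build.  Initializing *selected* sites neutrally
instead produces an enormous opening purge whose fitness variance
crashes the effective size several-fold and poisons every downstream
recovery test; this is the single most consequential numerical choice in
the module.

Desk scaling.  The default genome is 4 × 20 Mb and the default
per-bp mutation rate is inflated (2.5×10⁻⁷) so that ≥ 50 k segregating
sites exist at desk scale; the default trajectory (ancestral 100 →
crash to 25 at generations 18–12 → 30 since) is a scaled stand-in for
the study system's estimated history (ancestral ≈ 330, crash 12–18
generations ago, ≈ 25–30 since), whose pre-bottleneck parameters are
anyway only placeholders for recovery tests.  Two consequences of the
scaling matter and are handled explicitly:

* Inflated mutation deposits het sites *inside* IBD tracts
  (≈ 2 t μ per bp since a TMRCA t generations back), enough to defeat
  the ROH caller's one-het-per-window tolerance and fragment true IBD.
  Simulation worlds whose purpose is ROH structure therefore use a
  realistic 5×10⁻⁸ and accept sparser SNPs; diversity- and LD-oriented
  worlds keep the inflated rate.
* A 40–80 Mb genome supports only a few hundred independent LD blocks,
  so single-run LD-based Ne estimates carry large Monte-Carlo error;
  recovery criteria are therefore medians over ≥ 20 seeds.

What a green test does *not* establish: the simulator has no genotyping
error or missingness model beyond depth columns, no dog-admixture
component, no variable recombination map, and outgroups are single
haploid lineages rather than aligned genomes.  Conclusions about those
features of real data are outside what the synthetic world can license.

# Pipeline

`run_pipeline()` chains acquire → filter → kinship (optional relative
exclusion) → diversity ∥ ROH ∥ Ne ∥ load, with per-stage SNP sets: the
MAF filter applies to the kinship/LD/Ne set but not to the
diversity/ROH/load set, whose frequency spectra and homozygosity
structure it would distort (toggleable, since the per-analysis filter
matrix of any given study is a supplementary-material detail we do not
hard-code).  All randomness derives from the config seed; a rerun is
bit-identical, and the JSON manifest (versions, seed, config echo,
per-stage counts) suffices to reproduce any stage.

# Known limitations

* The Ne estimators are deliberately simple closed forms: no confidence
  intervals, no 200-generation trajectory fit; accuracy at n ≈ 12 is
  tens of percent.
* The exact Mann–Whitney enumeration is capped (~10 per group); larger
  groups need a normal approximation this package does not provide.
* The ROH caller is a faithful window-based implementation, not an HMM;
  its behaviour at SNP densities far below ~1 per 50 kb degrades with
  the density criterion itself.
* Polarization handles at most two outgroups and ignores outgroup
  heterozygosity.
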