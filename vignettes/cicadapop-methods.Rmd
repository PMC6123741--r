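---
title: "Methods: demographic inference and divergence scans for periodical cicada broods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: demographic inference and divergence scans for periodical cicada broods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cicadapop)
```

# The scientific setting

*Magicicada* periodical cicadas live 13 or 17 years underground and emerge
in synchronized broods. Three co-occurring species groups (Decim, Cassini,
Decula) each contain a 13-year and a 17-year species pair that diverged in
parallel. `cicadapop` implements the population-genomic machinery for
studying that divergence from transcriptome-derived SNPs: coalescent-based
demographic model comparison on the joint site-frequency spectrum (SFS),
introgression tests, and genome-scan statistics with simulation-calibrated
outlier thresholds. The four sampled broods are II and III (17-year) and
XIX and XXIII (13-year), with two diploid individuals per brood per
species.

# The structured-coalescent simulator

The engine (`coal_model()`, `build_model()`, C++ core) simulates
genealogies backward in time:

* within a deme of diploid effective size $N$, $k$ lineages coalesce at
  rate $k(k-1)/(4N)$ per generation;
* lineages migrate (backward) between demes at per-generation rates
  $m_{ij}$, supplied per epoch;
* at a divergence time, two demes merge into an ancestral deme with its
  own size.

Event scheduling is continuous-time (exponential waiting times,
Gillespie-style), with epochs delimited by the divergence times. All
randomness flows through R's RNG, so `set.seed()` makes every simulation
reproducible.

**The nine demographic models.** Three scenarios order the brood
divergences — S1 `((II,III),(XIX,XXIII))` (life cycles monophyletic), S2
`(II,(XXIII,(III,XIX)))` (geography first), S3 `(II,(III,(XIX,XXIII)))`
(13-year monophyletic, nested) — and each carries one of three gene-flow
patterns. With one current deme's size pinned via $\pi = 4N_e\mu$, the
free-parameter counts are:

* *none*: 3 divergence times + 3 current sizes + 3 ancestral sizes = **9**;
* *recent*: + 6 symmetric rates between the pairs of current demes = **15**;
* *past and recent*: + 4 ancestral-epoch rates = **19**.

The published table never prints which deme pairs carry "past" rates;
the 19 = 15 + 4 count forces exactly four. We assign them positionally:
after the first merge three demes coexist (3 pair rates `pm1..pm3`),
after the second merge two demes coexist (1 rate, `pm4`). "Recent" rates
stay active for a pair until either member merges. Migration rates are
symmetric throughout — the counts do not admit directional rates.

**Unlinked SNPs.** Low-mutation-rate SNP data follow the infinite-sites
distribution $P(\text{pattern } i) \propto E[L_i]$, the expected length of
branches subtending $i$ tips. Placing one mutation on each genealogy would
instead sample patterns as $E[L_i/L_{tot}]$ — trees are not size-biased by
their length — which visibly distorts the SFS at our sample sizes (the
singleton class of a folded $n = 8$ spectrum shifts from 0.441 to 0.461).
We therefore run a Poisson mutation process with a small per-tree
intensity (~0.2 expected sites, calibrated from a 50-tree warm-up):
each emitted site then has the exact marginal distribution, and almost all
sites come from distinct genealogies. Cross-validation against an
independent coalescent simulator (msprime, driven through Python in the
test suite) gives a total-variation distance on the folded joint SFS at
the Monte-Carlo noise floor (~0.02 at 10^5 sites).

**Linked loci.** One genealogy per locus (no intra-locus recombination;
transcript-scale loci), mutation count Poisson(total branch length × μ ×
length), infinite-sites placement on distinct positions; a locus whose
mutation count would exceed its length raises a saturation error rather
than silently recycling positions.

# The synthetic-data generator

`simulate_dataset()` is the package's study-conditions generator: 4 brood
demes × 2 diploids, locus lengths normal around 1627 bp (SD 25%, floored
at 300 bp, matching the transcript-cluster length distribution), unphased
genotypes with IUPAC ambiguity codes at heterozygous sites, and a
synonymous flag drawn per SNP at 0.68 (the complement of the genome-wide
non-synonymous proportion 0.32). `example_model()` fixes the default
history: S1 with a life-cycle split at 13,133 generations (~197 kya at 15
years/generation), within-cycle brood splits around 5,000 generations,
current sizes 20,000–25,000 diploids (π = 4N_eμ ≈ 1.2–1.5 × 10⁻³ at
μ = 1.53 × 10⁻⁸), ancestral sizes 10,000–15,000, and recent migration
strongest between the adjacent 13-year broods (N_eM ≈ 5) and weak
elsewhere (N_eM ≈ 0.6). These values were chosen once from the published
point estimates and range statements.

What the generator does *not* emulate: sequencing error, coverage-driven
missingness and quality filters (assumed applied upstream), intra-locus
recombination, selection, linkage between loci, and reading-frame
structure (the synonymous flag is a label, not an annotation). Tests that
pass on this generator therefore validate the estimators under neutral,
cleanly-filtered conditions — not robustness to artefacts of real RNA-seq
SNP calling.

# SFS construction and composite likelihood

`joint_folded_sfs()` counts alternate-allele copies per brood and folds on
the pooled minor allele; an exact 50/50 pooled tie takes the
lexicographically smaller of the entry and its complement (determinism).
Sites are excluded when monomorphic in-sample, when the pooled
minor-allele frequency is below `maf_min` (default 0.05 — the threshold is
taken as pooled rather than per-population; both the value and scope are
recorded in the object's provenance), when any used genotype is missing
(listwise deletion), or when not flagged synonymous.

`expected_sfs()` estimates a model's entry probabilities from `n_sim`
simulated SNPs under identical filters, excludes the monomorphic cell, and
floors unobserved canonical cells at ε = 0.1/`n_sim` before renormalising,
so `composite_loglik()` — `lnL = Σ m_i log p_i`, natural log — is always
finite. AIC = 2k − 2 lnL; Akaike weights follow from ΔAIC.

`fit_model()` maximises the simulated composite likelihood over any chosen
subset of parameters on the log10 scale. A fixed simulation seed per fit
(common random numbers) makes the surface deterministic, so one-parameter
fits use golden-section search and multi-parameter fits multi-start
Nelder–Mead. Parametric uncertainty comes from Poisson-bootstrap
replicates of the observed SFS, refitted with fresh simulation seeds so
the bootstrap spread includes the Monte-Carlo component of the estimate.

# Population-genetic statistics

Per-SNP F_st is the Weir–Cockerham (1984) θ from diploid dosages, with
variance components a (among populations), b (among individuals), c
(within individuals, from observed heterozygosity); negative estimates are
retained, monomorphic sites are undefined (NA, never 0). The locus-level
estimator is the ratio of summed components Σa/Σ(a+b+c) — not a mean of
ratios — and the maximum per-SNP value serves as the alternative locus
statistic. π and d_xy are per-site pairwise-difference means; Tajima's D
uses the standard 1989 constants.

Because the genotypes are unphased and loci carry few SNPs, phase-requiring
statistics (π, d_xy, Tajima's D) are computed by repeated random haplotype
sampling (RRHS): each replicate resolves every individual's heterozygous
sites independently at random into one pseudo-haplotype, and the estimate
is the mean over replicates (default 100). The cited strategy is ambiguous
about whether one or both complementary pseudo-haplotypes enter; we default
to one per individual and expose `two_haplotypes = TRUE` for the other
variant. F_st needs no phase and uses genotype frequencies directly.

# ABBA-BABA

`d_statistic()` uses the frequency (population-sample) form: per usable
site, derived-allele frequencies are taken relative to the outgroup major
allele (a 50/50 outgroup is dropped), ABBA = (1−p₁)p₂p₃ and
BABA = p₁(1−p₂)p₃, and D = Σ(ABBA−BABA)/Σ(ABBA+BABA). This handles
multi-individual operational taxa. `d_bootstrap()` resamples loci (the
natural exchangeable unit for transcript data), yielding SD, Z = |D|/SD
and the two-sided normal P = 2(1−Φ(Z)). The published table's footnote
maps its largest Z to a P that the normal two-sided formula does not
reproduce; we implement the standard formula and treat that mapping as
unresolvable.

Calibration note: in null simulations the locus-bootstrap SD runs a few
percent below the true sampling SD of D at small sample sizes (4 gene
copies per taxon), making the |Z| > 1.96 test mildly anticonservative
(empirical type-I error around 0.07 at ~10³ usable sites). This is a
small-sample property of the bootstrap-normal approximation; interpret
borderline Z scores accordingly.

# Outlier scans and the permutation test

Null distributions for the three statistics come from the fitted model:
10,000 unlinked SNPs (per-SNP F_st between pooled 13- and 17-year
groups), 5,000 linked 2500-bp loci (weighted F_st), and max-of-5 draws
from the SNP null (group size 5 follows the original choice and is
configurable, since nothing pins it). The 95% empirical quantile defines
"divergent"; calls are strictly greater-than, and undefined values are
never flagged. Shared outliers between two comparisons are counted over
the items testable in both; significance uses a permutation test that
redraws both outlier sets uniformly with fixed counts,
P = (1 + #{perm ≥ obs})/(1 + n_perm) — the add-one rule avoids reporting
zero at finite permutation counts, and the scheme converges to the
hypergeometric tail.

# The time-dependent rate curve

Apparent substitution rates decay with measurement timescale. From a table
of dated nodes (height in substitutions/site, age in million years),
`node_rates()` converts to per-generation rates using a 15-year generation
time (the 13/17 average), and `fit_rate_curve()` fits
Rate(t) = μ·exp(−λt) + k by bounded non-linear least squares on the raw
rate scale (per site per million generations, t in million years),
multi-start from (max−min rate, 1/median age, min rate). A closed-form
flat fit (μ = 0, k = mean rate) backstops the degenerate constant-rate
limit where the exponential model is singular. Rate(0) = μ + k gives the
instantaneous mutation rate; with the published parameters this is 0.0153
per million generations = 1.53 × 10⁻⁸ per generation, the value that
scales all demographic models.

# Numerical and design choices

* Coordinates are VCF-style 1-based; site keys are (locus, position).
* Missing genotypes: listwise per-site deletion everywhere that counts
  alleles; statistics that cannot be computed propagate NA.
* ε floor 0.1/n_sim on expected SFS entries (configurable); the original
  likelihood machinery uses an unpublished small floor.
* Which deme's size multiplies m in N_eM is not documented in the source
  material; `gene_flow_estimates()` reports N of the canonical first pair
  member and labels it.
* Pipeline seeds: `run_pipeline()` derives one sub-seed per stage from the
  root seed by fixed offsets and records them in `provenance.json`.
* Terminal masked bases (N) in alignments are treated as missing, like any
  other missing character.

# Problem sizes in the test suite

The validation suite runs at desk scale, chosen to keep each property
sharp while remaining quick: 2,000–2,500 loci for Watterson/π/Tajima
expectations; 60,000 SNPs for SFS-shape checks; 120,000 SNPs against the
external simulator; 20 replicates for divergence-time recovery (10,000-SNP
observed SFS, 2,000-SNP expected-SFS evaluations, 14 bootstrap refits) and
for scenario selection; 10,000/2,000/4,000 draws for the three outlier
nulls; 200 simulated datasets of 400 loci × 1000 bp for the D-statistic
type-I error; 100 replicates for noisy rate-curve recovery. The production-scale settings of
the original analysis (e.g. 100 bootstrap replicates, 5,000 locus
replicates) are the package defaults.

# Known limitations

* No intra-locus recombination and no linkage between loci; transcript
  data make the first mild and the second standard, but whole-genome use
  would need both revisited.
* The composite likelihood treats SNPs as independent; its AIC comparisons
  are heuristic in the usual way for SFS methods.
* Sample sizes here are tiny (4 gene copies per deme); Weir–Cockerham
  estimates at single SNPs are accordingly noisy, which is why locus-level
  and simulation-calibrated summaries carry the inference.
* The simulator supports instantaneous size changes at divergence events
  only (no continuous growth), matching the fitted model families.
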