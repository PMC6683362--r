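---
title: "Methods: ploidy and hybridogenetic structure from genomic and microsatellite data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ploidy and hybridogenetic structure from genomic and microsatellite data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological problem

The edible frog *Pelophylax* kl. *esculentus* is a hybridogenetic hybrid
between the pool frog *P. lessonae* (genomes LL) and the marsh frog
*P. ridibundus* (genomes RR). In the classic *lessonae–esculentus* (L-E)
system, diploid LR hybrids exclude their L genome from the germline,
transmit the R genome clonally, and must backcross with *P. lessonae* to
persist. All-hybrid (E-E) assemblages instead sustain themselves, classically
through triploid LLR/LRR individuals. Field surveys of such systems therefore
hinge on a handful of genomic quantities: which markers separate the L and R
genomes, what ploidy each hybrid carries, how much heterozygosity each class
of frog shows, and what offspring each mating could produce.

`hybridogen` implements that toolkit as a pipeline of small, testable
stages, together with a cohort simulator that provides ground truth for
every stage.

## Diagnostic loci

A locus is *species-diagnostic* when the parental reference panels are fixed
for different alleles (allele-frequency difference of 1.0 between LL-type and
RR-type reference samples). `find_diagnostic_loci()` evaluates fixation on
non-missing reference genotypes only and requires at least `min_ref_called`
(default 3) called samples per group; how missing reference genotypes should
be treated is genuinely open, and the floor makes the choice explicit instead
of guessing. Hybrid and unlabelled samples are ignored during discovery —
they are what the panel is for. Panels are sorted by locus identifier so
reports are reproducible, and by default only biallelic sites are admitted,
matching SNP-matrix practice; multiallelic sites can be admitted when the
two reference groups are each fixed for distinct alleles.

## Ploidy from allele depths

At a diagnostic locus a hybrid's two alleles mark its two genomes, so their
sequencing depths estimate genome dosage. With total depth $n$ and an
L-genome dosage proportion $p_L$ (1/2 in LR, 2/3 in LLR, 1/3 in LRR), the
L-allele depth is $\mathrm{Binomial}(n, p_L)$ up to sequencing error. Three
statistics summarize an individual (`individual_dosage_profile()`):

* `mean_ratio` — the arithmetic mean over loci of
  $\max(d_L, d_R) / \min(d_L, d_R)$, the statistic this field reports.
  It tends to 1 in diploids and 2 in triploids, but at finite depth the
  folding inflates it above 1 (at depth 100 per locus a true diploid
  averages about 1.17 per locus).
* `pooled_ratio` — the same ratio on depths summed over loci; much lower
  variance, still folded (a diploid at 376 loci of depth 100 sits near
  1.008, not exactly 1).
* `mean_log2_LR` — the mean of $\log_2(d_L / d_R)$; its sign orients a
  triploid call (LLR positive, LRR negative).

Because the published per-locus mean could average loci within individuals
or pool all locus ratios, the per-locus detail is retained in the profile so
either ordering can be recomputed.

Loci enter a profile only when the call contains both panel alleles and both
depths reach `min_depth_per_allele` (default 3): a heterozygote with a
zero-depth allele is indistinguishable from allelic dropout, so such loci
are excluded rather than imputed. Depths are used raw — no cross-locus
normalization — matching the direct use of coverage this method relies on.

`classify_ploidy()` calls `DIPLOID_LR` when `mean_ratio <= 1.4` and a
triploid class when `mean_ratio >= 1.7`, leaving an `UNDETERMINED` band in
between: observed diploids span roughly 1.0–1.3 while the triploid
expectation is 2, and the band avoids forcing borderline calls. Profiles
with fewer than `min_loci` (default 20) usable loci are never classified.
These thresholds are working constants of this package, not published
values.

`dosage_likelihood_call()` is the model-based companion: per-class binomial
log-likelihoods at $p_L \in \{1/2, 2/3, 1/3\}$, adjusted for a symmetric
per-read error $\varepsilon$ as $p' = p(1-\varepsilon) + (1-p)\varepsilon$.
It is far more sensitive at low depth (the ratio heuristic needs roughly
depth 50 before its band separates the classes; the likelihood call
separates them reliably at depth 20 with 300 loci), and is reported
alongside the heuristic call without overriding it.

## Microsatellite peak-height ratios

At co-amplifying microsatellites with L- and R-specific alleles, a genome
present in double copy roughly doubles its peak. `compute_phr()` quantifies
this as $\mathrm{PHR} = \log_{10}(H_R / H_L)$ when exactly one L-specific
and one R-specific peak are visible. The logarithm base is configurable but
defaults to 10, which puts the pure copy-number-2 signal at
$\pm\log_{10} 2 \approx \pm 0.301$, commensurate with the published
calibration ranges the classifier ships
(`phr_calibration()`; diploid LR $[-0.23, 0.00]$, LLR mean $-0.39$ in
$[-0.54, -0.29]$, LRR mean $0.17$ in $[0.09, 0.25]$ at the RICA1b5-analogous
genotype, applied to the 122/137 and 123/137 profiles). Calibration is
genotype-specific because amplification efficiency varies with allele size
and priming mismatches; whether a published calibration transfers exactly to
neighbouring alleles is surfaced as a configuration choice (supply your own
TSV), not an assumption.

Patterns that cannot be quantified are flagged instead: a single visible
peak may hide a null allele, three or more peaks indicate a triploid
(`detect_triallelic()`), and two same-genome peaks cannot be oriented.
Ranges are closed, validated to be pairwise disjoint at load time, and a
value outside every range classifies `OUT_OF_RANGE`.

## Population summaries

`observed_heterozygosity()` averages per-individual heterozygosity
(heterozygous called loci / called loci) within `(population, taxon)` groups
of at least `min_n = 5` individuals, omitting smaller groups with an
explicit note. The default scope is genome-wide (all loci), with a `loci`
argument for panel-restricted summaries; both scopes are explicit because a
panel-restricted hybrid is heterozygous by construction. All called loci are
included, monomorphic or not — the inclusion choice is documented here
because conventions differ.

`hybrid_index()` classifies individuals from the fractions of called panel
loci that are L/R-heterozygous, homozygous-L, or homozygous-R, with
thresholds `pure_min = het_min = 0.9`. It is a deliberately transparent
stand-in for Bayesian ancestry clustering — sufficient here because
diagnostic loci are fixed between the parental genomes, so a diploid hybrid
is heterozygous at essentially all of them and parentals at almost none.
The 0.9 thresholds tolerate genotyping error and missing data while keeping
the classes unambiguous; they are package constants, not estimates.

## The cross model

Genome copies carry their lineage and a sex chromosome (`Lx`, `Ly`, `Rx`).
Under the default model the R genome is strictly X-linked — primary
hybridizations involve L-lineage males and R-lineage females — so hybrid
males are `LyRx` and hybrid females `LxRx`; sex is male iff any Y is
present. The validator can be relaxed (`allow_Ry = TRUE`) for hypothetical
scenarios, and says so when it is.

Gametogenesis modes: genome exclusion (`ELIMINATE_L` / `ELIMINATE_R`),
Mendelian segregation for same-lineage diploids, unreduced `DIPLOID_LR`
eggs, a per-composition triploid table (recombined haploids and/or
unreduced diploid gametes — kept configurable because several behaviours
are documented across systems), and `AMPHI`: hybrid amphigamy, transmitting
L with probability `q` and R otherwise. `q` defaults to 0.5 as the minimal
symmetric assumption — nothing quantifies it empirically — and is a
first-class parameter so mixtures of L- and R-eliminating lineages
(`q` of 0 or 1 per individual) can be expressed with the same machinery.
Whether a female alternates genomes between clutches or among the germ
cells of one clutch reduces to the same marginal gamete distribution, so
the model does not distinguish the two.

`cross()` multiplies the parents' gamete distributions and reports the
offspring distribution before and after viability weighting. Homotypic
offspring built from hemiclonal genomes (RR in an L-E system, both LL and
RR in all-hybrid systems) carry the accumulated load of clonal transmission
and default to viability 0. In the `L_E` preset the parental species LL is
the sexual host of the system and keeps viability 1 (and symmetrically RR
under `R_E`): the load attaches to hemiclone-derived homotypes, not to the
sexually reproducing host — zeroing both would extinguish the host in the
generation recursion and contradict the system the preset names. Weights
are overridable, e.g. to small positive values to model the occasional
surviving RR adults all-hybrid systems produce.

`iterate_generations()` extends single crosses to a deterministic
genotype-frequency recursion under random mating within sexes — an
extension for studying system closure (no drift, no ecology, no mate
choice).

## The simulator

`simulate_cohort()` generates what the analysis assumes and nothing more:
fixed diagnostic loci; multinomial allele depths under class dosage with
negative-binomial (default, dispersion 5 at mean 20 — RAD libraries are
overdispersed; `"poisson"` is the equi-dispersed option) total depth;
symmetric cross-allele error at diagnostic loci only; a scalar residual
heterozygosity for the near-clonal LL/RR classes (default 0.01, the scale
of observed hemiclone diversity) versus `hybrid_het = 0.2` for hybrids
(the scale of observed genome-wide hybrid heterozygosity); and uniform
missingness (default 0.1). Genotype calls derive from the true genome
composition — heterozygous iff both genomes contribute — so the error rate
perturbs depths only, as with a caller that does not call alleles on stray
reads. Triploids are diploid-coded by default (as real SNP callers emit);
`ploidy_coding = "true"` writes the full allele multiset so truth files
round-trip.

What the simulator does *not* model, and what passing tests therefore do
not show about real data: linkage and LD, locus-specific depth biases,
batch/library effects, allelic dropout correlated with allele length,
reference bias, or a coalescent within classes. The heterozygosity contrast
is a single scalar, not a demographic model. Parameter-recovery results on
these cohorts demonstrate internal consistency of the statistics, not field
performance.

`simulate_peak_table()` mirrors the microsatellite side:
$H = \mathrm{base} \times e_a \times \mathrm{copies} \times
e^{\mathcal{N}(0, \sigma^2)}$, with per-allele efficiencies, lognormal
noise, and null alleles dropping records entirely (absent peaks are absent
rows, never zeros).

## Numerical and validation choices

Problem sizes used by the test-suite simulations were chosen to keep each
check sharp at desk scale: depth $10^4$ cohorts for law-of-large-numbers
checks (pooled ratios within 0.02 of their limits), depth-100 cohorts of
376 diagnostic loci for the coverage-ratio expectations, a 100-individual
five-class cohort at depth 20 with 300 diagnostic loci for joint
parameter recovery, and 200 random small matrices for oracle equivalence
of panel discovery against a brute-force frequency scan.

One caveat the profile statistics make visible: because `max/min` folds
sampling noise upward, the pooled diploid ratio converges to 1 only as
total depth grows without bound; at 376 loci × depth 100 its expectation is
about $1 + 4\,E|\hat p - 1/2| \approx 1.008$, which still rounds to 1.01 at
two decimals. The folding bias is a property of the statistic, not a bug,
and is why the likelihood call exists.

Determinism: all simulators take integer seeds and restore the caller's RNG
state; the pipeline writes byte-identical reports on reruns (headers carry
the tool version, seed, and a hash of the analysis parameters, never
timestamps).

## Known limitations

* The hybrid index is not an admixture estimator; individuals with partial
  panels or unusual ancestry classify `AMBIGUOUS` rather than receiving a
  posterior.
* PHR classification is only as good as its calibration; the shipped ranges
  apply to one marker and two genotypes, and new genotypes need new ranges.
* The dosage model assumes the panel is truly fixed; introgressed or
  paralogous loci violate the binomial model silently (the min-depth filter
  does not catch them).
* The cross model tracks genotype frequencies only: no ecology, no
  selection beyond class-level viability, no estimation of `q` from data.
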