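---
title: "Models and methods behind pigdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pigdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

pigdiv estimates within- and between-population genetic diversity from
SNP-array genotypes and pedigrees. This vignette explains the statistical
models, the parameters that matter, the choices made where the design was
genuinely open, and what the synthetic-data generator does and does not
establish. No empirical claim is made here that the test suite does not
itself compute.

## Data model and quality control

Genotypes live in a samples × SNPs matrix of A1-allele dosages
(0/1/2/missing), with SNPs sorted by (chromosome, position) and
coordinates 1-based inclusive throughout (the PLINK convention; BED export
converts to 0-based half-open on write). Two QC profiles are first-class:

* **inbreeding** profile — sample call rate ≥ 0.90, heterozygosity within
  3 SD, duplicates removed (concordance > 0.99 over co-called SNPs; the
  lower-call-rate member of each pair is dropped), unknown-position and
  sex-chromosome SNPs removed, SNP call rate ≥ 0.90. No MAF or
  Hardy–Weinberg filter: monomorphic and low-MAF SNPs are informative for
  homozygosity.
* **ld** profile — applied within population: SNP call rate ≥ 0.98,
  MAF ≥ 0.03, HWE exact p ≥ 1e-6. Within-population application avoids
  penalising SNPs fixed in only one breed.

All thresholds are strict inequalities: a sample at exactly 0.90 call rate
or a SNP at exactly MAF 0.03 is retained. The heterozygosity rule is
one-sided ("higher than" the mean + 3 SD) by default with a two-sided
switch, since excess heterozygosity indicates contamination while deficit
may be real inbreeding.

The Hardy–Weinberg test is the exact conditional test: given the allele
counts, the probability of each compatible heterozygote count follows the
Levene/Haldane distribution, and the two-sided p-value sums the
probabilities not exceeding that of the observed count (standard, not
mid-p). A recurrence over heterozygote counts keeps it stable to n in the
thousands; the suite checks it against full enumeration to 1e-12.

Pedigree verification uses method-of-moments IBD: per pair, IBS counts are
combined with allele frequencies to estimate P(IBD = 0, 1, 2), and
PI_HAT = P(IBD=2) + P(IBD=1)/2. Recorded parent–offspring pairs deviating
from 0.5 by more than 0.15 are flagged. No small-sample correction is
applied to the expected-IBS terms, so frequencies should come from a
reasonably large, not-too-related sample. Sex checks compute an
inbreeding-style F from X-chromosome homozygosity with expected
homozygosity from allele frequencies estimated in declared females only
(males are hemizygous and typed as homozygous, which would bias pooled
frequencies).

## Inbreeding estimators

**Pedigree (F_x).** F is the diagonal of the additive relationship matrix
minus one. It is computed per animal as half the kinship of its parents by
ancestor tracing with the A = TDT' decomposition (the tabular method in
topological order), which is exact and avoids materialising the full
matrix. Unknown parents define base animals, assumed unrelated and
non-inbred — the standard assumption, and the reason pedigree estimates
undershoot genomic ones when base-population inbreeding is unknown.
Pedigree depth is reported as *equivalent complete generations*
(Σ over known ancestors of (1/2)^g), plus a simple maximum-generation
count; the literature's "average depth" statistic is ambiguous between the
two, so both are emitted and neither is asserted against published values.

**ROH (F_ROH).** A run of homozygosity is defined here as a maximal run of
consecutive autosomal SNPs such that every window of 50 SNPs lying wholly
inside the run has ≤ 1 heterozygous and ≤ 1 missing call; runs below
50 SNPs or 1000 kb are discarded. The definition is deliberately *not*
PLINK's proportion-of-overlapping-windows algorithm: the published
parameter set (window size, het/missing allowances, minimum SNPs and
length) does not pin down PLINK's internal overlap threshold, whereas the
every-interior-window rule is fully specified by those parameters and can
be tested against a brute-force checker that examines every candidate
(start, end) pair. One subtlety: two maximal valid runs can overlap across
a dirty stretch; since segments of one sample must not overlap, the later
run is trimmed to start after the earlier one ends (a sub-run of a valid
run is always valid). This left-greedy rule is deterministic and shared by
implementation and oracle. F_ROH divides each animal's summed ROH length
by the total autosomal genome length, default L = 2,808,525 kb
(Sscrofa10.2); for simulated data L is the simulated genome length.

**SNP-by-SNP (F_SNP).** The observed proportion of homozygous genotypes
(equivalently 1 − observed heterozygosity). It counts identity-by-state,
so it runs on a different scale from F_x and F_ROH (typically ~0.6–0.7 on
real pig data) and is compared to them only through correlations.

## Linkage disequilibrium from unphased genotypes

The original workflow phased and imputed with external software; pigdiv
instead estimates two-locus haplotype frequencies directly from unphased
genotypes by maximum likelihood (EM), with pairwise deletion of missing
calls. Only the double-heterozygote class is phase-ambiguous; EM iterates
its cis/trans split to convergence (max frequency change < 1e-10, cap
1000 iterations). Because the LE starting point is a fixed point of the
symmetric double-root likelihood and local maxima exist for extreme
tables, the EM restarts from both ends of the admissible p_AB range and
keeps the best likelihood, breaking exact ties toward D ≥ 0 (flagged).
The suite verifies the EM against a 999-point grid search over the single
free parameter; the grid is valid because EM preserves the observed allele
frequencies as margins. From the haplotype frequencies,
D = p_AB − p_A p_B, r = D/√(p_A p_a p_B p_b), r² = r².

What a green EM test does *not* establish: for pairs with r ≈ 0 the
double-heterozygote split carries no phase information, so the EM estimate
of r has roughly twice the variance of phased counting (1/n vs 1/(2n) for
n diploids). This is an information floor, not an implementation defect;
the phased-vs-EM concordance test is therefore run on pairs with |r| ≥ 0.4
where phase is identified, and the finite-sample inflation of r² feeds the
Ne correction below.

LD decay groups within-chromosome pairs into 100-kb classes from 0 to
10 Mb ([lo, hi) half-open; a pair at exactly 100 kb falls in the second
bin) and summarises each class as the unweighted mean of per-chromosome
means — not the pooled-pair mean, which is also emitted for diagnostics.
Adjacent-SNP LD reports the mean r² over informative consecutive pairs and
the fractions strictly above 0.2 and 0.3; thinning keeps every 10th SNP
per chromosome before recomputing, mimicking a low-density panel.

The correlation of linkage phase correlates, across SNP pairs present in
both populations after within-population QC, the signed r of population 1
with that of population 2, per distance class, after harmonising each
SNP's A1 between datasets (an unharmonised A1/A2 swap at one locus of a
pair flips the sign of r). The headline value uses a dedicated 0–50 kb
window. Pairs monomorphic in either population are excluded.

## Effective population size

Sved's drift–recombination relationship E(r²) = 1/(4cNe + 1) is inverted
as Ne_t = (1 − r²)/(4cr²) for 0 < r² < 1, with c in Morgan obtained from
physical distance at 1 cM ≈ 1 Mb, and t = 1/(2c) generations in the past.
The generation grid is t = 1..10 by 1, 15..100 by 5, 150..1000 by 50. The
c-window probing generation t spans (1/(2t_hi), 1/(2t_lo)] where t_lo and
t_hi are midpoints to the neighbouring grid values (endpoints use t/2 and
t + (t − t_prev)/2); this generalises the single worked example — t = 1
selects c in (1/3, 1] Morgan — into an explicit rule and makes the windows
tile the c-axis without overlap. Within a window, r² is averaged per
chromosome then across chromosomes (the same rule as LD decay), pairs with
r² exactly 0 or 1 are excluded per the estimator's domain, and the
representative distance is c = 1/(2t) (the window's defining relationship;
the mean pair distance is available as an alternative).

**Finite-sample correction.** Raw r̂² from n diploids is inflated by
sampling noise even at linkage equilibrium. Calibration on independent
locus pairs (true r = 0, n = 100) measured the inflation of the EM
estimator at ≈ 1/n — twice the 1/(2n) appropriate for phased haplotype
counts, consistent with phase uncertainty doubling the sampling variance
of D. The optional `sample_size` correction therefore subtracts 1/n from
each window mean before inversion; it is off by default (matching the
published workflow, which applied none) and enabled where Ne must be
recovered quantitatively from modest samples: without it, recent-Ne
estimates at n = 100 are biased ~40% low because the true r² signal at
c ~ 0.5 Morgan (≈ 0.005 for Ne = 100) is the same size as the noise floor.
A residual downward bias at the largest c remains because the Sved model
is written in recombination fraction while a Poisson crossover process
gives θ = (1 − e^(−2c))/2 < c (Haldane); this affects t = 1–2 most and is
a property of the method, not of the implementation.

## The synthetic-data generator

The simulator is a forward Wright–Fisher diploid model: founders carry 2N
distinct haplotype labels with SNP alleles drawn per SNP from a uniform
MAF sampler (default U(0.05, 0.5)); each offspring draws parents under
random monogamous (pairing without replacement) or polygamous mating; each
gamete recombines with Poisson(chromosome length in Morgan) crossovers at
uniform positions, without interference. SNPs are equally spaced and
physical positions follow 1 Morgan = 100 Mb, consistent with the Ne
module's 1 cM/Mb default. Founder sexes alternate; later sexes are random
with both sexes guaranteed. A split specification divides the population
at a chosen generation into two isolated daughters sharing one pedigree.
Missingness and genotype errors are injected independently per call.

Defaults emulate the motivating study design at desk scale: recent N in the
tens to low hundreds, ~10 autosomes, thousands of SNPs per chromosome.
Founder labels are tracked at SNP resolution per gamete; mosaic intervals
are reconstructed with boundaries at the genetic midpoints between
adjacent SNPs, which tile each chromosome exactly. At default densities
(≥ 500 SNPs/Morgan) the discretisation error in true autozygosity is below
1e-3 — negligible against the sampling noise of any estimator under test —
and this representation makes a gamete two vectorised copies rather than
an interval merge, which is what keeps the acceptance-scale simulations
(N = 100, 40 generations, 20k SNPs) in tens of seconds.

What the simulator does not emulate: mutation, selection, non-random
mating by merit, crossover interference, X chromosomes (sex-check fixtures
are constructed directly), array genotyping artefacts beyond uniform
missingness/error, and real marker ascertainment. A green simulation test
therefore establishes correctness of the estimators under drift,
recombination and finite sampling — not robustness to ascertainment bias
or selection.

## Numerical and determinism choices

* Every stochastic step (simulation, pair subsampling) derives from an
  explicit seed and restores the caller's RNG state; pipeline reruns are
  byte-identical, which the suite asserts via checksums.
* EM convergence 1e-10 on frequencies; batch and single-pair EM may stop
  one iterate apart, so cross-checks compare at 1e-7.
* Ties: EM double roots resolve to D ≥ 0; duplicate-sample removal drops
  the lower-call-rate member; ROH overlap resolution is left-greedy.
* Degenerate inputs fail loudly: QC removing all samples or SNPs, empty
  generation grids, r² outside (0,1) at inversion, totals exceeding the
  genome length, cyclic pedigrees, and named-but-unrecorded parents are
  all errors, not warnings.
* Dense-map pair enumeration is capped (`max_pairs_per_window`,
  `max_pairs_per_chrom`) with seeded uniform subsampling; caps only bound
  runtime and do not bias window means.

## Known limitations

* No confidence intervals on Ne (block jackknife noted as future work);
  no mutation or α-style adjustment of the Sved formula.
* Shared-ROH "overlap" mode clusters by single linkage, so a chain of
  pairwise-overlapping segments forms one region whose span is the cluster
  union; exact-coordinate mode is the default.
* The IBD moment estimator assumes approximately unrelated frequency
  sources; within small, deeply related herds PI_HAT is biased and only
  the parent–offspring flagging contract is asserted.
* Pedigree F computation is exact but O(ancestors²) per animal; for herds
  beyond ~10⁴ animals a dedicated sparse implementation would be
  preferable.
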