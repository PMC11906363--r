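---
title: "Detecting somatic second hits in normal tissues: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting somatic second hits in normal tissues: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In a recessive cancer-predisposition syndrome one allele of a tumor
suppressor — here the motivating case is *NF1* in neurofibromatosis type 1 —
is inactivated in the germline, and neoplasia classically requires a somatic
"second hit" on the remaining allele. The question this package's workflow
addresses is whether such second hits also accumulate in histologically
*normal* tissues, which requires detecting very small clones (cell fractions
of a few percent) of three kinds: point mutations, copy-neutral loss of
heterozygosity (CN-LOH), and single-copy deletions, against sequencing error
and low-level tumor contamination.

Every statistical stage is exercised against a synthetic cohort generator
with exactly known ground truth, so no patient data is needed to validate
the machinery.

# The synthetic cohort

`simulate_cohort()` builds one predisposed proband and two unaffected
controls from an explicit configuration (`default_cohort_config()`):

* **Lineage.** Each individual is a cell genealogy with an *explicit*
  topology (no random clone placement: ground truth must be exact) and
  Poisson(λ = 150) somatic substitutions per branch — a scale typical of
  childhood tissues where lineages carry a few hundred substitutions. A
  node's genotype is the union of the branch sets on its root path, so the
  number of mutations two samples share is exactly the branch-length sum of
  their common root path.
* **Proband.** A heterozygous germline truncating variant inside an
  NF1-sized footprint on chromosome 17; a tumor clone with
  whole-chromosome-17 CN-LOH retaining the *mutant* haplotype, plus 300
  extra truncal substitutions; and planted second-hit clones: a truncating
  point mutation (carried by three samples, two of which share a recent
  ancestor), CN-LOH clones at cell fractions 0.13 and 0.02 losing the
  wild-type haplotype, a CN-LOH clone at 0.10 losing the *mutant* haplotype
  (the germ-layer curiosity the LOH caller must report as `mutant_loss`),
  and a one-copy deletion clone at 0.15. The 2–56% range matches the clone
  sizes the method is meant to resolve.
* **Reads.** Depth is Poisson(`target_depth`, default 30× for
  microdissections, 40× for the bulk tumor); alt reads are
  Binomial(depth, v) with `v = vaf(1−e) + (1−vaf)e/3`. The e/3 convention
  — an error lands on one specific alternative base uniformly over the
  three non-reference bases — matches the per-allele framing of the
  downstream Fisher tests. Default e = 10⁻³ per base.
* **Contamination.** Two normal samples carry 0.5% tumor contamination
  (below the 1% purity gate) and one carries 5% (which the gate must
  exclude). The contaminating fraction across samples is not something the
  study design pins down; these values were chosen once as a realistic
  sub-percent level plus one clear violation, and are part of the fixed
  study conditions.
* **Duplex bundles.** `emit_duplex_reads()` samples molecules per site
  (each molecule is one chromosome copy, so a molecule carries a variant
  with probability equal to the allele dosage), and emits one row per
  strand. A true variant sits on both strands; single-strand errors are
  independent per strand, so a concordant false call needs two matching
  errors — probability (e/3)² per molecule at one read per strand.

Reproducibility is strict: one master seed, per-stage child seeds via
`derive_seed()`, identical `(config, seed)` gives byte-identical output.

What the generator does *not* emulate: mapping artifacts, strand bias,
GC-dependent coverage, indel errors, subclonal copy-number complexity, and
barcode clashes in duplex data. Passing tests therefore demonstrate the
statistical machinery is calibrated under its stated model, not that the
pipeline is robust to alignment-level artifacts.

# Tumor contamination from truncal mutations

At a diploid-heterozygous truncal site, tumor cells at fraction *t*
contribute expected VAF *t*/2, so `estimate_purity()` pools reads over all
truncal sites and doubles the aggregate VAF, clamped to [0, 1]. The 95% CI
is Clopper–Pearson on the pooled counts mapped through the same doubling.
Pooling (rather than per-site medians) is what gives sensitivity below 1%
contamination — the gate all "normal tissue" claims sit behind. Truncal
sites on the tumor's LOH chromosome are excluded: there the doubling is not
exact (the tumor is hemizygous/homozygous), and keeping only diploid-het
sites keeps the estimator unbiased without a copy-number model.

# Haplotype-resolved LOH calling

Because the tumor lost one whole copy of chromosome 17, each germline
heterozygous SNP can be phased by which allele has the greater allele
fraction in a near-pure tumor sample (`phase_by_tumor()`). Ties are dropped
rather than guessed — ambiguous SNPs only add noise — as are SNPs under the
tumor depth floor (default 10×).

`test_loh()` then tests each sample for aggregate allelic imbalance: trials
= summed coverage over phased SNPs covered ≥ 10× in that sample, successes
= summed coverage of the tumor-retained alleles, and a two-sided exact
binomial test against

p0 = purity + (1 − purity) · 0.5,

the expected retained-allele fraction when the only source of imbalance is
tumor contamination (the tumor is 2+0 at the locus; normal cells are 1+1).
P values are BH-adjusted across all samples in the run (one family per
phased panel), and a sample is *flagged* only when q < 0.01, median kept-SNP
coverage ≥ 30×, and purity < 1% — so that no flagged imbalance can be
explained by tumor infiltration.

Aggregate counts cannot identify the mechanism, so the implied clone
fraction is reported under both models: CN-LOH, `c = 2a − 1`, and one-copy
deletion, `c = (2a − 1)/a`, where `a` is the aggregate fraction of the
favored haplotype. Direction is `wt_loss` when the retained (mutant)
haplotype is in excess and `mutant_loss` otherwise — the latter is a real
phenomenon in non-neuroectodermal tissues and must not be filtered away.

Note the calibration fact documented by the null simulations
(`null_loh_flag_rate()`): under the global null the probability that BH
rejects *anything* equals the q threshold, so the per-run "any flagged
sample" rate sits at ~1% by construction; the per-sample false-flag rate is
two orders of magnitude lower.

# Error-aware presence genotyping

`genotype_presence()` decides whether a *known* candidate mutation is
present in a sample by comparing its alt/total counts against the pooled
counts at the same site in control individuals — a locus-specific error
model. The test is the one-sided Fisher exact test (computed as the
hypergeometric tail, identical to `fisher.test(..., alternative =
"greater")` and cross-checked against it and an enumeration oracle in the
tests), BH-adjusted over all (mutation × sample) pairs in the run — the
global family is the more conservative reading and the easier one to audit.
No hard alt-read floor is applied by default; the q threshold already
encodes the error model. A `min_alt = 2` floor is used where the caller
stands in for a site-specific error-model ("Shearwater-like") caller over
thousands of candidate sites.

**Design choice — what the error panel is.** For shared-ancestry counting,
a leave-one-out panel built from the same individual's other samples
contaminates itself: a mutation genuinely shared by several samples raises
its own panel rate and can never be called, which is precisely the signal
the analysis needs (and breaks the tree-oracle identity the simulator
guarantees). The default panel is therefore the control individuals' pooled
counts, which carry no shared somatic ancestry with the proband;
`presence_by_panel()` (leave-one-out) remains available for settings where
no unrelated controls exist and the candidates are rare.

# Shared somatic ancestry

Two tissues carrying the same second hit either inherited it from a common
ancestor or acquired it independently; in the former case they share many
other substitutions too. `pairwise_sharing()` counts substitutions called
present in both members of each pair; `permutation_test()` compares the mean
count over test pairs against the mean of equally many counts drawn without
replacement from the control-pair pool, repeated `n_draws = 1000` times. P
is the fraction of draws whose control mean is *strictly* greater — ties
count as non-exceedances, no small-sample +1 correction is applied, and a
zero-exceedance result is displayed as a bound ("<0.001") while stored as 0.
Control pairs come from clean samples (< 1% purity, no second hit),
stratified CNS-vs-CNS versus CNS-vs-mesoderm so germ-layer architecture does
not masquerade as relatedness; pairs from the same original biopsy are
excluded from the pool by construction of the configuration.

# Single-gene dN/dS

`enumerate_impacts()` lists all 3L possible substitutions of an L-base CDS,
classifies each by codon translation (standard code), overrides the
essential splice positions (the ±2 intronic bases at each exon boundary,
derived automatically from the exon structure) as truncating, and records
the trinucleotide context from the CDS itself (N-padded at gene ends;
intronic splice rows have unknown context and take the mean spectrum rate).
`expected_class_fractions()` turns a mutation spectrum — uniform by default,
since no fitted spectrum is published for this setting — into neutral class
proportions e_syn, e_mis, e_trunc; any positive rescaling of the spectrum
leaves them unchanged.

The selection model is the single-gene core of the dN/dS framework: counts
(n_syn, n_mis, n_trunc) ~ Poisson(λ·e_class·ω_class) with ω_syn ≡ 1 and λ a
gene-level rate nuisance. The MLE is the normalized observed/expected ratio
ω_c = (n_c/e_c)/(n_syn/e_syn).

**Design choice — exact conditional intervals.** The asymptotic
likelihood-ratio interval undercovers at single-gene counts: with an
expected truncating count around 2, replicates observing zero truncating
mutations get an LRT upper bound just *below* 1, and measured coverage at
50 mutations drops to ~89%. Conditioning on m = n_syn + n_c makes n_c
binomial with p = e_cω/(e_syn + e_cω); inverting the Clopper–Pearson
interval for p and mapping back gives an ω interval with at least nominal
coverage at any count (measured ~98% at the same design), at the price of
conservatism. `positive_selection` is declared when the truncating lower
bound exceeds 1; n_syn = 0 gives ω = ∞ with a finite lower bound.

# Duplex consensus calling

`call_duplex()` requires, per molecule, a majority of variant reads on
*both* strands (ties break to no consensus; `min_reads_per_strand` defaults
to 1 because the contract is the both-strand requirement, not a depth
floor), and the site must be absent from the matched-normal call set.
Duplex coverage counts molecules with both strands covering the site,
independent of variant content. The operating characteristic that matters —
concordant false calls at (e/3)² per molecule versus e/3 single-strand — is
verified against the analytic value in the tests.

# Mutation burden and clonal expansions

`fit_burden_model()` fits a Gaussian linear mixed model (the response is a
raw substitution count; a count GLMM is deliberately not used, keeping the
model the simple linear one the analysis calls for) with second-hit status,
modality (bulk vs microdissection) and coverage as fixed effects and the
originating tissue piece as a random intercept, via `nlme`. Constant
covariates are dropped (collinear with the intercept); a single tissue
piece degrades to OLS with a warning. The expansion yardstick is 100
mutations: postnatal rates are tens of substitutions per year (≈27/year in
glia, ≈17/year in neurons, stored as documented metadata only), so a
recent expansion must add a burden of that order even in a child. The
verdict is `effect ≥ expansion_threshold` (default 100), and a
statistically significant but small effect — e.g. seven mutations — is
correctly reported as incompatible with a recent expansion.

# Driver annotation

The rules are explicit and closed-form, so the implementation is a direct
transcription with fixtures: small variants (hotspot missense/in-frame in
dominant genes at residue recurrence > 4; loss-of-function in recessive
genes; the NF1-specific rule that any inactivating variant is a probable
driver and missense only at recurrence > 4), copy number (oncogene
amplification at CN ≥ 5 below ploidy 2.7, ≥ 9 at or above; TSG loss at CN
= 0 below 2.7, CN ≤ ploidy − 2.7 at or above; tier 1 needs the tier-1 gene
list, ≤ 10 Mb, and a recognized mechanism — fusion-only genes never
qualify; tier 2 needs ≤ 1 Mb), and structural variants (recognized fusion,
TSG truncation, or activating intragenic deletion). All boundaries are
closed exactly as stated and tested at the boundary values. The tier-1 gene
list ships as a fixture; residue recurrence counts are synthetic stand-ins
(live databases are version-dependent), and the per-gene "recognized
mechanism" flags are the package's own minimal curation.

# Problem sizes and numerical choices

The calibration suites run at the sizes the analysis contracts state: 500
replicates of 200 samples × 3 sites for the genotyping null, 500 replicates
of 100 samples × 1,000 SNPs for the LOH null, 1,000 neutral dN/dS
replicates at 50 mutations, 1,000 permutation draws, ~10⁶ duplex molecules
pooled over independent replicates for the error-rate check. Module tests
use down-scaled versions of the same designs. Degenerate inputs resolve to
typed results rather than crashes where the analysis must continue (a
sample with no qualifying SNPs is "untestable", a zero-depth genotype test
is "untested") and to errors where continuing would be wrong (empty SNP
panel, zero control depth, all-zero spectrum, CDS not divisible by 3).

# Limitations

No breakpoint/segmentation inference (whole-panel imbalance only); no
de-novo variant discovery; no copy-number-aware purity deconvolution; the
beta-binomial dispersion machinery of full site-specific error models is
replaced by the pooled Fisher contract; the dN/dS estimator is single-gene
by design (no covariates, no indel model). The simulator's diploid,
artifact-free read model means test results certify statistical calibration,
not robustness to real sequencing artifacts.
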