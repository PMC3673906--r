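---
title: "Methods: pooled-sample SNP discovery, masking and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-sample SNP discovery, masking and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpmill)
```

# The problem

Conifer breeding programs need thousands of validated SNP markers, but
species like Douglas-fir have no reference genome and enormous genome
sizes, so SNP resources are built from transcriptome sequencing instead.
The practical design is: assemble a reference transcriptome from long
reads, map pooled short-read libraries from many genotypes against it,
call variants from the pooled read counts (individual genotypes are never
observed, only allele frequencies), select assayable candidate SNPs for a
fixed-content genotyping array, and validate the candidates by genotyping
a population sample. `snpmill` implements the computational core of this
workflow, plus a synthetic-data generator with planted truth so every
stage can be tested end to end without any sequencing data.

# Pooled-sample variant calling

## The composite-null binomial test

At a site covered by `n` reads of which `k` carry a non-reference base,
the caller asks whether the data are consistent with "no real
polymorphism above a minimal frequency": the composite null is that the
population alternative-allele frequency is at most a boundary value
$\theta$ given a per-base error rate $e$. Evaluated at the boundary, a
read shows the alternative allele with probability

$$p_0 = \theta (1 - e) + (1 - \theta)\, e,$$

either because it genuinely carries the allele and is read correctly, or
because it carries the reference allele and is misread. The reported
probability is the one-sided upper tail
$P(X \ge k),\ X \sim \mathrm{Binomial}(n, p_0)$, with the defaults
$\theta = 0.01$ and $e = 0.01$ (so $p_0 = 0.0198$). Small values indicate
sites unlikely to be monomorphic-plus-error. The test suite checks this
tail against an independent pmf-summation oracle exhaustively for all
`(k, n)` with `n` up to 200.

The cited family of pooled-sample methods includes likelihood variants
that model the exact number of chromosomes in the pool; our pools have
no well-defined chromosome count (tissue mixtures from dozens of
genotypes), so the boundary binomial test — which needs exactly the two
stated parameters — is the form implemented.

## Site-level filters

Per dataset, a candidate needs total depth $\ge 5$ and $\ge 2$
alternative reads; sites with RMS mapping quality below 20 are flagged;
sites deeper than 20,000 reads are skipped. Two rules deserve comment:

* **Fixed differences.** If a dataset's reads carry a single allele that
  differs from the reference, there is no polymorphism *within* the
  dataset; the disagreement is treated as a reference error, never
  emitted as a SNP. Indels are the exception: an indel against the
  reference is recorded even without within-dataset polymorphism.
* **N bases.** Bases below the base-quality floor (notably vendor
  quality-2 bases) count toward depth but never toward alleles. The
  synthetic generator emits an optional N fraction to exercise this.

Ties for the alternative allele are broken in the fixed order
A &lt; C &lt; G &lt; T, for determinism. Tri-allelic sites are scored on
the best single alternative; the full allele set is retained so the
bi-allelic rule can be enforced downstream.

## Combining datasets

Per-dataset probabilities at a shared site are combined with Fisher's
method, $X^2 = -2 \sum_i \ln p_i$, referred to a $\chi^2$ distribution
with $2k$ degrees of freedom. The upper tail is computed with the
closed form for even df,
$e^{-x/2} \sum_{i=0}^{k-1} (x/2)^i / i!$, accumulated in log space; a
quadrature oracle over the $\chi^2$ density verifies it to $10^{-10}$
across df 2–12. With all five datasets present this is the
ten-degree-of-freedom combination. When a dataset has no computed
probability at a site, it is omitted and the degrees of freedom shrink
to $2 \times (\text{datasets present})$: using a fixed df = 10 with
missing data would treat absence as evidence. This is a deliberate
design choice and the main place where a literal fixed-df reading was
rejected. Zero probabilities are clamped at $10^{-300}$ (logged), which
preserves ordering.

## Flanking variants and IUPAC masking

Assay probes hybridize to the sequence around a target SNP, so *any*
plausible variant near a target must be masked before design. A variant
qualifies as flanking at the permissive threshold $P_F = 0.10$ if it
beats $P_F$ in any single dataset **or** in the pooled combination.
Masked SNP positions are rewritten as the IUPAC code of their allele set
(reference plus alternatives; the code table comes from Biostrings), so
sequence length is preserved; the combined mask across datasets uses the
union of per-dataset allele sets. Indels have no IUPAC symbol and are
carried as a separate interval track (BED, 0-based half-open) instead.

# Target SNPs and array candidates

The target cascade retains SNPs that lie on the longest isotig of their
isogroup (avoiding redundant SNPs across transcript variants), are
bi-allelic, are not within a window (default ±10 nt) of a masked indel,
exceed mapping quality 40 in at least one dataset, and beat the target
threshold $P_S$ (one of $10^{-2}, 10^{-3}, 10^{-4}$) in at least one
dataset. "Near a high-quality indel" is delegated in the original
workflow to an opaque variant-caller annotation; the window rule is a
reproducible, tunable stand-in. Relaxing $P_S$ can only grow the target
set — a superset property the tests verify.

Array selection then proceeds in four steps: (1) SNPs on low-confidence
isotigs (classes C5/C6, below) are excluded; (2) SNPs in prioritized
genes (differential expression or annotation interest) are selected up
to two per isotig with ≥ 50 nt spacing, preferring lower mean
probability; (3) remaining SNPs need detection in ≥ 2 datasets, and only
the most probable SNP per isotig survives (ties broken by position, then
allele order); (4) non-priority survivors are dropped if they need the
two-probe Infinium I chemistry (A/T and C/G pairs), lack a design score
≥ 0.60, have < 10 mean covering reads, or < 0.05 mean minor-allele read
frequency — priority SNPs are exempt from step 4. Mean reads and mean
frequency are averaged over the datasets that detected the SNP, not over
all datasets, to avoid zero-imputation bias; the frequency rule is
applied to the read-based *minor*-allele frequency, the reading that
makes the filter symmetric in the two alleles. Every dropped row carries
the first rule it failed, so input = selected + rejected at every stage.

The resource extrapolation multiplies a candidate count by the measured
conversion rate and rounds: with 278,979 candidates and the 72.5%
conversion rate measured on the validation array the estimate is 202,260
genotypable SNPs.

# Assembly quality evaluation

## Confidence classes

Each assembled isotig is compared against a related species' unigene
catalog and classified by three criteria: number of distinct subjects
matched (counting only hits within 5 percentage points of the isotig's
best identity), whether other isotigs match the same subject
("partners"), and whether partner alignments overlap the focal
alignment on the shared subject. The classes are C1 (one subject, no
partners, highest confidence) through C6 (multiple subjects, overlapping
partners, lowest), with C7 for no match. Overlap is evaluated on
subject-side coordinates with closed intervals — the structural pictures
that define the classes show overlap on the reference unigene, and the
subject is the only shared coordinate system. The synthetic
match-table generator constructs each class by design and the classifier
must recover the plan exactly; plans in which a partnered class has no
possible partner (a single C3 alone, or one overlapping-class member)
are rejected as infeasible rather than silently adjusted.

## Strand orientation

dUTP strand-specific libraries read the antisense strand, so for a
forward-oriented transcript most reads map as reverse complements (C)
rather than direct output (D). Per sequence, a two-tailed exact binomial
test of C against D at null 0.5 (summing outcomes at most as probable
as the observed one, via `stats::binom.test`) decides: significant with
C > D gives "+", with C < D gives "−", otherwise ambiguous — including
the no-data case D = C = 0.

## Assembly statistics and contaminant screening

N50 follows the standard convention (smallest length L such that
sequences ≥ L cover half the assembled nucleotides), which guarantees
N50 ≥ median. Prose descriptions of N50 sometimes invert the
inequality; the standard convention is implemented and tested.
Contaminant screening applies three gates to a sequence's best database
hit — bit-score > 50, E-value < 1e-10, and subject genus present in a
bacterial/fungal name list — and removes the sequence only when all
three hold.

# Genotyping-array QC

Calls with per-call quality below 0.15 become no-calls. Per locus, the
call frequency, genotype counts, minor allele frequency, observed
heterozygosity $n_{AB}/n_{called}$ and expected heterozygosity $2pq$
are computed; a locus is *successful* when its call frequency is
≥ 0.85 and it is polymorphic. Expected heterozygosity uses plain
$2pq$, not the $n/(n-1)$ small-sample correction: the attainable range
then tops out at exactly 0.5, matching how the summary ranges are
reported. Loci that pass the call-rate gate but are monomorphic form
their own accounting category (called, not polymorphic).

Hardy-Weinberg departures are tested with the exact conditional test:
given the observed allele counts, all heterozygote counts of matching
parity are enumerated through the standard recurrence (run in log
space so deep samples cannot overflow), and the p-value sums every
configuration at most as probable as the observed one — the cumulative
form, not the mid-p variant, which is the standard form of the cited
exact test. An independent full-enumeration oracle (multinomial over
allele pairings) checks every configuration with up to 10 individuals.
The family-wise screen uses a Bonferroni threshold of
$0.05 / n_{\text{successful}}$; at the validation family size of 5847
successful loci this is $0.9 \times 10^{-5}$ to one significant figure.

# The synthetic-data generator

The generator is first-class, tested code, and its defaults are the
study conditions: five pooled datasets, per-base error 0.01, and
negative-binomial per-site coverage (mean 50, dispersion 5) — RNA-seq
pileups are overdispersed relative to Poisson. Sequencing error
substitutes each of the three non-true bases with probability $e/3$,
so at a site with planted alternative frequency $f$ the expected
alternative read fraction is $f(1-e) + (1-f)\,e/3$; generator tests
verify this closed form at 3-standard-error tolerance. Variants are
planted at 2 per kb by default with frequencies uniform on
[0.05, 0.5]; 60% segregate in two or more datasets; 10% are indels.
Genotype matrices follow the inbreeding-adjusted Hardy-Weinberg model
$P(AB) = 2pq(1-f_{\mathrm{in}})$ with independent no-calls. One master
seed fans out deterministically to per-component child seeds, so a
configuration reproduces byte-identical outputs while components stay
independent.

What the generator does *not* emulate: read-level artifacts (alignment
error, strand bias, indel realignment ambiguity, PCR duplicates),
linkage between nearby variants, expression-level variation between
genes, and paralog collapse — the main real-world cause of spurious
heterozygosity. Passing tests therefore demonstrate the correctness of
the statistics and the filter logic under the stated models, not
robustness to mis-assembly; the confidence-class machinery exists
precisely because paralog collapse must be handled upstream.

# Numerical choices and problem sizes

Tolerances: binomial tail vs. oracle $10^{-12}$; Fisher closed form vs.
quadrature $10^{-10}$ absolute; HWE vs. enumeration $10^{-12}$.
Stochastic checks run at fixed seeds with 3-SE bands. Caller power is
measured on 1000 replicate sites at planted frequency 0.20 with
coverage drawn from the generator's model conditioned on callable
depth ≥ 50 (at a fixed depth of exactly 50 the exact power of the
boundary test is 89.9%; the conditional coverage model reflects the
stated sites-of-at-least-depth-50 condition). Calibration of the HWE
test uses 5000–10,000 simulated loci at 260 individuals. The end-to-end
pipeline examples run at 4–25 isotigs of 300–1000 nt — sizes chosen so
the full suite exercises every stage in well under a minute while the
statistical checks retain their stated resolution.

# Worked example

```{r, eval = FALSE}
library(snpmill)
cfg <- sim_config(n_isotigs = 6, isotig_length_range = c(400L, 800L),
                  seed = 42)
run <- run_pipeline(cfg, outdir = "run1")
pipeline_report(run)
```

# Known limitations

* The caller's composite-null test controls false positives but does not
  estimate allele frequencies with uncertainty; `freq` columns are raw
  read fractions.
* The indel probability model reuses the SNP binomial tail on
  supporting-read counts; indel-specific error processes (homopolymer
  slippage) are not modeled, which is why whole datasets can be marked
  indel-untrusted instead.
* Design scores are an input join; the vendor's scoring algorithm is
  proprietary and absent scores simply fail the ≥ 0.60 rule for
  non-priority SNPs.
* The pipeline driver's confidence classes and priority lists are
  simulated placements in the synthetic run; with real data they are
  inputs from the homology comparison and expression analysis.
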