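---
title: "Detecting differential C>U RNA editing from paired pileups: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting differential C>U RNA editing from paired pileups: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuedit)
```

## The problem

Site-specific C>U RNA editing — deamination of a cytidine so the
transcript reads U (sequenced as T) where the genome has C — is carried
out in human monocytes and macrophages by APOBEC-family cytidine
deaminases and is induced by stimuli such as hypoxia, interferons and M1
macrophage polarization. Detecting such editing from bulk RNA-seq is a
needle-in-a-haystack problem: a genuine edit looks exactly like a
sequencing error, a mapping artifact, or an unannotated genomic
polymorphism, except that its level responds to the stimulus.

`cuedit` implements the comparative design that makes this tractable:
test and control samples from the *same donors* (e.g. hypoxic vs normoxic
monocyte preparations, or M1 vs M2 macrophages from the same blood draw)
are sequenced, piled up per genome position, and compared *pairwise*.
Artifacts shared by both members of a pair cancel; sites whose variant
level changes consistently across donors remain.

The pipeline stages are, in order:

1. parse per-sample `samtools mpileup` text into strand-split A/C/G/T
   call counts (`read_pileup()`, `merge_samples()`);
2. screen sites for candidacy (`screen_sites()`);
3. filter by editing level (`level_filter()`);
4. exclude known polymorphisms and annotation-ambiguous sites, and
   assign genes (`annotation_exclusions()`);
5. test each candidate with a paired beta-binomial model
   (`estimate_dispersion()`, `fit_paired_bb()`);
6. control FDR with Storey bootstrap q-values (`qvalues()`);
7. call differential sites (`call_differential()`);
8. remove mapping and strand artifacts (`flank_uniqueness_filter()`,
   `strand_bias_filter()`);
9. deduce the RNA-level change from the gene's coding strand
   (`deduce_rna_change()`); and
10. annotate sequence context (`motif_class()`, `palindrome_flank()`,
    `relative_entropy()`, `site_in_loop()`).

`run_pipeline()` composes all stages and writes a manifest with per-stage
site counts.

## Pileups and the candidacy screen

Counts are taken from mpileup text with base quality at least Phred 20;
`.`/`,` are reference calls on the forward/reverse strand and letters are
variant calls, with read-start/end marks and indel strings consumed
silently. Only A/T/G/C calls count — `N`, deletions and reference skips
do not.

A site is a candidate only if **all** of the following hold, with
defaults in `screen_thresholds()`:

1. at least 20 calls in both samples of at least one donor pair, and at
   least 5 calls in every sample (coverage);
2. the reference base makes up at least half the calls in all test or in
   all control samples (the edit must not look fixed);
3. at least 2 identical variant calls in at least 2 samples of one
   group, at least 1 such call in every sample of one group, and no
   more than 5 calls for any *different* variant anywhere (consistent,
   single-variant support — exactly one nucleotide change is considered
   per site);
4. at least 95% of calls are reference-or-variant in every sample
   (purity).

If several variant bases satisfy rule 3 the one with the highest total
count wins (alphabetical on ties, flagged). Candidates are then filtered
by level: at least 2.5% in at least two samples of a group, a group mean
of at least 5%, and range/mean at least 2 across all samples pooled —
the last rule discards sites that are uniformly "edited" in every sample
(a polymorphism signature) before multiple testing. A site with a known
population polymorphism of frequency above 20% matching its change, a
site in no annotated gene, or a site in exons (or only introns) of
several genes on both strands is excluded; a site exonic in one gene and
intronic in another on the opposite strand is assigned the exon-bearing
gene, whose strand later determines the RNA-level change.

The screen is deliberately rule-based and is verified in the test suite
against an independently written brute-force checker over randomized
count tables (100% agreement required over 10,000 tables).

## The paired beta-binomial (inverted beta-binomial) test

For each candidate, donor pair $i$ contributes variant/total counts
$(v_i^T, n_i^T)$ and $(v_i^C, n_i^C)$. The model:

* pair $i$ has a latent baseline editing proportion $\pi_i$;
* the test member's proportion satisfies
  $\mathrm{odds}(\pi_i^T) = \beta \cdot \mathrm{odds}(\pi_i^C)$, with a
  single fold change $\beta$ shared by all pairs (the odds scale keeps
  $\beta$ meaningful as levels approach 0 or 1);
* given its proportion, each member's count is beta-binomial with
  intra-class correlation $\rho$ (variance inflation $1 + (n-1)\rho$),
  shared across samples.

$H_0\!: \beta = 1$ is tested by a 1-df likelihood-ratio chi-square;
$\hat\beta$ is reported with magnitude capped at $10^4$ (a site with no
control variant calls has unbounded $\hat\beta$; the cap keeps fold
changes printable and sortable).

Two small-sample issues shape the implementation, and both were
diagnosed by simulation during development:

**Incidental baselines.** With 3 pairs there are 6 observations and 3
nuisance baselines; naively profiling them biases the dispersion
estimate down and inflates the LRT (rejection of a true null at
nominal 5% was 10–16% in our simulations). The per-pair baselines are
therefore profiled out with a Cox–Reid adjustment — the same
incidental-parameter correction used for dispersion estimation in
count-model RNA-seq packages — implemented in C++
(`src/ibb.cpp`).

**Per-site dispersion is unidentifiable.** After profiling the baselines
and the fold, roughly two degrees of freedom remain to estimate $\rho$ —
hopeless per site. All sites of an experiment share the sequencing and
biological overdispersion, so `estimate_dispersion()` estimates one
$\rho$ across sites by method of moments on within-pair differences of
editing proportions, after removing each site's own fold (with a
$k/(k-1)$ degrees-of-freedom correction), and `run_pipeline()` holds it
fixed in every per-site test. This mirrors standard RNA-seq practice of
pooling dispersion across genes. With the pooled workflow the null
rejection rate at $\alpha = 0.05$ is 5–7% for $\rho \in \{0.005, 0.02\}$
at coverage 100 with 3 pairs, and power for a 1% → 20% shift is
essentially 1; both are exercised by the acceptance suite. Calling
`fit_paired_bb()` without a `rho` argument still works — the site's own
dispersion is then estimated jointly — but its p-values are liberal with
few pairs, and the documentation says so.

Optimization uses deterministic moment-based starting values (the
alternative fit is additionally seeded from the null solution so the LRT
can never go negative through an optimizer failure); a stochastic
restart scheme would put hidden RNG state inside a fitting routine, so
it was deliberately avoided. Convergence tolerance is `factr = 1e4`
(L-BFGS-B) on the outer parameters and $10^{-10}$ on the inner Newton
profile; degenerate inputs (no variant calls anywhere, or saturated
counts) return $\hat\beta = 1$, $p = 1$, flagged.

At $\rho = 0$ the p-value tracks the exact conditional test (the
test-member count is product-hypergeometric given pair totals): on
tables with totals up to 30 per member the chi-square p agrees with the
LR-ordered exact p to about 0.05 in the mid-range, which is the
approximation quality one should expect from a 1-df chi-square at those
counts.

## Multiple testing and calling

Q-values use Storey's procedure: $\hat\pi_0$ estimated by the bootstrap
method over $\lambda \in \{0.05, \dots, 0.95\}$ (the $\lambda$
minimizing the bootstrap MSE around the minimum $\hat\pi_0(\lambda)$ is
selected), the robust small-$m$ formula
$q = \hat\pi_0 m p / \{r(1-(1-p)^m)\}$, and monotonicity enforced by a
cumulative minimum from the largest p-value. A site is called when
$q < 0.05$, the fold exceeds 2 in either direction
($\beta > 2$ or $\beta < 1/2$), and the mean level of the higher group
is at least 5%. Concordance with a second-aligner pileup set
(p < 0.05, same direction, same fold rule) can be switched on in the
configuration; it is off by default because the pipeline consumes
pileups regardless of which aligner produced them.

## Artifact filters

**Flank uniqueness.** For each call, four 30-base queries are built: the
29-base 5′ flank plus the site base, and the site base plus the 29-base
3′ flank, each with the reference and with the variant base. If any
query matches the genome exactly (either strand) anywhere other than the
site's own locus, the site is dropped — its support could come from
mis-mapped reads of a perfect repeat. Exact string matching implements
"aligned perfectly" faithfully and needs no external aligner.

**Strand bias.** A real edit is seen on reads of both orientations.
A site is dropped if, summed over all samples, the variant was called
from more than nine forward reads but no reverse read (or vice versa);
or if within the test group or within the control group the variant
calls' forward fraction differs significantly (p < 0.05) from the
reference calls' forward fraction, compared pairwise within each sample.
Because read strands are assigned per read, the null here is plain
binomial given the totals, and the paired LRT is referred to its exact
parametric Monte Carlo distribution (199 draws, seeded from the counts
so results are reproducible and filters commute) rather than to the
asymptotic chi-square, which is liberal at the 10–50 variant calls this
filter typically examines. A group whose variant calls do not exceed
the nine-read trigger is exempt from the significance sub-rule: fewer
than ten reads cannot evidence strand bias either way, and testing them
only produces spurious drops.

## Sequence and structure context

Context windows are extracted from the gene's coding strand as RNA, the
edited base centered, so C>U sites read C at position 0. The tetramer at
positions −3…0 is classified as `canonical` (CAUC), `variant` (CACC,
CCUC, CUUC, UAUC — the 1-nt neighbours of CAUC) or `other`, and the
−4…+1 hexamer is checked against CCAUCG. Per-position relative entropy
$R_j = \sum_b p_{jb}\log_2(p_{jb}/q_b)$ against a uniform background
(0–2 bits) summarizes logo information content, with a bootstrap 95% CI.

Palindromic flanks — reverse-complementary $k$-mers ending just upstream
of the tetramer and starting just downstream of the edited base, able to
form the stem of a stem-loop that presents the edited C — are searched
for $k$ from 7 down to 2 with up to 2 nt of offset on either arm; the
largest matching $k$ is reported. The search is a codified stand-in for
what was historically done by eye, and its parameters are configurable.

Whether the edited base sits in a loop is decided on a folded structure
of the ±30-nt window. The built-in engine is base-pair maximization
(Nussinov recurrence; Watson–Crick plus G·U pairs; minimum hairpin loop
3; deterministic traceback preferring unpaired bases, then the smallest
partner). This is an explicit combinatorial approximation, not a
thermodynamic minimum-free-energy structure: it overpairs relative to
real RNA, so "in loop" verdicts are conservative. Any external folder
can be plugged in as a function from sequence to dot-bracket string, and
results record which engine produced them.

## Targeted quantification

`sanger_level()` converts chromatogram peak heights to editing percent:
minor/(major+minor) × 100, one decimal. Peak-calling software only
reports a minor peak above 5% of the major peak, so an absent minor peak
is assigned 4%/(104%) = 3.8% — the value 3.8 exactly, by convention, not
3.846.

`targeted_editing()` estimates the editing level at one known position
from pileup counts with indeterminability rules for low or impure
coverage: indeterminable if reference-plus-variant calls are under 99%
of the total, if there are fewer than 200 calls with no variant call, or
fewer than 100 calls with exactly one. For a minus-strand gene such as
*SDHB* the plus-strand pileup shows reference G and variant A, the
defaults; both bases are parameters, so either strand works.
`count_c_positions()` and `cdna_range_length()` support per-ORF editing
profiles in cDNA (c.) coordinates, and `in_silico_pcr()` checks primer
pairs by exact matching.

## The synthetic-data generator

`simulate_dataset()` builds a complete, fully known experiment: a
uniform-composition genome (20 kb by default) tiled with 10
exon–intron–exon genes on random strands with intergenic gaps; 50
planted C>U sites in exons (coding-strand C, so plus-strand G>A for
minus-strand genes); per-sample mpileup files for 3 test/control pairs;
and a truth table. Per site, pair and condition, a baseline editing
proportion is drawn — Beta(1, 99) for controls (mean 1%) and Beta(4, 16)
for tests (mean 20%) — and realized counts are beta-binomial with
$\rho = 0.01$ at negative-binomial coverage (mean 100, size 10).
Non-planted positions carry only sequencing errors (0.2% per call,
uniform over the other bases). Read strand is an independent fair coin
per call. Half of the planted sites are written into a CCAUCG hexamer
with a directly adjacent 5-bp palindromic stem, so the context stage has
planted signal. Emitted base qualities are a constant Phred 30 — above
the parser's default cutoff, so the quality filter is exercised but
never triggered. Everything is deterministic given the seed.

These defaults were chosen once as a realistic bulk RNA-seq editing
experiment and are not tuned: coverage ~100× matches a deep bulk
library over expressed exons; 1% control levels are at the edge of
detectability; 20% test levels match strongly induced editing; drawing
the baselines independently per pair *and* condition makes the realized
fold vary across donors, which is why the pooled dispersion the
pipeline estimates on planted sites (~0.05) deliberately exceeds the
nominal member-level $\rho$.

What the generator does **not** emulate — and hence what green tests do
not establish about real data: alignment and mapping error (reads are
never simulated, so the flank-uniqueness filter only ever sees planted
repeats), reference bias, non-uniform error profiles along reads,
genomic SNPs in the sample (the polymorphism exclusion is tested on
constructed tables), library-size differences between members of a
pair, and expression-dependent coverage.

`evaluate_recovery()` scores calls against truth (sensitivity,
precision, empirical FDR). Under the defaults the pipeline recovers
90–100% of planted sites with FDR 0 and makes no calls on a null
dataset of 20,000 error-only positions; the residual sensitivity loss
is almost entirely the strand-bias significance rule rejecting ~5% of
true sites at its nominal level, which is the cost the published filter
design pays for artifact control.

## Problem sizes and determinism

The test and acceptance suites run the calibration experiment at 2,000
null sites (1,000 per $\rho$ setting) and 400 alternative sites, the
screening-oracle comparison at 10,000 random tables, the recovery
experiment on the 50-site default dataset plus a null dataset, and the
context oracles on dozens of randomized windows — sizes chosen so the
whole suite completes in a few minutes while keeping Monte Carlo noise
well inside the asserted margins. Every stochastic step takes an
explicit seed: the generator requires one, `run_pipeline()` seeds the
q-value bootstrap from its configuration, and the strand-bias Monte
Carlo derives its seed from the data, so reruns are bit-identical.

## Known limitations

* The fold-change test assumes one shared $\beta$ across pairs;
  donor-specific induction strength ends up in the dispersion, reducing
  power rather than biasing calls.
* The pooled dispersion assumes exchangeable sites; a minority of sites
  with much larger overdispersion would be anti-conservatively tested.
* Chi-square p-values are approximate at very small counts (about
  ±0.05 versus the exact conditional test at totals ≤ 30).
* Base-pair maximization is not a thermodynamic folder; loop verdicts
  are engine-labelled and an external folder can be substituted.
* The per-site screen's "calls" are quality-filtered A/T/G/C calls;
  mapping quality is assumed handled upstream when the pileup was made.
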