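---
title: "Measuring site-specific C-to-U RNA editing: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring site-specific C-to-U RNA editing: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuedit)
```

`cuedit` quantifies the fraction of transcripts edited at a single
cytidine, the way the *SDHB* c.136C>U (R46X) system is measured: from
RNA-seq pileups against a pooled error background, from allele-specific
qPCR crossing points, and from deep amplicon tallies. This vignette
explains each model, the parameters that matter, and the design decisions
taken where the methodology is genuinely open.

## The coordinate model

A `gene_model` ties three coordinate systems together: genomic intervals
(0-based half-open internally; all user-facing output is 1-based),
CDS (c.) positions numbered from the first base of the start codon (HGVS
convention; UTRs are representable in exons but carry no c. number), and
codons (`codon_number = ceiling(pos/3)`). For minus-strand genes the CDS
sequence is stored in transcript orientation — the reverse complement of
the plus-strand genome over the CDS spans read right to left — and every
pileup or read simulation complements plus-strand base calls into
transcript orientation at the boundary. This is the single invariant the
whole package leans on: *all tallies, fractions, and variant classes are
reported in transcript orientation*. Mapping is validated by exhaustive
round-trip enumeration and by a mirror-fixture property (a gene and its
reverse-complemented, strand-flipped mirror must give identical
transcript views).

Ambiguity codes in reference sequences are rejected at model build time;
the systems this package targets have unambiguous references, and
permitting IUPAC codes would poison the base-count background pool.

## In-silico RFLP

`digest_amplicon()` cuts at each occurrence of a recognition site
(default Taq1, TCGA), at a configurable offset within the site. The
offset defaults to after the first base (T^CGA); only fragment sums are
observable on a gel, so the offset is exposed rather than hard-coded.
Overlapping occurrences are resolved left-to-right, which matches
processive digestion and makes fragment lengths well defined.
`edit_destroys_site()` answers the verification question directly: does
substituting the edited base remove a site occurrence overlapping the
edit? Site creation elsewhere is deliberately ignored — the assay reads
loss of cutting, not gain.

## Pileup tallies and the background-error null

`tally_from_alignments()` walks every aligned base over the CDS and
assigns it to exactly one of five categories — A, C, G, T, or ambiguous —
per position. The category conservation invariant (the five counts sum to
the filtered depth) is asserted throughout the tests. Three choices here
are substantive:

* **Ambiguous calls.** N base calls, deletions and reference skips
  overlapping a CDS position all count as "ambiguous". They are one of
  the five categories, so by default they stay in the depth denominator
  of every fraction; `include_ambiguous_in_depth = FALSE` restricts the
  denominator to A/C/G/T for users who prefer a called-base denominator.
* **Filters.** The default base-quality floor of 13 emulates the default
  of samtools-style pileup tools; MAPQ filtering, duplicate exclusion and
  secondary/supplementary exclusion are on by default. Per-base alignment
  quality recalibration (BAQ) is *not* reimplemented: the quality floor
  is an approximation of that behaviour, and tallies from BAQ-enabled
  tools may differ slightly at low-quality columns. Overlapping mates are
  counted independently by default (each alignment record is one
  observation); `collapse_mate_overlap = TRUE` counts each (read, position)
  once for fragment-level counting.
* **The null.** The background for a candidate site with reference base C
  is the pooled T-at-C fraction over *all* C-bearing CDS positions —
  including the query site itself by default, matching a pool defined
  over "any" same-base position. Including the site makes the test
  slightly conservative when editing is high; `include_query_site =
  FALSE` gives the cleaner leave-one-out null. Both are exposed because
  the choice is not decidable from the assay definition.

The site-vs-background comparison is a two-tailed chi-square with Yates
continuity correction on the 2×2 table (site edited/other vs background
edited/other), computed in closed form and clipped to zero when
|ad − bc| ≤ N/2. Counts are held in double precision: background pools
over deep data reach 10^6–10^7 and the cross-products overflow 32-bit
integers. Known polymorphisms are handled by a user-supplied SNP position
list (TSV or VCF); a call whose genomic position appears in the list is
flagged, not suppressed — distinguishing a germline allele from an edit
is the analyst's decision.

## The qPCR model

The forward model treats amplification as (1+E)-fold per cycle: a well
with effective template T crosses threshold at Cp = log_{1+E}(K/T) for an
assay constant K. Two assays per sample — total transcript and
allele-specific (edited) — give the estimator

f̂ = (1+E)^(Cp_total − Cp_allele),

which is 2^ΔCp at the default E = 1 (100% duplication efficiency). The
default is deliberately the uncalibrated, assumption-of-perfect-doubling
form; a measured efficiency from `efficiency_from_dilution_series()` is
opt-in. Replicate wells are averaged on the Cp scale (not the linear
scale) before ΔCp — the common practice for crossing-point data; a
replicate spread above 0.5 cycles is flagged. Estimated fractions above 1
arise when noisy wells invert ΔCp; they are clipped to 1 with a warning
rather than erroring, so plates with one bad well still process.

Assay specificity is characterized from pure control templates: the
false-positive fraction (apparent editing on 100% wild-type template,
e.g. ~1.4% for a well-behaved allele-specific primer) and the recovery
(apparent fraction on 100% edited template, e.g. ~91%). The linear
unmixing `correct_estimate()` inverts the induced distortion
(observed = f·recovery + (1−f)·fp), but it is OFF by default everywhere:
uncorrected estimates are conservative (slightly below truth), and
reporting them stringently avoids overstating editing. The run-acceptance
practice of carrying a known positive control sample is a QC convention,
not a computation, and is not modelled.

## Amplicon screening

`call_variants()` reports one call per (position, non-reference base)
whose frequency *strictly* exceeds the threshold (default 10%) at
sufficient depth (default floor 100; at a 10% rule, shallower positions
are too noisy to screen). The strict boundary is decided in exact integer
arithmetic — counts scaled against the threshold in millionths — so a
variant at exactly the threshold is never reported regardless of
floating-point representation. Classification into canonical edit classes
(A-to-G for A-to-I, C-to-T for C-to-U) operates in transcript orientation
only; amplicons derive from sense transcripts, so antisense classes are
out of scope. `compare_methods()` reports both readings of "X% higher on
average" — the mean of per-pair ratios and the ratio of means — because
the phrase does not decide between them; neither is privileged.

## Cohort statistics

`wilcoxon_signed_rank()` and `mann_whitney_u()` are exact by default at
cohort scale: the full distribution of the statistic over all sign
assignments (2^n) or group assignments (C(n, n_a)) is computed by a
generating-function convolution over doubled mid-ranks, which handles
ties exactly — the situation that forces stock implementations onto a
normal approximation. Zero differences are dropped before ranking
(standard signed-rank practice; the handling is stated because data with
identical paired values are common in percent-editing tables). The exact
limits (n ≤ 25 pairs; combined n ≤ 20) keep the computation instant at
desk scale; above them a tie-corrected normal approximation (without
continuity correction) takes over, and the `method` field says which path
ran. Two-sided p-values are twice the smaller exact tail, capped at 1.
`extrapolate_pure_population()` is ordinary least squares of editing on
cell fraction with the point estimate at fraction 1.0, flagged as an
extrapolation whenever 1.0 lies outside the observed range — which it
essentially always is, so the prediction inherits the linearity
assumption.

## The synthetic-data generators

Every input the pipeline consumes can be generated with an explicit seed;
simulators save and restore the caller's RNG state, so there is no hidden
global randomness. What they emulate — and do not:

* **Reads** (`simulate_alignments()`): single-end, fixed-length,
  uniformly positioned over the CDS in transcript coordinates; each read
  is drawn from an edited molecule with probability f independently at
  each covered edit site; sequencing errors are i.i.d. per base at rate ε,
  uniform over the three wrong bases (ε/3 each — the aggregate background
  observed in deep data constrains only the total, so the uniform
  spectrum is a modelling choice, configurable via the error rate).
  Reads are emitted as plus-strand SAM records with intron-spanning N
  CIGAR ops, so minus-strand genes genuinely exercise complementation.
  Not modelled: base-quality profiles, PCR duplicates, paired ends,
  fragment-length distributions, alignment error. Passing tests therefore
  demonstrate correctness of the counting and testing machinery, not
  robustness to mapping artefacts in real BAMs.
* **Tallies** (`simulate_tally()`): the per-position multinomial
  marginal of the read model (P(edited base) = f(1−ε) + (1−f)ε/3, ...),
  at exact depth; distributional equivalence with the read path is
  asserted by a two-sample test.
* **qPCR plates** (`simulate_qpcr_plate()`): the (1+E)-per-cycle model
  above with Gaussian well noise (default sd 0.15 cycles, a typical
  replicate spread) and allele cross-reactivity (defaults fp = 1.38%,
  recovery = 91%, matching a stringent allele-specific assay). Zero
  effective template yields a no-amplification sentinel (NA Cp).
* **Cohorts** (`simulate_cohort()`): donors draw a log-normal baseline
  editing fraction (median 2%, the uncultured monocyte-enriched level)
  linked positively to a Beta-distributed CD14+ fraction (mean ~27%,
  overnight cold-aggregation enrichment); normoxic culture multiplies the
  baseline by a day profile peaking at ~5× on days 5–7, hypoxic culture
  by a donor-level log-normal multiplier (median 9, i.e. 2% → ~18%)
  times a profile peaking on day 2; measurements get multiplicative
  log-normal noise and are clipped to [0, 1). No quantitative noise model
  for donor variability is published for this system, so these defaults
  are invented to reproduce the reported ranges qualitatively and are
  labelled as such; they are the package's fixed study conditions, not
  tuning knobs.

The synthetic *SDHB* surrogate (`synthetic_sdhb_model()`) deserves its
own caveat: it enforces the structural facts the pipeline depends on —
843-bp CDS, 213 C-bearing positions, codon 46 = CGA with its first base
inside the gene's sole Taq1 site, c.136 in exon 2 of an eight-exon
minus-strand gene, no internal stops — and randomizes everything else.
It is a stand-in for, not a copy of, the RefSeq sequence; analyses that
depend on the actual sequence context (primer design, other restriction
sites) need the real reference.

## Numerical choices and degenerate inputs

* Yates χ² in closed form, double precision, clipped at the correction
  saturation point; zero marginals return NA with a warning rather than a
  fabricated statistic.
* Strict-threshold comparisons in integer arithmetic (millionths), never
  via floating-point `>` on fractions.
* Exact test distributions via integer-valued DP on doubled ranks;
  counts stay below 2^53 for all supported n, so double arithmetic is
  exact.
* Zero-depth sites, empty background pools, all-zero difference vectors,
  constant regressors and zero-variance correlations all signal
  explicitly (warning + NA, or a classed error) instead of returning
  numbers.
* Standard-curve fits require ≥ 3 dilution steps, warn on non-monotone
  mean Cp and error on non-positive slopes.

## Problem sizes in the test-suite and acceptance runs

The shipped tests and the acceptance script run entirely on simulated
data at sizes chosen to make the statistical assertions sharp but cheap:
read-level checks at ≤ 10^4 reads against a brute-force per-read recount
oracle; estimator-recovery checks at depth 5000 (the depth at which a 3
binomial-SD band around 1.7% editing is ±0.5%); chi-square size checks
over 2000 simulated null datasets at parameters giving large expected
cell counts (depth 3000, ε = 6%), where the asymptotic reference
distribution is trustworthy; 200-replicate power and recovery
Monte-Carlos elsewhere. The full suite completes in well under a minute.

## Known limitations

* BAQ and indel realignment are not reproduced; tallies can differ from
  mpileup-derived counts at noisy columns.
* The pileup walk loads all records overlapping the gene region;
  whole-genome BAMs should be indexed so region queries apply.
* No de novo editing-site discovery, hyper-editing rescue, or A-to-I
  cluster analysis — the package quantifies nominated sites.
* No raw fluorescence processing: Cp values are inputs.
* Cohort modelling is deliberately simple (no mixed-effects or
  longitudinal structure, no multiple-testing correction beyond raw p);
  it matches the analysis style of small paired donor studies.
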