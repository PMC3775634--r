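# cuedit

Quantification of site-specific C-to-U RNA editing of a coding transcript.

Certain mRNAs are post-transcriptionally edited at single cytidines, read
as T in sequencing data and as a new allele in PCR assays. The motivating
system is *SDHB* c.136C>U in human monocytes: deamination of the cytosine
at CDS position 136 converts codon 46 (CGA, arginine) into a premature
stop (TGA, R46X), inactivating a fraction of the transcripts of this
mitochondrial complex II subunit. The editing rate is low in resting
blood monocytes (a few percent), rises during normoxic macrophage
differentiation, and is strongly induced by hypoxia — so measuring a
*fraction of edited transcripts* accurately, against sequencing error and
assay cross-reactivity, is the central methodological problem.

`cuedit` implements that measurement stack as a tested R package for
anyone quantifying low-level site-specific RNA editing (or any minor
transcript allele) from bulk RNA-seq pileups, allele-specific qPCR or
deep amplicon sequencing:

* **Gene model** — strand-aware mapping between CDS (c.) coordinates and
  genomic coordinates over multi-exon genes, codon consequence prediction
  of single-base edits, reference-base position counts, and in-silico
  restriction digests (RFLP) for edit verification
  (`gene_model()`, `map_cds_to_genome()`, `consequence_of_edit()`,
  `digest_amplicon()`, `edit_destroys_site()`).
* **Pileup editing quantification** — five-category base-call tallies
  (A/C/G/T/ambiguous, transcript orientation) from BAM/SAM over the CDS;
  the editing fraction at a candidate site; a background error null pooled
  over all positions sharing the site's reference base (for *SDHB*, the
  213 C-bearing positions of the 843-bp CDS); and a two-tailed
  Yates-corrected chi-square site-vs-background test
  (`tally_from_alignments()`, `site_fraction()`, `background_fraction()`,
  `yates_chi_square()`, `call_editing_site()`). The 2×2 statistic is

  χ² = N (|ad − bc| − N/2)² / ((a+b)(c+d)(a+c)(b+d)),

  with (a, b) the edited/other calls at the site and (c, d) the pooled
  background calls.
* **Allele-specific qPCR** — the ΔCp estimator of the edited-transcript
  fraction, f̂ = (1+E)^(Cp_total − Cp_allele) (2^ΔCp at the default 100%
  duplication efficiency); standard-curve efficiency fitting from serial
  dilutions, E = d^(1/slope) − 1; assay specificity profiles from pure
  control templates (false-positive rate, recovery) with optional linear
  unmixing; and 2^−ΔΔCt relative expression
  (`estimate_editing_fraction()`, `efficiency_from_dilution_series()`,
  `specificity_from_controls()`, `correct_estimate()`,
  `ddct_relative_expression()`).
* **Amplicon screening** — variant calls from deep amplicon tallies under
  a strict frequency reporting rule (default ">10%", decided in exact
  integer arithmetic), canonical edit classification (A-to-G, C-to-T),
  and paired comparison of sequencing vs qPCR estimates
  (`call_variants()`, `classify_canonical()`, `compare_methods()`).
* **Cohort statistics** — exact Wilcoxon matched-pairs signed-rank and
  Mann-Whitney U tests (full enumeration with mid-ranked ties at small n,
  tie-corrected normal approximation above), Pearson correlation, and
  linear extrapolation of editing to a pure cell population
  (`wilcoxon_signed_rank()`, `mann_whitney_u()`,
  `extrapolate_pure_population()`).
* **Synthetic data** — seeded simulators for every input: aligned reads
  (SAM) or direct tallies under a per-site editing fraction and uniform
  error spectrum, qPCR plates under a (1+E)-fold-per-cycle model with
  allele cross-reactivity, paired donor cohorts with a hypoxia effect,
  plus a fully synthetic *SDHB*-like gene fixture
  (`simulate_alignments()`, `simulate_tally()`, `simulate_qpcr_plate()`,
  `simulate_cohort()`, `synthetic_sdhb_model()`).

File formats go through the standard Bioconductor stack: Rsamtools for
BAM/SAM, Biostrings for FASTA and sequence arithmetic, plus plain TSV for
plates, tallies, donor tables and gene models (BED12 or JSON).

## Worked example

```r
library(cuedit)

model <- synthetic_sdhb_model()      # synthetic SDHB-like fixture
consequence_of_edit(model, 136, "T")
#> codon 46: CGA -> TGA, effect "nonsense"   (the R46X stop)

# a whole-blood-like sample: 1.7% editing, 0.18% sequencing error
cfg <- pileup_sim_config(model, depth = 5000, error_rate = 0.0018,
                         edits = c("136" = 0.017), seed = 42)
tal <- simulate_tally(cfg)
call_editing_site(tal, model, 136)
#> <site_editing_call> c.136C>T  76/5000 = 0.0152  background 717/1065000 = 0.0006732
#>   chi2 = 1399, p = 4.34e-306, snp_overlap = FALSE

estimate_editing_fraction(cp_total = 20.1, cp_allele = 25.9)
#> 0.0179   # 2^-5.8: the allele assay crosses 5.8 cycles late
```

The site call reads: 76 of 5000 reads carry T at c.136 (1.52%, within
sampling error of the simulated 1.7%), while T-at-C calls across all 213
C-bearing positions run at 0.067% — the sequencing-error floor — and the
Yates chi-square rejects equality decisively. The ΔCp line converts a
5.8-cycle gap between the total and allele-specific assays into a 1.8%
edited fraction under perfect doubling.

The numbered scripts under `analysis/` walk the full workflow
(gene model and RFLP checks, pileup quantification across the observed
editing range, qPCR calibration, amplicon screening, cohort statistics)
and write their tables under `results/`:

```sh
Rscript analysis/01_gene_model.R
Rscript analysis/02_pileup_editing.R   # ... through 05
```

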