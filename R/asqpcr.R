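#' Read a qPCR plate table
#'
#' TSV columns: `sample_id`, `assay` (`TOTAL` or `ALLELE_T`), `replicate`,
#' `cp`, and optionally `template_amount` (mol) and `dilution_step` for
#' calibration series.
#'
#' @param path file path.
#' @return data.frame of wells.
#' @export
read_cp_plate <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "assay", "replicate", "cp")
  if (!all(need %in% names(x)))
    stop("plate table must have columns: ", paste(need, collapse = ", "))
  if (any(!is.na(x$cp) & x$cp <= 0)) stop("Cp values must be positive")
  x
}

#' Average replicate wells per (sample, assay)
#'
#' Cp values are averaged on the cycle scale (not the linear scale). A
#' replicate spread above `outlier_sd` cycles is flagged for review.
#'
#' @param wells data.frame of wells as from [read_cp_plate()].
#' @param outlier_sd flag threshold on the replicate standard deviation
#'   (default 0.5 cycles).
#' @return data.frame with one row per (sample_id, assay): `mean_cp`,
#'   `sd_cp` (`NA` for single wells), `n_wells`, `outlier`.
#' @export
aggregate_replicates <- function(wells, outlier_sd = 0.5) {
  wells <- wells[!is.na(wells$cp), , drop = FALSE]
  if (nrow(wells) == 0) stop("no wells with Cp values")
  key <- interaction(wells$sample_id, wells$assay, drop = TRUE)
  agg <- do.call(rbind, lapply(split(wells, key), function(w) {
    data.frame(sample_id = w$sample_id[1], assay = w$assay[1],
               mean_cp = mean(w$cp),
               sd_cp = if (nrow(w) > 1) sd(w$cp) else NA_real_,
               n_wells = nrow(w), stringsAsFactors = FALSE)
  }))
  agg$outlier <- !is.na(agg$sd_cp) & agg$sd_cp > outlier_sd
  rownames(agg) <- NULL
  agg
}

#' Edited-transcript fraction from the delta-Cp of paired assays
#'
#' The fraction of edited transcripts is `(1 + efficiency)^(cp_total -
#' cp_allele)`; with the default 100% duplication efficiency this is
#' `2^(delta Cp)`. Fractions above 1 (an assay anomaly: the allele assay
#' crossing before the total assay) are clipped to 1 with a warning.
#'
#' @param cp_total mean Cp of the total-transcript assay.
#' @param cp_allele mean Cp of the allele-specific (edited) assay.
#' @param efficiency per-cycle duplication efficiency E (1.0 = perfect
#'   doubling). The default assumes 100% efficiency; pass a measured value
#'   from [efficiency_from_dilution_series()] to opt in to calibration.
#' @return numeric vector of fractions in (0, 1].
#' @export
estimate_editing_fraction <- function(cp_total, cp_allele, efficiency = 1.0) {
  stopifnot(efficiency > 0)
  f <- (1 + efficiency)^(cp_total - cp_allele)
  if (any(f > 1, na.rm = TRUE)) {
    warning("delta Cp > 0 for ", sum(f > 1, na.rm = TRUE),
            " sample(s): fraction clipped to 1 (assay anomaly)")
    f <- pmin(f, 1)
  }
  f
}

#' Per-sample editing estimates from a plate of wells
#'
#' Aggregates replicates and pairs the `TOTAL` and `ALLELE_T` assays per
#' sample before applying [estimate_editing_fraction()].
#'
#' @inheritParams aggregate_replicates
#' @inheritParams estimate_editing_fraction
#' @param total_assay,allele_assay assay labels to pair.
#' @return data.frame with `sample_id`, `mean_cp_total`, `mean_cp_allele`,
#'   `delta_cp`, `fraction`, `n_wells`.
#' @export
editing_estimates <- function(wells, efficiency = 1.0,
                              total_assay = "TOTAL",
                              allele_assay = "ALLELE_T") {
  agg <- aggregate_replicates(wells)
  tot <- agg[agg$assay == total_assay, ]
  alt <- agg[agg$assay == allele_assay, ]
  ids <- intersect(tot$sample_id, alt$sample_id)
  miss <- setdiff(unique(agg$sample_id), ids)
  if (length(miss) > 0)
    stop("sample(s) missing one assay: ", paste(miss, collapse = ", "))
  tot <- tot[match(ids, tot$sample_id), ]
  alt <- alt[match(ids, alt$sample_id), ]
  delta <- tot$mean_cp - alt$mean_cp
  data.frame(sample_id = ids,
             mean_cp_total = tot$mean_cp, mean_cp_allele = alt$mean_cp,
             delta_cp = delta,
             fraction = estimate_editing_fraction(tot$mean_cp, alt$mean_cp,
                                                  efficiency),
             n_wells = tot$n_wells + alt$n_wells,
             stringsAsFactors = FALSE)
}

#' Amplification efficiency from a serial dilution series
#'
#' Fits mean Cp against dilution step by least squares; the per-cycle
#' duplication efficiency is `E = d^(1/slope) - 1` where `d` is the fold
#' dilution per step. A perfect assay on an 8-fold series gains 3 cycles
#' per step (E = 1); 2.8583 cycles per step gives E = 1.07 (107%).
#'
#' @param wells data.frame with columns `cp` and `dilution_step` (integer,
#'   increasing with dilution); replicate rows per step are averaged.
#' @param dilution_factor fold dilution between consecutive steps
#'   (default 8).
#' @return a `standard_curve` list: `dilution_factor`, `cp_by_step`,
#'   `slope_per_step`, `efficiency`, `r2`, `n_steps`.
#' @export
efficiency_from_dilution_series <- function(wells, dilution_factor = 8) {
  if (!all(c("cp", "dilution_step") %in% names(wells)))
    stop("wells must have columns cp and dilution_step")
  wells <- wells[!is.na(wells$cp), , drop = FALSE]
  steps <- sort(unique(wells$dilution_step))
  if (length(steps) < 3) stop("need at least 3 dilution steps")
  mean_cp <- vapply(steps, function(s) mean(wells$cp[wells$dilution_step == s]),
                    numeric(1))
  if (is.unsorted(mean_cp))
    warning("mean Cp not monotone in dilution step; curve may be invalid")
  fit <- lm(mean_cp ~ steps)
  slope <- unname(coef(fit)[2])
  if (slope <= 0) stop("non-positive slope: invalid standard curve")
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((mean_cp - mean(mean_cp))^2)
  structure(
    list(dilution_factor = dilution_factor,
         cp_by_step = data.frame(dilution_step = steps, mean_cp = mean_cp),
         slope_per_step = slope,
         efficiency = dilution_factor^(1 / slope) - 1,
         r2 = 1 - ss_res / ss_tot,
         n_steps = length(steps)),
    class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> %g-fold series, %d steps: %.4f cycles/step, E = %.1f%%, r2 = %.4f\n",
    x$dilution_factor, x$n_steps, x$slope_per_step, 100 * x$efficiency, x$r2))
  invisible(x)
}

#' Allele-specific assay specificity from control templates
#'
#' Characterizes the allele-specific assay from apparent edited fractions
#' measured on pure control templates: the false-positive amplification
#' rate on 100% wild-type template and the recovery on 100% edited
#' template.
#'
#' @param wildtype_fractions apparent fractions on pure wild-type (C)
#'   template.
#' @param edited_fractions apparent fractions on pure edited (T) template.
#' @return a `specificity_profile` list: `false_positive_fraction`,
#'   `recovery`, `n_wildtype_runs`, `n_edited_runs`.
#' @export
specificity_from_controls <- function(wildtype_fractions, edited_fractions) {
  if (length(wildtype_fractions) < 1 || length(edited_fractions) < 1)
    stop("need at least one run per control template")
  fp <- mean(wildtype_fractions)
  rec <- mean(edited_fractions)
  if (!(fp >= 0 && fp < rec && rec <= 1.2))
    stop("invalid profile: need 0 <= false positive < recovery <= 1.2")
  structure(list(false_positive_fraction = fp, recovery = rec,
                 n_wildtype_runs = length(wildtype_fractions),
                 n_edited_runs = length(edited_fractions)),
            class = "specificity_profile")
}

#' Correct an observed editing fraction for assay specificity
#'
#' Optional linear unmixing of the apparent fraction using a
#' [specificity_from_controls()] profile: `true = (observed - fp) /
#' (recovery - fp)`, clipped to \[0, 1\]. Left off by default throughout
#' the package, matching the stringent convention of reporting uncorrected
#' (slightly conservative) estimates.
#'
#' @param observed observed (apparent) fraction(s).
#' @param profile a `specificity_profile`.
#' @return corrected fraction(s) in \[0, 1\].
#' @export
correct_estimate <- function(observed, profile) {
  fp <- profile$false_positive_fraction
  rec <- profile$recovery
  if (!(rec > fp)) stop("invalid profile: recovery must exceed false positive")
  pmin(1, pmax(0, (observed - fp) / (rec - fp)))
}

#' Relative expression by the 2^-ddCt method
#'
#' `fold = 2^-((cp_target_case - cp_ref_case) - (cp_target_ctrl -
#' cp_ref_ctrl))`, with the reference assay a housekeeping gene (e.g.
#' beta-2 microglobulin).
#'
#' @param cp_target_case,cp_ref_case mean Cp of the target and reference
#'   genes in the case condition.
#' @param cp_target_ctrl,cp_ref_ctrl the same in the control condition.
#' @return fold change (1 = no change).
#' @export
ddct_relative_expression <- function(cp_target_case, cp_ref_case,
                                     cp_target_ctrl, cp_ref_ctrl) {
  ddct <- (cp_target_case - cp_ref_case) - (cp_target_ctrl - cp_ref_ctrl)
  2^(-ddct)
}
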