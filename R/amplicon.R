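#' Screen an amplicon tally for transcript variants
#'
#' Reports one call per (position, non-reference base) whose frequency
#' strictly exceeds `threshold` at depth of at least `min_depth`.
#' Ambiguous calls never produce variants. The strict-inequality boundary
#' is decided by exact integer arithmetic (counts scaled against the
#' threshold expressed in millionths), so a variant at exactly the
#' threshold is never reported regardless of floating-point rounding.
#'
#' @param tally a `base_call_tally` over the amplicon's CDS span.
#' @param model a [gene_model()].
#' @param threshold reporting frequency threshold (default 0.10, i.e. the
#'   ">10%" rule); must be expressible in millionths.
#' @param min_depth minimum filtered depth for a position to be screened
#'   (default 100).
#' @return data.frame of calls: `cds_pos`, `ref`, `alt`, `alt_count`,
#'   `depth`, `fraction`, `canonical_class`.
#' @export
call_variants <- function(tally, model, threshold = 0.10, min_depth = 100L) {
  if (threshold < 0 || threshold >= 1) stop("threshold must be in [0, 1)")
  thr_ppm <- round(threshold * 1e6)
  if (abs(thr_ppm - threshold * 1e6) > 1e-6)
    stop("threshold must be expressible in millionths")
  calls <- list()
  for (i in seq_len(nrow(tally))) {
    depth <- tally$depth[i]
    if (depth < min_depth) next
    ref <- tally$ref[i]
    for (alt in setdiff(BASES, ref)) {
      cnt <- tally[[alt]][i]
      # strict fraction > threshold, exact in integer arithmetic
      if (cnt * 1e6 > thr_ppm * depth) {
        calls[[length(calls) + 1L]] <- data.frame(
          cds_pos = tally$cds_pos[i], ref = ref, alt = alt,
          alt_count = cnt, depth = depth, fraction = cnt / depth,
          canonical_class = classify_canonical(ref, alt),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(calls) == 0) {
    return(data.frame(cds_pos = integer(0), ref = character(0),
                      alt = character(0), alt_count = integer(0),
                      depth = integer(0), fraction = numeric(0),
                      canonical_class = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, calls)
}

#' Classify a substitution as a canonical RNA-editing class
#'
#' In transcript orientation, A-to-G marks A-to-I editing and C-to-T marks
#' C-to-U editing; the remaining 10 ordered base pairs are non-canonical.
#' Antisense changes are deliberately not folded in: amplicons derive from
#' sense transcripts.
#'
#' @param ref,alt reference and alternative bases (transcript
#'   orientation), vectorized.
#' @return character vector: `"A_to_G"`, `"C_to_T"` or `"non_canonical"`.
#' @export
classify_canonical <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(!(ref %in% BASES) | !(alt %in% BASES)))
    stop("bases must be A/C/G/T")
  if (any(ref == alt)) stop("ref == alt (no-op)")
  ifelse(ref == "A" & alt == "G", "A_to_G",
         ifelse(ref == "C" & alt == "T", "C_to_T", "non_canonical"))
}

#' Compare sequencing-based and qPCR-based editing estimates
#'
#' For each pair the relative excess of the sequencing estimate over the
#' qPCR estimate is `seq/qpcr - 1`. Both the arithmetic mean of the
#' per-pair excesses and the excess of the means (ratio of means - 1) are
#' reported, since "X% higher on average" is ambiguous between the two.
#' Pairs with a zero qPCR fraction are skipped with a warning.
#'
#' @param qpcr_fraction,seq_fraction paired editing estimates (any common
#'   scale: proportions or percent).
#' @return a `method_comparison` list: `pairs` (data.frame with per-pair
#'   `relative_excess`), `mean_relative_excess`, `ratio_of_means_excess`,
#'   `n_used`.
#' @export
compare_methods <- function(qpcr_fraction, seq_fraction) {
  if (length(qpcr_fraction) != length(seq_fraction))
    stop("inputs must be paired")
  keep <- qpcr_fraction > 0
  if (any(!keep))
    warning(sum(!keep), " pair(s) with zero qPCR fraction skipped")
  q <- qpcr_fraction[keep]; s <- seq_fraction[keep]
  if (length(q) == 0) stop("no usable pairs")
  excess <- s / q - 1
  structure(
    list(pairs = data.frame(qpcr_fraction = q, seq_fraction = s,
                            relative_excess = excess),
         mean_relative_excess = mean(excess),
         ratio_of_means_excess = mean(s) / mean(q) - 1,
         n_used = length(q)),
    class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf(
    "<method_comparison> n = %d: mean per-pair excess %.1f%%, ratio-of-means excess %.1f%%\n",
    x$n_used, 100 * x$mean_relative_excess, 100 * x$ratio_of_means_excess))
  invisible(x)
}
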