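#' Read filtering configuration for pileup tallies
#'
#' Approximates the default filtering of a samtools-style pileup: a base
#' quality floor of 13, no mapping-quality floor, and exclusion of
#' duplicate and secondary/supplementary alignment records. Per-base
#' alignment-quality recalibration (BAQ) is not reimplemented; the quality
#' floor is the documented approximation.
#'
#' @param min_base_quality Phred floor for A/C/G/T base calls (default 13).
#'   N calls count as "ambiguous" regardless of their quality.
#' @param min_mapping_quality Phred floor for alignment MAPQ (default 0).
#' @param exclude_duplicates drop reads flagged as PCR/optical duplicates.
#' @param exclude_secondary_supplementary drop secondary and supplementary
#'   alignment records.
#' @param collapse_mate_overlap when `TRUE`, bases where both mates of a
#'   read pair overlap the same position are counted once (first record
#'   wins). Default `FALSE`: every alignment record is counted
#'   independently.
#' @return a `read_filter_config` list.
#' @export
read_filter_config <- function(min_base_quality = 13L,
                               min_mapping_quality = 0L,
                               exclude_duplicates = TRUE,
                               exclude_secondary_supplementary = TRUE,
                               collapse_mate_overlap = FALSE) {
  stopifnot(min_base_quality >= 0, min_mapping_quality >= 0)
  structure(list(min_base_quality = as.integer(min_base_quality),
                 min_mapping_quality = as.integer(min_mapping_quality),
                 exclude_duplicates = isTRUE(exclude_duplicates),
                 exclude_secondary_supplementary =
                   isTRUE(exclude_secondary_supplementary),
                 collapse_mate_overlap = isTRUE(collapse_mate_overlap)),
            class = "read_filter_config")
}

#' Tally per-CDS-position base calls from aligned reads
#'
#' Walks every filter-passing aligned base over the model's CDS and counts
#' it in exactly one of five categories (A, C, G, T, ambiguous), always in
#' transcript orientation: for minus-strand genes plus-strand read bases
#' are complemented. N calls, deletions and reference skips overlapping a
#' CDS position are counted as "ambiguous"; A/C/G/T calls below the base
#' quality floor are dropped.
#'
#' @param alignments path to a BAM file or an uncompressed SAM file (SAM is
#'   converted on the fly). If a BAM index (.bai) is present only the CDS
#'   region is read.
#' @param model a [gene_model()].
#' @param filters a [read_filter_config()].
#' @return a `base_call_tally` data.frame with one row per CDS position:
#'   `cds_pos`, `gpos` (0-based genomic), `ref` (transcript orientation),
#'   counts `A`, `C`, `G`, `T`, `ambiguous` and their sum `depth`.
#' @export
tally_from_alignments <- function(alignments, model,
                                  filters = read_filter_config()) {
  bam <- ensure_bam(alignments)
  header_targets <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!model$chrom %in% names(header_targets))
    stop("chromosome ", model$chrom, " absent from alignment header")
  flag <- Rsamtools::scanBamFlag(
    isDuplicate = if (filters$exclude_duplicates) FALSE else NA,
    isSecondaryAlignment =
      if (filters$exclude_secondary_supplementary) FALSE else NA,
    isSupplementaryAlignment =
      if (filters$exclude_secondary_supplementary) FALSE else NA,
    isUnmappedQuery = FALSE)
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual")
  use_index <- file.exists(paste0(bam, ".bai"))
  if (use_index) {
    spans <- model$cds_spans
    which <- GenomicRanges::GRanges(
      model$chrom,
      IRanges::IRanges(min(spans[, 1]) + 1L, max(spans[, 2])))
    param <- Rsamtools::ScanBamParam(flag = flag, what = what, which = which)
    rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  } else {
    param <- Rsamtools::ScanBamParam(flag = flag, what = what)
    rec <- Rsamtools::scanBam(bam, param = param)[[1]]
    on_chrom <- !is.na(rec$rname) & as.character(rec$rname) == model$chrom
    rec <- lapply(rec, `[`, on_chrom)
  }
  tally_records(rec, model, filters)
}

ensure_bam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = TRUE)
  } else {
    path
  }
}

# core per-base walk over scanBam record list
tally_records <- function(rec, model, filters) {
  keep <- rec$mapq >= filters$min_mapping_quality | is.na(rec$mapq)
  rec <- lapply(rec, `[`, keep)
  n <- length(rec$pos)
  gmap <- cds_genomic_positions(model)        # transcript order
  cds_of_gpos <- integer(0)
  tal <- matrix(0L, nrow = cds_length(model), ncol = 5,
                dimnames = list(NULL, c("A", "C", "G", "T", "ambiguous")))
  if (n > 0) {
    ops <- GenomicAlignments::explodeCigarOps(rec$cigar)
    lens <- GenomicAlignments::explodeCigarOpLengths(rec$cigar)
    nop <- lengths(ops)
    op <- unlist(ops)
    len <- unlist(lens)
    ridx <- rep.int(seq_len(n), nop)
    consumes_ref <- op %in% c("M", "=", "X", "D", "N")
    consumes_query <- op %in% c("M", "=", "X", "I", "S")
    # per-op ref/query start offsets within each read
    ref_off <- ave_cumsum(ifelse(consumes_ref, len, 0L), ridx)
    q_off <- ave_cumsum(ifelse(consumes_query, len, 0L), ridx)
    ref_start <- rec$pos[ridx] - 1L + ref_off    # 0-based
    q_start <- 1L + q_off

    # --- aligned bases (M/=/X) ---
    mi <- which(op %in% c("M", "=", "X"))
    gpos <- rep.int(ref_start[mi], len[mi]) + sequence(len[mi]) - 1L
    qidx <- rep.int(q_start[mi], len[mi]) + sequence(len[mi]) - 1L
    bidx <- rep.int(ridx[mi], len[mi])
    cpos <- match(gpos, gmap)
    inside <- !is.na(cpos)
    if (any(inside)) {
      cpos <- cpos[inside]
      qidx <- qidx[inside]
      bidx <- bidx[inside]
      seqs <- strsplit(as.character(rec$seq), "", fixed = TRUE)
      quals <- decode_quals(rec$qual)
      base <- unlist(seqs, use.names = FALSE)[
        qidx + rep_offsets(lengths(seqs))[bidx]]
      qual <- unlist(quals, use.names = FALSE)[
        qidx + rep_offsets(lengths(quals))[bidx]]
      if (filters$collapse_mate_overlap) {
        key <- paste(rec$qname[bidx], cpos)
        first <- !duplicated(key)
        cpos <- cpos[first]; base <- base[first]; qual <- qual[first]
      }
      is_n <- !(base %in% BASES)
      pass <- is_n | qual >= filters$min_base_quality
      cpos <- cpos[pass]; base <- base[pass]; is_n <- is_n[pass]
      if (model$strand == "-")
        base[!is_n] <- complement_base(base[!is_n])
      cat5 <- ifelse(is_n, "ambiguous", base)
      tab <- table(factor(cpos, levels = seq_len(cds_length(model))),
                   factor(cat5, levels = colnames(tal)))
      tal <- tal + unclass(tab)
    }

    # --- deletions and reference skips over CDS positions -> ambiguous ---
    di <- which(op %in% c("D", "N"))
    if (length(di) > 0) {
      # only intersections with CDS spans matter; expand per-base there
      amb <- amb_positions(ref_start[di], len[di], model$cds_spans)
      if (length(amb) > 0) {
        cposa <- match(amb, gmap)
        cposa <- cposa[!is.na(cposa)]
        if (length(cposa) > 0) {
          cnt <- table(factor(cposa, levels = seq_len(cds_length(model))))
          tal[, "ambiguous"] <- tal[, "ambiguous"] + as.integer(cnt)
        }
      }
    }
  }
  out <- data.frame(cds_pos = seq_len(cds_length(model)),
                    gpos = gmap, ref = cds_bases(model),
                    tal, check.names = FALSE, stringsAsFactors = FALSE)
  out$depth <- out$A + out$C + out$G + out$T + out$ambiguous
  class(out) <- c("base_call_tally", "data.frame")
  out
}

# exclusive cumulative sum within consecutive groups: offset of each op's
# start relative to its read's first op
ave_cumsum <- function(x, group) {
  cs <- cumsum(x)
  start_idx <- which(!duplicated(group))
  grp_sizes <- diff(c(start_idx, length(x) + 1L))
  offset <- rep.int(cs[start_idx] - x[start_idx], grp_sizes)
  as.integer(cs - x - offset)
}

# flat-index offsets for ragged list unlisting
rep_offsets <- function(lens) {
  c(0L, cumsum(lens)[-length(lens)])
}

# Phred+33 decoding; works for character vectors and XStringSet quals
decode_quals <- function(qual) {
  lapply(as.character(qual), function(q) utf8ToInt(q) - 33L)
}

# 0-based genomic positions of the intersection of (start, start+len) ops
# with CDS spans
amb_positions <- function(starts, lens, spans) {
  out <- integer(0)
  for (i in seq_along(starts)) {
    s <- starts[i]; e <- starts[i] + lens[i]   # half-open
    for (j in seq_len(nrow(spans))) {
      lo <- max(s, spans[j, 1]); hi <- min(e, spans[j, 2])
      if (hi > lo) out <- c(out, seq.int(lo, hi - 1L))
    }
  }
  out
}

#' Editing fraction at a single CDS site
#'
#' @param tally a `base_call_tally` from [tally_from_alignments()] or
#'   [simulate_tally()].
#' @param site 1-based CDS position.
#' @param edited_base the base read from edited molecules (for C-to-U
#'   editing, `"T"`).
#' @param include_ambiguous_in_depth ambiguous calls are one of the five
#'   tally categories and are counted in the depth denominator by default;
#'   set `FALSE` to restrict the denominator to A/C/G/T calls.
#' @return list with `fraction`, `edited_count` and `depth`. Depth 0 yields
#'   `fraction = NA` with a warning.
#' @export
site_fraction <- function(tally, site, edited_base = "T",
                          include_ambiguous_in_depth = TRUE) {
  edited_base <- match.arg(toupper(edited_base), BASES)
  row <- tally[tally$cds_pos == site, , drop = FALSE]
  if (nrow(row) != 1) stop("site ", site, " not present in tally")
  depth <- row$A + row$C + row$G + row$T +
    if (include_ambiguous_in_depth) row$ambiguous else 0L
  edited <- row[[edited_base]]
  if (depth == 0) {
    warning("site ", site, " has zero filtered depth; fraction undefined")
    return(list(fraction = NA_real_, edited_count = 0L, depth = 0L))
  }
  list(fraction = edited / depth, edited_count = as.integer(edited),
       depth = as.integer(depth))
}

#' Pooled background error fraction over same-reference-base positions
#'
#' Pools edited-base and total counts over every CDS position whose
#' transcript-orientation reference base equals `ref_base` (e.g. the 213
#' C-bearing positions of the SDHB CDS), forming the null against which a
#' candidate editing site is tested.
#'
#' @inheritParams site_fraction
#' @param model a [gene_model()].
#' @param ref_base reference base defining the pool (default `"C"`).
#' @param include_query_site keep the query site in the pool (default
#'   `TRUE`, matching a pool over "any" same-base position); set `FALSE`
#'   and supply `site` for a cleaner null.
#' @param site the query site (needed when `include_query_site = FALSE`).
#' @param min_depth positions with filtered depth below this are excluded.
#' @return list with `fraction`, `edited_count`, `depth` and `n_positions`.
#' @export
background_fraction <- function(tally, model, ref_base = "C",
                                edited_base = "T",
                                include_query_site = TRUE, site = NULL,
                                min_depth = 1L,
                                include_ambiguous_in_depth = TRUE) {
  ref_base <- match.arg(toupper(ref_base), BASES)
  edited_base <- match.arg(toupper(edited_base), BASES)
  pool <- tally[tally$ref == ref_base, , drop = FALSE]
  if (!include_query_site) {
    if (is.null(site))
      stop("site must be given when include_query_site = FALSE")
    pool <- pool[pool$cds_pos != site, , drop = FALSE]
  }
  depth <- pool$A + pool$C + pool$G + pool$T +
    if (include_ambiguous_in_depth) pool$ambiguous else 0L
  pool <- pool[depth >= min_depth, , drop = FALSE]
  depth <- depth[depth >= min_depth]
  if (nrow(pool) == 0) {
    warning("no qualifying background position with depth >= ", min_depth)
    return(list(fraction = NA_real_, edited_count = 0L, depth = 0L,
                n_positions = 0L))
  }
  edited <- sum(pool[[edited_base]])
  list(fraction = edited / sum(depth), edited_count = as.integer(edited),
       depth = as.integer(sum(depth)), n_positions = nrow(pool))
}

#' Yates-corrected chi-square test for a 2x2 table
#'
#' \deqn{\chi^2 = N(|ad-bc| - N/2)^2 / ((a+b)(c+d)(a+c)(b+d))}
#' clipped to 0 when \eqn{|ad-bc| \le N/2}; the two-tailed p-value comes
#' from the chi-square distribution with 1 df.
#'
#' @param a,b,c,d cell counts (site edited / site other, background edited
#'   / background other).
#' @return list with `chi2` and `p_value`. A zero marginal yields `NA`s
#'   with a warning (undefined test).
#' @export
yates_chi_square <- function(a, b, c, d) {
  # double precision: products like a*d overflow 32-bit integers at
  # transcriptome-scale background depths
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- sum(counts)
  if (n == 0) stop("empty table")
  marg <- c(a + b, c + d, a + c, b + d)
  if (any(marg == 0)) {
    warning("zero marginal: chi-square undefined")
    return(list(chi2 = NA_real_, p_value = NA_real_))
  }
  delta <- abs(a * d - b * c)
  chi2 <- if (delta <= n / 2) 0 else n * (delta - n / 2)^2 / prod(marg)
  list(chi2 = chi2, p_value = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Call editing at a site against the pooled background null
#'
#' Composes [site_fraction()], [background_fraction()] and
#' [yates_chi_square()] into a single site-vs-background editing call. The
#' 2x2 table rows are (site edited, site other) and (background edited,
#' background other).
#'
#' @inheritParams background_fraction
#' @param site 1-based CDS position of the candidate site.
#' @param snp_positions known SNP genomic positions (1-based) used to flag
#'   candidate sites that coincide with polymorphisms; see
#'   [read_snp_positions()].
#' @return a `site_editing_call` list with the site and background counts
#'   and fractions, `chi2`, `p_value` and `snp_overlap`.
#' @export
call_editing_site <- function(tally, model, site, edited_base = "T",
                              snp_positions = integer(0),
                              include_query_site = TRUE, min_depth = 1L,
                              include_ambiguous_in_depth = TRUE) {
  ref_base <- cds_bases(model)[site]
  sf <- site_fraction(tally, site, edited_base,
                      include_ambiguous_in_depth = include_ambiguous_in_depth)
  bg <- background_fraction(tally, model, ref_base, edited_base,
                            include_query_site = include_query_site,
                            site = site, min_depth = min_depth,
                            include_ambiguous_in_depth =
                              include_ambiguous_in_depth)
  test <- if (!is.na(sf$fraction) && !is.na(bg$fraction)) {
    yates_chi_square(sf$edited_count, sf$depth - sf$edited_count,
                     bg$edited_count, bg$depth - bg$edited_count)
  } else list(chi2 = NA_real_, p_value = NA_real_)
  gpos1 <- map_cds_to_genome(model, site)$gpos + 1L
  structure(
    list(site = site, ref_base = ref_base, edited_base = edited_base,
         genomic_pos = gpos1,
         edited_count = sf$edited_count, site_depth = sf$depth,
         site_fraction = sf$fraction,
         background_edited = bg$edited_count,
         background_depth = bg$depth,
         background_fraction = bg$fraction,
         chi2 = test$chi2, p_value = test$p_value,
         snp_overlap = gpos1 %in% as.integer(snp_positions)),
    class = "site_editing_call")
}

#' @export
print.site_editing_call <- function(x, ...) {
  cat(sprintf(
    "<site_editing_call> c.%d%s>%s  %d/%d = %.4g  background %d/%d = %.4g\n  chi2 = %.4g, p = %.3g, snp_overlap = %s\n",
    x$site, x$ref_base, x$edited_base, x$edited_count, x$site_depth,
    x$site_fraction, x$background_edited, x$background_depth,
    x$background_fraction, x$chi2, x$p_value, x$snp_overlap))
  invisible(x)
}

#' Write / read a per-position tally TSV
#'
#' Columns: `cds_pos`, `genomic_pos` (1-based, VCF convention), `ref`,
#' `A`, `C`, `G`, `T`, `ambiguous`, `depth`.
#'
#' @param tally a `base_call_tally`.
#' @param path file path.
#' @return `write_tally` returns `path` invisibly; `read_tally` returns a
#'   `base_call_tally` data.frame.
#' @export
write_tally <- function(tally, path) {
  out <- data.frame(cds_pos = tally$cds_pos, genomic_pos = tally$gpos + 1L,
                    ref = tally$ref, A = tally$A, C = tally$C, G = tally$G,
                    T = tally$T, ambiguous = tally$ambiguous,
                    depth = tally$depth, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tally
#' @export
read_tally <- function(path) {
  x <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(cds_pos = x$cds_pos, gpos = x$genomic_pos - 1L,
                    ref = x$ref, A = x$A, C = x$C, G = x$G, T = x$T,
                    ambiguous = x$ambiguous, depth = x$depth,
                    check.names = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("base_call_tally", "data.frame")
  out
}

#' Read known SNP positions from a VCF or two-column TSV
#'
#' Used to flag candidate editing sites that coincide with documented
#' polymorphisms. For VCF input the vcfR reader is used; TSV input must
#' have columns chrom and 1-based pos (header optional).
#'
#' @param path path to a `.vcf` file or a 2-column TSV.
#' @param chrom optional chromosome filter.
#' @return integer vector of 1-based positions.
#' @export
read_snp_positions <- function(path, chrom = NULL) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("reading VCF requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    df <- data.frame(chrom = vcfR::getCHROM(v),
                     pos = as.integer(vcfR::getPOS(v)))
  } else {
    first <- readLines(path, n = 1)
    has_header <- grepl("[A-Za-z]", strsplit(first, "\t")[[1]][2])
    df <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
    df <- data.frame(chrom = as.character(df[[1]]), pos = as.integer(df[[2]]))
  }
  if (!is.null(chrom)) df <- df[df$chrom == chrom, , drop = FALSE]
  df$pos
}
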