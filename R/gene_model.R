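#' Strand-aware coding gene model
#'
#' A `gene_model` ties a CDS (c.) coordinate system to genomic coordinates
#' and sequence. Genomic intervals are 0-based half-open internally; c.
#' positions are 1-based from the first base of the start codon (HGVS
#' convention). For minus-strand genes `cds_seq` is the reverse complement
#' of the plus-strand genomic bases over the CDS spans read in descending
#' genomic order, i.e. it is always in transcript orientation.
#'
#' @param gene_id character scalar identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix (start, end) of 0-based half-open exon
#'   intervals, sorted ascending and non-overlapping.
#' @param cds_spans two-column matrix of CDS sub-intervals; each must lie
#'   within an exon.
#' @param cds_seq CDS nucleotide sequence in transcript orientation
#'   (A/C/G/T only; length divisible by 3). Ambiguity codes are rejected.
#' @param chrom_len optional chromosome length (used when emitting SAM).
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds_spans, cds_seq,
                       chrom_len = NULL) {
  exons <- as_span_matrix(exons, "exons")
  cds_spans <- as_span_matrix(cds_spans, "cds_spans")
  if (!strand %in% c("+", "-"))
    stop("strand must be \"+\" or \"-\"")
  cds_seq <- toupper(as.character(cds_seq))
  chars <- strsplit(cds_seq, "", fixed = TRUE)[[1]]
  if (!all(chars %in% BASES))
    stop("cds_seq contains non-A/C/G/T characters (ambiguity codes are rejected)")
  if (sum(cds_spans[, 2] - cds_spans[, 1]) != nchar(cds_seq))
    stop("cds_seq length does not match the summed CDS span width")
  if (nchar(cds_seq) %% 3L != 0L)
    stop("CDS length must be divisible by 3")
  # every CDS span must lie within one exon
  for (i in seq_len(nrow(cds_spans))) {
    hit <- exons[, 1] <= cds_spans[i, 1] & exons[, 2] >= cds_spans[i, 2]
    if (!any(hit))
      stop("CDS span ", i, " is not contained in any exon")
  }
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         exons = exons, cds_spans = cds_spans, cds_seq = cds_seq,
         chrom_len = if (is.null(chrom_len)) max(exons[, 2]) + 1000L
                     else as.integer(chrom_len)),
    class = "gene_model")
}

as_span_matrix <- function(x, what) {
  if (is.data.frame(x)) x <- as.matrix(x[, 1:2])
  if (is.vector(x) && length(x) == 2) x <- matrix(x, ncol = 2)
  x <- matrix(as.integer(x), ncol = 2,
              dimnames = list(NULL, c("start", "end")))
  if (any(x[, 2] <= x[, 1])) stop(what, ": empty or inverted interval")
  if (is.unsorted(x[, 1], strictly = TRUE) && nrow(x) > 1)
    stop(what, ": intervals must be sorted ascending by start")
  if (nrow(x) > 1 && any(x[-1, 1] < x[-nrow(x), 2]))
    stop(what, ": intervals must not overlap")
  x
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s  %s:%s  %d exon(s), CDS %d bp (%d codons)\n",
              x$gene_id, x$chrom, x$strand, nrow(x$exons),
              nchar(x$cds_seq), nchar(x$cds_seq) %/% 3L))
  invisible(x)
}

cds_length <- function(model) nchar(model$cds_seq)

# 0-based genomic position of every CDS base, in transcript order
cds_genomic_positions <- function(model) {
  spans <- model$cds_spans
  per_span <- lapply(seq_len(nrow(spans)),
                     function(i) seq.int(spans[i, 1], spans[i, 2] - 1L))
  if (model$strand == "+") {
    as.integer(unlist(per_span))
  } else {
    as.integer(unlist(rev(lapply(per_span, rev))))
  }
}

cds_bases <- function(model) strsplit(model$cds_seq, "", fixed = TRUE)[[1]]

#' Map CDS (c.) positions to genomic coordinates
#'
#' @param model a [gene_model()].
#' @param pos integer vector of 1-based CDS positions.
#' @return data.frame with `cds_pos`, `gpos` (0-based genomic position),
#'   `base_plus` (plus-strand reference base) and `base_transcript`
#'   (transcript-orientation reference base). For plus-strand genes the two
#'   bases are identical; for minus-strand genes they are complements.
#' @export
map_cds_to_genome <- function(model, pos) {
  pos <- as.integer(pos)
  if (any(pos < 1L | pos > cds_length(model)))
    stop("CDS position out of range 1..", cds_length(model))
  gmap <- cds_genomic_positions(model)
  tb <- cds_bases(model)[pos]
  pb <- if (model$strand == "+") tb else complement_base(tb)
  data.frame(cds_pos = pos, gpos = gmap[pos],
             base_plus = pb, base_transcript = tb,
             stringsAsFactors = FALSE)
}

#' Map genomic positions to CDS (c.) positions
#'
#' Inverse of [map_cds_to_genome()] on its image; positions not covered by
#' the CDS (introns, UTRs, intergenic) return `NA` ("non-coding").
#'
#' @param model a [gene_model()].
#' @param gpos integer vector of 0-based genomic positions.
#' @param chrom optional chromosome name; an error is raised if it does not
#'   match the model's chromosome.
#' @return integer vector of 1-based CDS positions (`NA` = non-coding).
#' @export
map_genome_to_cds <- function(model, gpos, chrom = NULL) {
  if (!is.null(chrom) && !identical(chrom, model$chrom))
    stop("chromosome ", chrom, " does not match model chromosome ", model$chrom)
  match(as.integer(gpos), cds_genomic_positions(model))
}

#' Count CDS positions carrying a given reference base
#'
#' Counts positions whose transcript-orientation reference base equals
#' `base`; counts over the four bases sum to the CDS length. Used to define
#' the background pool (e.g. the 213 C-bearing positions of the SDHB CDS).
#'
#' @param model a [gene_model()].
#' @param base one of `"A"`, `"C"`, `"G"`, `"T"`.
#' @return integer count.
#' @export
count_base_positions <- function(model, base) {
  base <- match.arg(toupper(base), BASES)
  sum(cds_bases(model) == base)
}

#' Protein consequence of a single-base edit
#'
#' @param model a [gene_model()].
#' @param pos 1-based CDS position of the edit.
#' @param alt the alternative (edited) base, transcript orientation; must
#'   differ from the reference base at `pos`.
#' @return list with `codon_number`, `codon_offset` (1-3), `ref_codon`,
#'   `alt_codon`, `ref_aa`, `alt_aa` and `effect` (one of `"synonymous"`,
#'   `"missense"`, `"nonsense"`).
#' @examples
#' m <- synthetic_sdhb_model()
#' consequence_of_edit(m, 136, "T")  # CGA -> TGA, R46X nonsense
#' @export
consequence_of_edit <- function(model, pos, alt) {
  pos <- as.integer(pos)
  if (pos < 1L || pos > cds_length(model))
    stop("CDS position out of range")
  alt <- match.arg(toupper(alt), BASES)
  bases <- cds_bases(model)
  if (bases[pos] == alt)
    stop("alt base equals the reference base at c.", pos, " (no-op)")
  codon_number <- ceiling(pos / 3)
  codon_offset <- ((pos - 1L) %% 3L) + 1L
  idx <- (codon_number - 1L) * 3L + 1:3
  ref_codon <- paste(bases[idx], collapse = "")
  alt_bases <- bases
  alt_bases[pos] <- alt
  alt_codon <- paste(alt_bases[idx], collapse = "")
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  effect <- if (alt_aa == "*" && ref_aa != "*") "nonsense"
            else if (alt_aa == ref_aa) "synonymous"
            else "missense"
  list(codon_number = codon_number, codon_offset = codon_offset,
       ref_codon = ref_codon, alt_codon = alt_codon,
       ref_aa = ref_aa, alt_aa = alt_aa, effect = effect)
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

#' In-silico restriction digest of an amplicon
#'
#' Cuts `sequence` at every occurrence of `recognition_site`, placing the
#' cut at a fixed offset within the site (default after the first base:
#' Taq1 T^CGA). Overlapping occurrences are resolved left-to-right. Zero
#' occurrences yield a single full-length fragment.
#'
#' @param sequence amplicon nucleotide string.
#' @param recognition_site recognition sequence (default `"TCGA"`).
#' @param cut_offset 0-based offset of the cut within each site occurrence
#'   (default 1, i.e. after the first base).
#' @return list with `amplicon_length`, `cut_positions` (0-based offsets)
#'   and `fragment_lengths` (bp, summing to `amplicon_length`).
#' @export
digest_amplicon <- function(sequence, recognition_site = "TCGA",
                            cut_offset = 1L) {
  sequence <- toupper(as.character(sequence))
  site <- toupper(as.character(recognition_site))
  if (nchar(site) == 0) stop("recognition_site must be non-empty")
  if (cut_offset < 0 || cut_offset > nchar(site))
    stop("cut_offset must lie within the recognition site")
  len <- nchar(sequence)
  starts <- site_starts(sequence, site)
  # resolve overlaps left-to-right
  keep <- integer(0)
  last_end <- -1L
  for (s in starts) {
    if (s > last_end) {
      keep <- c(keep, s)
      last_end <- s + nchar(site) - 1L
    }
  }
  cuts <- keep - 1L + as.integer(cut_offset)  # 0-based cut offsets
  cuts <- cuts[cuts > 0L & cuts < len]
  frags <- diff(c(0L, cuts, len))
  list(amplicon_length = len, cut_positions = cuts,
       fragment_lengths = as.integer(frags))
}

# all (possibly overlapping) 1-based start positions of `site` in `sequence`
site_starts <- function(sequence, site) {
  if (nchar(sequence) < nchar(site)) return(integer(0))
  m <- Biostrings::matchPattern(site, Biostrings::DNAString(sequence))
  sort(BiocGenerics::start(m))
}

#' Does a single-base edit destroy a restriction site?
#'
#' `TRUE` iff at least one occurrence of `recognition_site` overlapping
#' `pos` in the reference sequence is absent after substituting `alt`.
#' Creation of a new site elsewhere does not affect the result (only
#' destruction is tested).
#'
#' @param sequence reference nucleotide string.
#' @param pos 1-based position of the edit within `sequence`.
#' @param alt substituted base.
#' @param recognition_site recognition sequence (default `"TCGA"`).
#' @return logical scalar.
#' @export
edit_destroys_site <- function(sequence, pos, alt, recognition_site = "TCGA") {
  sequence <- toupper(as.character(sequence))
  site <- toupper(recognition_site)
  pos <- as.integer(pos)
  if (pos < 1L || pos > nchar(sequence)) stop("pos outside sequence")
  w <- nchar(site)
  ref_hits <- site_starts(sequence, site)
  ref_hits <- ref_hits[ref_hits <= pos & pos <= ref_hits + w - 1L]
  if (length(ref_hits) == 0) return(FALSE)
  edited <- sequence
  substr(edited, pos, pos) <- toupper(alt)
  new_hits <- site_starts(edited, site)
  any(!(ref_hits %in% new_hits))
}

#' Build a gene model from a BED12-like record plus a reference FASTA
#'
#' Reads the first record of a BED12 file (chrom, chromStart, chromEnd,
#' name, score, strand, thickStart, thickEnd, itemRgb, blockCount,
#' blockSizes, blockStarts) and extracts the CDS sequence (the thick
#' region) from `fasta_file`. Coordinates are BED-native 0-based half-open.
#'
#' @param bed_file path to a BED12 TSV (no header).
#' @param fasta_file path to a FASTA file containing the chromosome.
#' @param gene_id optional override for the gene identifier (default: the
#'   BED name column).
#' @return a [gene_model()].
#' @export
read_gene_model_bed <- function(bed_file, fasta_file, gene_id = NULL) {
  bed <- read.delim(bed_file, header = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#")
  if (ncol(bed) < 12) stop("BED12 record requires 12 columns")
  r <- bed[1, ]
  chrom <- as.character(r[[1]])
  chrom_start <- as.integer(r[[2]])
  strand <- as.character(r[[6]])
  thick <- c(as.integer(r[[7]]), as.integer(r[[8]]))
  sizes <- as.integer(strsplit(as.character(r[[11]]), ",")[[1]])
  starts <- as.integer(strsplit(as.character(r[[12]]), ",")[[1]])
  exons <- cbind(chrom_start + starts, chrom_start + starts + sizes)
  cds_spans <- intersect_spans(exons, thick)
  genome <- Biostrings::readDNAStringSet(fasta_file)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (!chrom %in% names(genome))
    stop("chromosome ", chrom, " not found in ", fasta_file)
  seq <- genome[[chrom]]
  cds_seq <- extract_transcript_seq(seq, cds_spans, strand)
  gene_model(gene_id = if (is.null(gene_id)) as.character(r[[4]]) else gene_id,
             chrom = chrom, strand = strand, exons = exons,
             cds_spans = cds_spans, cds_seq = cds_seq,
             chrom_len = length(seq))
}

intersect_spans <- function(spans, interval) {
  s <- pmax(spans[, 1], interval[1])
  e <- pmin(spans[, 2], interval[2])
  keep <- e > s
  if (!any(keep)) stop("CDS interval does not intersect any exon")
  cbind(s[keep], e[keep])
}

# transcript-orientation sequence over 0-based half-open spans of a
# plus-strand chromosome sequence (DNAString or character)
extract_transcript_seq <- function(chrom_seq, spans, strand) {
  chrom_seq <- Biostrings::DNAString(as.character(chrom_seq))
  parts <- vapply(seq_len(nrow(spans)), function(i) {
    as.character(Biostrings::subseq(chrom_seq, spans[i, 1] + 1L, spans[i, 2]))
  }, character(1))
  s <- paste(parts, collapse = "")
  if (strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

#' Write / read a self-contained gene-model JSON fixture
#'
#' The JSON bundles identifiers, strand, exon and CDS intervals (0-based
#' half-open) and the transcript-orientation CDS sequence, so tests can
#' round-trip models without FASTA/BED files.
#'
#' @param model a [gene_model()].
#' @param path file path.
#' @return `write_gene_model_json` returns `path` invisibly;
#'   `read_gene_model_json` returns a [gene_model()].
#' @export
write_gene_model_json <- function(model, path) {
  jsonlite::write_json(
    list(gene_id = model$gene_id, chrom = model$chrom, strand = model$strand,
         chrom_len = model$chrom_len,
         exons = unname(apply(model$exons, 1, as.list)),
         cds_spans = unname(apply(model$cds_spans, 1, as.list)),
         cds_seq = model$cds_seq),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gene_model_json
#' @export
read_gene_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(v) {
    if (is.data.frame(v)) as.matrix(v[, c("start", "end")])
    else if (is.matrix(v)) v
    else matrix(unlist(v), ncol = 2, byrow = TRUE)
  }
  gene_model(x$gene_id, x$chrom, x$strand, as_mat(x$exons),
             as_mat(x$cds_spans), x$cds_seq, chrom_len = x$chrom_len)
}
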