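#' Configuration for simulated pileups and read sets
#'
#' The forward model: each read originates from an edited molecule with
#' probability `f` independently at every edit site it covers; sequencing
#' errors are then applied i.i.d. per base at rate `error_rate`, uniformly
#' over the three wrong bases (rate/3 each).
#'
#' @param model a [gene_model()].
#' @param depth target per-position depth (reads for
#'   [simulate_alignments()], exact per-position count for
#'   [simulate_tally()]).
#' @param error_rate per-base sequencing error probability (< 0.1).
#' @param edits named numeric vector: names are 1-based CDS positions,
#'   values the true edited fractions.
#' @param edited_base base produced by the edit (default `"T"`, C-to-U).
#' @param read_length read length in bp (reads only).
#' @param seed mandatory RNG seed; there is no hidden global random state.
#' @return a `pileup_sim_config` list.
#' @export
pileup_sim_config <- function(model, depth = 50L, error_rate = 0.001,
                              edits = numeric(0), edited_base = "T",
                              read_length = 75L, seed) {
  stopifnot(error_rate >= 0, error_rate < 0.1,
            all(edits >= 0), all(edits <= 1))
  if (missing(seed) || is.null(seed))
    stop("seed is a mandatory argument")
  if (length(edits) > 0) {
    pos <- as.integer(names(edits))
    if (any(is.na(pos) | pos < 1 | pos > cds_length(model)))
      stop("edit positions must be named 1-based CDS positions")
  }
  if (read_length > cds_length(model))
    stop("read_length exceeds the CDS length")
  structure(list(model = model, depth = as.integer(depth),
                 error_rate = error_rate, edits = edits,
                 edited_base = match.arg(toupper(edited_base), BASES),
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "pileup_sim_config")
}

# for each erroneous call, one of the 3 wrong bases uniformly
WRONG_BASE <- matrix(c("C", "G", "T",
                       "A", "G", "T",
                       "A", "C", "T",
                       "A", "C", "G"),
                     nrow = 4, byrow = TRUE, dimnames = list(BASES, NULL))

#' Simulate aligned reads over a gene model
#'
#' Draws single-end reads of fixed length uniformly over the CDS (in
#' transcript coordinates), applies per-site editing and uniform
#' sequencing error, and emits them as SAM records in plus-strand genomic
#' orientation regardless of the gene's strand (minus-strand genes yield
#' reverse-complemented read sequences and intron-spanning `N` CIGAR ops
#' where a read crosses an exon junction).
#'
#' @param cfg a [pileup_sim_config()].
#' @param sam_path output SAM path.
#' @param fasta_path optional path to also write the plus-strand reference
#'   chromosome FASTA (requires a model built by [random_gene_model()] or
#'   [synthetic_sdhb_model()], which carry their genome sequence).
#' @return list with `sam` (path), `n_reads`, and `truth`: per edit site
#'   the number of covering reads and of edited molecules, plus the
#'   post-error expected fractions.
#' @export
simulate_alignments <- function(cfg, sam_path, fasta_path = NULL) {
  stopifnot(inherits(cfg, "pileup_sim_config"))
  model <- cfg$model
  lc <- cds_length(model)
  rl <- cfg$read_length
  n_reads <- max(1L, as.integer(round(cfg$depth * lc / rl)))
  with_seed(cfg$seed, {
    tstart <- sample.int(lc - rl + 1L, n_reads, replace = TRUE)
    mat <- read_matrix(model, tstart, rl)
    truth <- apply_edits(mat, tstart, rl, cfg)
    mat <- truth$mat
    mat <- apply_errors(mat, cfg$error_rate)
    writeout <- emit_sam(model, tstart, mat, sam_path)
  })
  if (!is.null(fasta_path)) write_model_fasta(model, fasta_path)
  list(sam = sam_path, n_reads = n_reads, truth = truth$record)
}

# n x read_length matrix of transcript-orientation reference bases
read_matrix <- function(model, tstart, rl) {
  cb <- cds_bases(model)
  idx <- outer(tstart, 0:(rl - 1L), "+")
  matrix(cb[idx], nrow = length(tstart))
}

apply_edits <- function(mat, tstart, rl, cfg) {
  record <- list()
  if (length(cfg$edits) > 0) {
    pos <- as.integer(names(cfg$edits))
    for (k in seq_along(pos)) {
      p <- pos[k]
      cover <- which(tstart <= p & tstart + rl - 1L >= p)
      edited <- cover[runif(length(cover)) < cfg$edits[k]]
      if (length(edited) > 0)
        mat[cbind(edited, p - tstart[edited] + 1L)] <- cfg$edited_base
      record[[as.character(p)]] <- list(
        cds_pos = p, true_fraction = unname(cfg$edits[k]),
        covering_reads = length(cover),
        edited_molecules = length(edited))
    }
  }
  list(mat = mat, record = record)
}

apply_errors <- function(mat, error_rate) {
  if (error_rate <= 0) return(mat)
  hit <- which(runif(length(mat)) < error_rate)
  if (length(hit) > 0) {
    cur <- mat[hit]
    mat[hit] <- WRONG_BASE[cbind(match(cur, BASES),
                                 sample.int(3L, length(hit), replace = TRUE))]
  }
  mat
}

emit_sam <- function(model, tstart, mat, sam_path) {
  rl <- ncol(mat)
  reads_t <- do.call(paste0, lapply(seq_len(rl), function(j) mat[, j]))
  gmap <- cds_genomic_positions(model)
  # POS and CIGAR depend only on the transcript start; compute per distinct
  u <- sort(unique(tstart))
  geom <- lapply(u, function(t) {
    g <- sort(gmap[t:(t + rl - 1L)])
    runs <- split(g, cumsum(c(1L, diff(g) != 1L)))
    mlen <- lengths(runs)
    gaps <- if (length(runs) > 1) {
      vapply(seq_len(length(runs) - 1L), function(i) {
        runs[[i + 1L]][1] - (runs[[i]][mlen[i]] + 1L)
      }, numeric(1))
    } else numeric(0)
    cig <- paste0(mlen[1], "M")
    for (i in seq_along(gaps)) cig <- paste0(cig, gaps[i], "N", mlen[i + 1], "M")
    list(pos = g[1] + 1L, cigar = cig)
  })
  names(geom) <- as.character(u)
  gsel <- geom[as.character(tstart)]
  pos1 <- vapply(gsel, `[[`, numeric(1), "pos")
  cigar <- vapply(gsel, `[[`, character(1), "cigar")
  seqs <- if (model$strand == "-") {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(reads_t)))
  } else reads_t
  qual <- strrep("I", rl)
  lines <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", model$chrom, model$chrom_len),
    sprintf("read%06d\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
            seq_along(tstart), model$chrom, pos1, cigar, seqs, qual))
  writeLines(lines, sam_path)
  invisible(sam_path)
}

write_model_fasta <- function(model, fasta_path) {
  genome <- attr(model, "genome_seq")
  if (is.null(genome))
    stop("model carries no genome sequence; use random_gene_model()/synthetic_sdhb_model()")
  ss <- Biostrings::DNAStringSet(genome)
  names(ss) <- model$chrom
  Biostrings::writeXStringSet(ss, fasta_path)
  invisible(fasta_path)
}

#' Simulate a base-call tally directly (no read emission)
#'
#' Per-position multinomial shortcut marginally equivalent to piling up
#' [simulate_alignments()] output: at an edit site with fraction `f` and
#' error rate `e` the category probabilities are
#' `P(ref) = (1-f)(1-e) + f e/3`, `P(edited) = f(1-e) + (1-f) e/3`, and
#' `e/3` for each remaining base. Depth is exactly `cfg$depth` at every
#' position.
#'
#' @param cfg a [pileup_sim_config()].
#' @return a `base_call_tally` data.frame (ambiguous counts are zero: the
#'   multinomial model has no N calls, deletions or skips).
#' @export
simulate_tally <- function(cfg) {
  stopifnot(inherits(cfg, "pileup_sim_config"))
  model <- cfg$model
  lc <- cds_length(model)
  cb <- cds_bases(model)
  e <- cfg$error_rate
  f <- rep(0, lc)
  alt <- rep(NA_character_, lc)
  if (length(cfg$edits) > 0) {
    p <- as.integer(names(cfg$edits))
    f[p] <- cfg$edits
    alt[p] <- cfg$edited_base
  }
  counts <- with_seed(cfg$seed, {
    t(vapply(seq_len(lc), function(i) {
      pr <- rep(e / 3, 4)
      names(pr) <- BASES
      pr[cb[i]] <- (1 - f[i]) * (1 - e) + f[i] * e / 3
      if (f[i] > 0)
        pr[alt[i]] <- f[i] * (1 - e) + (1 - f[i]) * e / 3
      as.integer(stats::rmultinom(1, cfg$depth, pr))
    }, integer(4)))
  })
  out <- data.frame(cds_pos = seq_len(lc),
                    gpos = cds_genomic_positions(model),
                    ref = cb,
                    A = counts[, 1], C = counts[, 2],
                    G = counts[, 3], T = counts[, 4],
                    ambiguous = 0L, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out$depth <- out$A + out$C + out$G + out$T
  class(out) <- c("base_call_tally", "data.frame")
  out
}

#' Configuration for the allele-specific qPCR forward model
#'
#' Amplification follows a (1+E)-fold-per-cycle model: a well with
#' effective template `T` crosses threshold at
#' `Cp = log(threshold_constant / T) / log(1 + E)` plus Gaussian well
#' noise. The allele-specific assay sees effective template
#' `total * (f * allele_recovery + (1 - f) * allele_fp)`, modelling both
#' incomplete recovery of edited template and false-positive amplification
#' of wild-type template.
#'
#' @param efficiency per-cycle duplication efficiency E.
#' @param threshold_constant template amount at which Cp = 0 (mol);
#'   defaults to 1e-9 so femtomole inputs cross around cycle 20.
#' @param noise_sd Gaussian well noise on the Cp scale (cycles).
#' @param replicates wells per (sample, assay).
#' @param allele_fp apparent fraction amplified from pure wild-type
#'   template (assay false-positive rate).
#' @param allele_recovery apparent fraction recovered from pure edited
#'   template.
#' @param seed mandatory RNG seed.
#' @return a `qpcr_sim_config` list.
#' @export
qpcr_sim_config <- function(efficiency = 1.0, threshold_constant = 1e-9,
                            noise_sd = 0.15, replicates = 2L,
                            allele_fp = 0.0138, allele_recovery = 0.91,
                            seed) {
  stopifnot(efficiency > 0, noise_sd >= 0, replicates >= 1,
            allele_fp >= 0, allele_fp < allele_recovery,
            allele_recovery <= 1.2)
  if (missing(seed) || is.null(seed))
    stop("seed is a mandatory argument")
  structure(list(efficiency = efficiency,
                 threshold_constant = threshold_constant,
                 noise_sd = noise_sd, replicates = as.integer(replicates),
                 allele_fp = allele_fp, allele_recovery = allele_recovery,
                 seed = as.integer(seed)),
            class = "qpcr_sim_config")
}

#' Simulate an allele-specific qPCR plate
#'
#' @param samples data.frame with columns `sample_id`, `total_amount`
#'   (mol, > 0) and `true_fraction` (edited fraction in \[0, 1\]).
#' @param cfg a [qpcr_sim_config()].
#' @return list with `wells` (a plate data.frame usable by
#'   [editing_estimates()]) and `truth` (the input samples plus the
#'   expected apparent fraction `f * recovery + (1 - f) * fp`). Wells whose
#'   effective template is zero get `cp = NA` (no amplification).
#' @export
simulate_qpcr_plate <- function(samples, cfg) {
  stopifnot(inherits(cfg, "qpcr_sim_config"),
            all(c("sample_id", "total_amount", "true_fraction") %in%
                  names(samples)))
  if (any(samples$total_amount <= 0)) stop("template amounts must be > 0")
  if (any(samples$true_fraction < 0 | samples$true_fraction > 1))
    stop("true_fraction must lie in [0, 1]")
  f <- samples$true_fraction
  apparent <- f * cfg$allele_recovery + (1 - f) * cfg$allele_fp
  template <- data.frame(
    sample_id = rep(samples$sample_id, 2),
    assay = rep(c("TOTAL", "ALLELE_T"), each = nrow(samples)),
    template = c(samples$total_amount, samples$total_amount * apparent),
    stringsAsFactors = FALSE)
  wells <- template[rep(seq_len(nrow(template)), each = cfg$replicates), ]
  wells$replicate <- rep(seq_len(cfg$replicates), nrow(template))
  wells$cp <- with_seed(cfg$seed, {
    cp0 <- ifelse(wells$template > 0,
                  log(cfg$threshold_constant / wells$template) /
                    log(1 + cfg$efficiency),
                  NA_real_)
    cp0 + ifelse(is.na(cp0), 0, rnorm(nrow(wells), 0, cfg$noise_sd))
  })
  rownames(wells) <- NULL
  truth <- samples
  truth$apparent_fraction <- apparent
  list(wells = wells[, c("sample_id", "assay", "replicate", "cp", "template")],
       truth = truth)
}

#' Configuration for paired-donor cohort simulation
#'
#' Emulates the structure of a monocyte-enrichment editing study: each
#' donor has a log-normal baseline editing fraction linked positively to
#' its CD14+ monocyte fraction; normoxic culture multiplies it by a day
#' profile peaking on days 5-7, hypoxic culture by a donor-level
#' log-normal multiplier times a profile peaking on day 2; measurements
#' get multiplicative log-normal noise and are clipped to \[0, 1).
#'
#' @param n_donors number of donors.
#' @param days culture days simulated for both conditions.
#' @param baseline_median,baseline_sdlog log-normal baseline editing
#'   (median 0.02 emulates uncultured monocyte-enriched PBMCs).
#' @param hypoxia_multiplier_median,hypoxia_multiplier_sdlog donor-level
#'   hypoxia effect at the day-2 peak (median 9: baseline 2% to ~18%).
#' @param day_profile_normoxia,day_profile_hypoxia per-day multipliers
#'   (days 1-7); normoxia rises to ~5x on days 5-7, hypoxia is expressed
#'   relative to its day-2 peak (= 1).
#' @param cd14_shape1,cd14_shape2 Beta parameters of the CD14+ fraction
#'   (mean ~0.27, matching overnight cold-aggregation enrichment).
#' @param cd14_exponent strength of the CD14-to-baseline link.
#' @param noise_sdlog measurement noise (log scale).
#' @param seed mandatory RNG seed.
#' @return a `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_donors = 14L, days = 1:7,
                              baseline_median = 0.02, baseline_sdlog = 0.8,
                              hypoxia_multiplier_median = 9,
                              hypoxia_multiplier_sdlog = 0.5,
                              day_profile_normoxia =
                                c(1, 1.2, 1.8, 3, 5, 5.5, 4.5),
                              day_profile_hypoxia =
                                c(0.55, 1, 0.7, 0.45, 0.3, 0.2, 0.15),
                              cd14_shape1 = 2.5, cd14_shape2 = 6.5,
                              cd14_exponent = 1, noise_sdlog = 0.3,
                              seed) {
  if (missing(seed) || is.null(seed))
    stop("seed is a mandatory argument")
  stopifnot(n_donors >= 2, length(day_profile_normoxia) >= max(days),
            length(day_profile_hypoxia) >= max(days))
  structure(list(n_donors = as.integer(n_donors), days = as.integer(days),
                 baseline_median = baseline_median,
                 baseline_sdlog = baseline_sdlog,
                 hypoxia_multiplier_median = hypoxia_multiplier_median,
                 hypoxia_multiplier_sdlog = hypoxia_multiplier_sdlog,
                 day_profile_normoxia = day_profile_normoxia,
                 day_profile_hypoxia = day_profile_hypoxia,
                 cd14_shape1 = cd14_shape1, cd14_shape2 = cd14_shape2,
                 cd14_exponent = cd14_exponent, noise_sdlog = noise_sdlog,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Simulate a paired-donor editing cohort
#'
#' @param cfg a [cohort_sim_config()].
#' @return list with `measurements` (data.frame: `donor_id`, `condition`,
#'   `day`, `compartment`, `editing_fraction`, `cd14_fraction`; one
#'   uncultured day-0 row plus paired normoxia/hypoxia rows per donor and
#'   day) and `truth` (per-donor baselines, hypoxia multipliers and CD14
#'   fractions).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_donors
    donor <- sprintf("donor%02d", seq_len(n))
    cd14 <- stats::rbeta(n, cfg$cd14_shape1, cfg$cd14_shape2)
    cd14_mean <- cfg$cd14_shape1 / (cfg$cd14_shape1 + cfg$cd14_shape2)
    baseline <- cfg$baseline_median *
      exp(rnorm(n, 0, cfg$baseline_sdlog)) *
      (cd14 / cd14_mean)^cfg$cd14_exponent
    hmult <- cfg$hypoxia_multiplier_median *
      exp(rnorm(n, 0, cfg$hypoxia_multiplier_sdlog))
    rows <- list()
    noise <- function(k) exp(rnorm(k, 0, cfg$noise_sdlog))
    clip <- function(x) pmin(pmax(x, 0), 0.999)
    rows$uncultured <- data.frame(
      donor_id = donor, condition = "uncultured", day = 0L,
      compartment = "total",
      editing_fraction = clip(baseline * noise(n)),
      cd14_fraction = cd14, stringsAsFactors = FALSE)
    for (d in cfg$days) {
      rows[[paste0("n", d)]] <- data.frame(
        donor_id = donor, condition = "normoxia", day = d,
        compartment = "total",
        editing_fraction = clip(baseline * cfg$day_profile_normoxia[d] *
                                  noise(n)),
        cd14_fraction = cd14, stringsAsFactors = FALSE)
      rows[[paste0("h", d)]] <- data.frame(
        donor_id = donor, condition = "hypoxia", day = d,
        compartment = "total",
        editing_fraction = clip(baseline * hmult *
                                  cfg$day_profile_hypoxia[d] * noise(n)),
        cd14_fraction = cd14, stringsAsFactors = FALSE)
    }
    list(measurements = do.call(rbind, c(rows, make.row.names = FALSE)),
         truth = data.frame(donor_id = donor, baseline = baseline,
                            hypoxia_multiplier = hmult,
                            cd14_fraction = cd14,
                            stringsAsFactors = FALSE))
  })
}

#' Random multi-exon gene-model fixture
#'
#' Generates a random coding gene on a random chromosome sequence:
#' `n_exons` exons holding a CDS of `cds_len` bases (divisible by 3) with
#' random introns, on either strand. The plus-strand chromosome sequence
#' is attached as attribute `"genome_seq"` so reads and FASTA files can be
#' produced.
#'
#' @param seed mandatory RNG seed.
#' @param n_exons number of exons (all coding in this fixture).
#' @param cds_len CDS length in bp, divisible by 3.
#' @param strand `"+"` or `"-"`.
#' @param intron_range min/max intron length.
#' @param chrom chromosome name.
#' @param gene_start 0-based genomic start of the first exon.
#' @return a [gene_model()] with attribute `"genome_seq"`.
#' @export
random_gene_model <- function(seed, n_exons = 3L, cds_len = 300L,
                              strand = "-", intron_range = c(50L, 500L),
                              chrom = "chrSim", gene_start = 100L) {
  if (missing(seed) || is.null(seed))
    stop("seed is a mandatory argument")
  stopifnot(cds_len %% 3 == 0, n_exons >= 1, cds_len >= 3 * n_exons)
  with_seed(seed, {
    cds_seq <- paste(sample(BASES, cds_len, replace = TRUE), collapse = "")
    # split cds_len into n_exons transcript portions of >= 3 bp
    cuts <- if (n_exons > 1) {
      sort(sample(seq(3L, cds_len - 3L), n_exons - 1L))
    } else integer(0)
    widths_t <- diff(c(0L, cuts, cds_len))
    introns <- if (n_exons > 1) {
      sample(seq(intron_range[1], intron_range[2]), n_exons - 1L,
             replace = TRUE)
    } else integer(0)
    build_gene_on_genome(cds_seq, widths_t, introns, strand, chrom,
                         gene_start, gene_id = "simgene")
  })
}

# Lay a transcript-orientation CDS onto a fresh random chromosome.
# widths_t are the per-exon CDS portions in transcript order; for minus
# strand genes the genomic span order is the reverse.
build_gene_on_genome <- function(cds_seq, widths_t, introns, strand, chrom,
                                 gene_start, gene_id) {
  plus_concat <- if (strand == "-") {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds_seq)))
  } else cds_seq
  widths_g <- if (strand == "-") rev(widths_t) else widths_t
  n_exons <- length(widths_g)
  starts <- integer(n_exons)
  g <- gene_start
  spans <- matrix(0L, n_exons, 2)
  off <- 0L
  exon_seqs <- character(n_exons)
  for (i in seq_len(n_exons)) {
    spans[i, ] <- c(g, g + widths_g[i])
    exon_seqs[i] <- substr(plus_concat, off + 1L, off + widths_g[i])
    off <- off + widths_g[i]
    g <- g + widths_g[i] + if (i < n_exons) introns[i] else 0L
  }
  gene_end <- spans[n_exons, 2]
  chrom_len <- gene_end + 200L
  genome <- sample(BASES, chrom_len, replace = TRUE)
  for (i in seq_len(n_exons)) {
    genome[(spans[i, 1] + 1L):spans[i, 2]] <-
      strsplit(exon_seqs[i], "", fixed = TRUE)[[1]]
  }
  model <- gene_model(gene_id, chrom, strand, exons = spans,
                      cds_spans = spans, cds_seq = cds_seq,
                      chrom_len = chrom_len)
  attr(model, "genome_seq") <- paste(genome, collapse = "")
  model
}

#' Synthetic surrogate of the SDHB coding gene
#'
#' A fully synthetic minus-strand, eight-exon gene model reproducing the
#' structural facts of the SDHB coding region that the pipeline depends
#' on: an 843-bp CDS (281 codons) with exactly 213 C-bearing positions,
#' codon 46 = CGA (arginine) whose first base is c.136 and sits inside the
#' gene's sole Taq1 site (TCGA at c.135-138, so the C>T edit both creates
#' the R46X stop and destroys the site), c.136 falling in exon 2, an ATG
#' start, a terminal stop and no internal in-frame stops. Everything else
#' about the sequence is random: this is a synthetic stand-in, not the
#' RefSeq NM_003000.2 sequence.
#'
#' @param seed RNG seed (default 101 gives the package's canonical
#'   fixture).
#' @return a [gene_model()] with attribute `"genome_seq"`.
#' @export
synthetic_sdhb_model <- function(seed = 101L) {
  n_codons <- 281L
  target_c <- 213L
  stops <- c("TAA", "TAG", "TGA")
  all_codons <- apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = "")
  ok_codons <- setdiff(all_codons, stops)
  end_t <- ok_codons[substr(ok_codons, 3, 3) == "T"]
  fixed_idx <- c(1L, 45L, 46L, n_codons)
  with_seed(seed, {
    codons <- sample(ok_codons, n_codons, replace = TRUE)
    codons[1] <- "ATG"
    codons[45] <- sample(end_t, 1)       # c.135 = T completes T^CGA
    codons[46] <- "CGA"                  # c.136-138, R46 -> TGA on edit
    codons[n_codons] <- "TAA"
    for (iter in seq_len(20000L)) {
      seq <- paste(codons, collapse = "")
      occ <- site_starts(seq, "TCGA")
      bad <- occ[occ != 135L]
      n_c <- sum(strsplit(seq, "", fixed = TRUE)[[1]] == "C")
      if (length(bad) == 0 && n_c == target_c) break
      if (length(bad) > 0) {
        # resample an unconstrained codon overlapping the spurious site
        hit <- unique(ceiling(c(bad[1], bad[1] + 3L) / 3))
        hit <- setdiff(hit, fixed_idx)
        if (length(hit) == 0) hit <- setdiff(seq_len(n_codons), fixed_idx)
        j <- hit[1]
      } else {
        j <- sample(setdiff(seq_len(n_codons), fixed_idx), 1)
      }
      cur_c <- sum(strsplit(codons[j], "", fixed = TRUE)[[1]] == "C")
      cand_c <- vapply(ok_codons, function(cc)
        sum(strsplit(cc, "", fixed = TRUE)[[1]] == "C"), integer(1))
      pool <- if (length(bad) > 0) ok_codons
              else if (n_c < target_c) ok_codons[cand_c > cur_c]
              else ok_codons[cand_c < cur_c]
      if (length(pool) == 0) pool <- ok_codons
      codons[j] <- sample(pool, 1)
    }
    seq <- paste(codons, collapse = "")
    stopifnot(sum(strsplit(seq, "", fixed = TRUE)[[1]] == "C") == target_c,
              identical(site_starts(seq, "TCGA"), 135L))
    # eight exons; c.136 falls in exon 2 (transcript portions sum to 843)
    widths_t <- c(102L, 117L, 87L, 120L, 105L, 96L, 120L, 96L)
    introns <- sample(200:1500, 7L, replace = TRUE)
    build_gene_on_genome(seq, widths_t, introns, strand = "-",
                         chrom = "chr1_synth", gene_start = 10000L,
                         gene_id = "SDHB_synthetic")
  })
}

#' Synthetic RFLP amplicons around the editing site
#'
#' Builds the two verification amplicons used for in-silico Taq1 RFLP of
#' the edited site, sized like the printed assay: a 285-bp cDNA amplicon
#' (24 bp of synthetic 5' flank plus the first 261 CDS bases, Taq1 site at
#' amplicon position 159 so digestion yields 159 + 126 bp) and a 233-bp
#' genomic-context amplicon (Taq1 site at position 131, yielding 131 +
#' 102 bp). Each contains exactly one Taq1 site, and the C of the site
#' corresponds to the editable base: substituting T destroys the site.
#'
#' @param model a [synthetic_sdhb_model()] (or any model whose CDS has its
#'   sole TCGA at c.135).
#' @param seed RNG seed for the synthetic flanks.
#' @return list with `cdna`, `gdna` (sequences), `cdna_edit_pos` (160),
#'   `gdna_edit_pos` (132).
#' @export
synthetic_rflp_amplicons <- function(model = synthetic_sdhb_model(),
                                     seed = 7L) {
  core <- substr(model$cds_seq, 1, 261)
  stopifnot(identical(site_starts(core, "TCGA"), 135L))
  with_seed(seed, {
    repeat {
      flank <- paste(sample(BASES, 24, replace = TRUE), collapse = "")
      cdna <- paste0(flank, core)
      if (identical(site_starts(cdna, "TCGA"), 159L)) break
    }
    repeat {
      g <- sample(BASES, 233, replace = TRUE)
      g[131:134] <- c("T", "C", "G", "A")
      gdna <- paste(g, collapse = "")
      if (identical(site_starts(gdna, "TCGA"), 131L)) break
    }
    list(cdna = cdna, gdna = gdna,
         cdna_edit_pos = 160L, gdna_edit_pos = 132L)
  })
}
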