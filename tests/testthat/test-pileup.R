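# A small SAM written by hand: chrT is 60 bp; the gene is a plus-strand
# single-exon 30-codon CDS over [0, 60) ... trimmed to what each case needs.
hand_sam <- function(dir, records, chrom = "chrSim", len = 2000L) {
  path <- file.path(dir, "hand.sam")
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", chrom, len),
               records), path)
  path
}

test_that("reference-only reads tally as pure reference at every position", {
  m <- random_gene_model(seed = 61, n_exons = 2, cds_len = 120, strand = "+")
  cfg <- pileup_sim_config(m, depth = 10, error_rate = 0, edits = numeric(0),
                           read_length = 40, seed = 1)
  sam <- tempfile(fileext = ".sam")
  simulate_alignments(cfg, sam)
  tal <- tally_from_alignments(sam, m)
  nonref <- mapply(function(i, r) {
    sum(tal[i, c("A", "C", "G", "T")]) - tal[i, r]
  }, seq_len(120), tal$ref)
  expect_true(all(nonref == 0))
  expect_true(all(tal$ambiguous == 0))
  expect_true(sum(tal$depth) > 0)
})

test_that("tallies equal a brute-force per-read recount, both strands", {
  for (strand in c("+", "-")) {
    m <- random_gene_model(seed = 71, n_exons = 3, cds_len = 240,
                           strand = strand)
    cfg <- pileup_sim_config(m, depth = 40, error_rate = 0.01,
                             edits = c("50" = 0.3, "151" = 0.05),
                             read_length = 60, seed = 72)
    sam <- tempfile(fileext = ".sam")
    sim <- simulate_alignments(cfg, sam)
    expect_lte(sim$n_reads, 1e4)
    tal <- tally_from_alignments(sam, m)
    oracle <- oracle_recount(sam, m)
    expect_equal(as.matrix(tal[, c("A", "C", "G", "T", "ambiguous")]),
                 oracle, ignore_attr = TRUE)
    expect_equal(tal$depth,
                 unname(rowSums(oracle)))  # category conservation
  }
})

test_that("plus-strand A/C/G/T counts agree with Rsamtools::pileup", {
  m <- random_gene_model(seed = 81, n_exons = 2, cds_len = 150, strand = "+")
  cfg <- pileup_sim_config(m, depth = 30, error_rate = 0.02, read_length = 50,
                           edits = c("75" = 0.2), seed = 82)
  sam <- tempfile(fileext = ".sam")
  simulate_alignments(cfg, sam)
  tal <- tally_from_alignments(sam, m)

  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = TRUE)
  p <- Rsamtools::pileup(
    bam,
    scanBamParam = Rsamtools::ScanBamParam(
      which = GenomicRanges::GRanges(
        m$chrom, IRanges::IRanges(min(m$cds_spans[, 1]) + 1,
                                  max(m$cds_spans[, 2])))),
    pileupParam = Rsamtools::PileupParam(
      max_depth = 10000, min_base_quality = 13, min_mapq = 0,
      distinguish_strands = FALSE, distinguish_nucleotides = TRUE))
  for (cds_pos in c(1, 40, 75, 150)) {
    g1 <- map_cds_to_genome(m, cds_pos)$gpos + 1
    sub <- p[p$pos == g1, ]
    for (b in c("A", "C", "G", "T")) {
      expect_equal(tal[[b]][cds_pos],
                   sum(sub$count[sub$nucleotide == b]),
                   info = sprintf("pos %d base %s", cds_pos, b))
    }
  }
})

test_that("the same molecule population tallies identically on either strand", {
  mp <- random_gene_model(seed = 91, n_exons = 3, cds_len = 180, strand = "+")
  mm <- random_gene_model(seed = 91, n_exons = 3, cds_len = 180, strand = "-")
  expect_equal(mp$cds_seq, mm$cds_seq)  # same transcript, mirrored layout
  tals <- lapply(list(mp, mm), function(m) {
    cfg <- pileup_sim_config(m, depth = 25, error_rate = 0.005,
                             edits = c("90" = 0.25), read_length = 45,
                             seed = 92)
    sam <- tempfile(fileext = ".sam")
    simulate_alignments(cfg, sam)
    tally_from_alignments(sam, m)
  })
  cols <- c("cds_pos", "ref", "A", "C", "G", "T", "ambiguous", "depth")
  expect_equal(tals[[1]][, cols], tals[[2]][, cols])
})

test_that("N calls, deletions and reference skips count as ambiguous", {
  m <- gene_model("g", "chrSim", "+", c(100, 160), c(100, 160),
                  strrep("ACGTAC", 10))
  d <- withr::local_tempdir()
  sam <- hand_sam(d, c(
    # 10M read with an N at query position 4 (-> c.4)
    "r1\t0\tchrSim\t101\t60\t10M\t*\t0\t0\tACGNACGTAC\tIIIIIIIIII",
    # deletion of 2 bases after 4 matches
    "r2\t0\tchrSim\t101\t60\t4M2D4M\t*\t0\t0\tACGTGTAC\tIIIIIIII",
    # reference skip across 6 bases inside the CDS
    "r3\t0\tchrSim\t101\t60\t3M6N3M\t*\t0\t0\tACGACG\tIIIIII"))
  tal <- tally_from_alignments(sam, m)
  # c.4: N call + skip; c.5/c.6: deletion + skip; c.7-9: skip only
  expect_equal(tal$ambiguous[4:9], c(2L, 2L, 2L, 1L, 1L, 1L))
  expect_equal(tal$ambiguous[c(1:3, 10:12)], rep(0L, 6))
  expect_equal(tal$depth, rowSums(tal[, c("A", "C", "G", "T", "ambiguous")]),
               ignore_attr = TRUE)
  expect_equal(as.matrix(tal[, c("A", "C", "G", "T", "ambiguous")]),
               oracle_recount(sam, m), ignore_attr = TRUE)
})

test_that("read filters drop low-quality, duplicate and secondary records", {
  m <- gene_model("g", "chrSim", "+", c(100, 130), c(100, 130),
                  strrep("ACGTAC", 5))
  d <- withr::local_tempdir()
  sam <- hand_sam(d, c(
    "ok\t0\tchrSim\t101\t60\t6M\t*\t0\t0\tACGTAC\tIIIIII",
    # base qualities below 13 (')' = Q8) are dropped
    "lowq\t0\tchrSim\t101\t60\t6M\t*\t0\t0\tACGTAC\t))))))",
    # duplicate and secondary flags
    "dup\t1024\tchrSim\t101\t60\t6M\t*\t0\t0\tACGTAC\tIIIIII",
    "sec\t256\tchrSim\t101\t60\t6M\t*\t0\t0\tACGTAC\tIIIIII",
    # low MAPQ
    "lowmq\t0\tchrSim\t101\t5\t6M\t*\t0\t0\tACGTAC\tIIIIII"))
  # only "ok" survives: lowq bases fall below the quality floor, dup and
  # sec are flag-excluded, lowmq fails the MAPQ floor
  tal <- tally_from_alignments(sam, m,
                               read_filter_config(min_mapping_quality = 10))
  expect_equal(tal$depth[1:6], rep(1L, 6))
  tal2 <- tally_from_alignments(sam, m, read_filter_config())
  expect_equal(tal2$depth[1:6], rep(2L, 6))  # lowmq passes at floor 0
  tal3 <- tally_from_alignments(
    sam, m, read_filter_config(exclude_duplicates = FALSE,
                               exclude_secondary_supplementary = FALSE))
  expect_equal(tal3$depth[1:6], rep(4L, 6))
  # overlapping mates: same qname twice, collapse flag counts each base once
  sam2 <- hand_sam(d, c(
    "pair\t0\tchrSim\t101\t60\t6M\t*\t0\t0\tACGTAC\tIIIIII",
    "pair\t0\tchrSim\t104\t60\t6M\t*\t0\t0\tTACGTA\tIIIIII"))
  t_keep <- tally_from_alignments(sam2, m)
  t_coll <- tally_from_alignments(
    sam2, m, read_filter_config(collapse_mate_overlap = TRUE))
  expect_equal(t_keep$depth[4:6], rep(2L, 3))
  expect_equal(t_coll$depth[4:6], rep(1L, 3))
})

test_that("missing chromosome raises an input error; empty region is zero", {
  m <- gene_model("g", "chrMissing", "+", c(100, 130), c(100, 130),
                  strrep("ACGTAC", 5))
  d <- withr::local_tempdir()
  sam <- hand_sam(d, "r\t0\tchrSim\t101\t60\t6M\t*\t0\t0\tACGTAC\tIIIIII")
  expect_error(tally_from_alignments(sam, m), "absent")
  m2 <- gene_model("g", "chrSim", "+", c(1000, 1030), c(1000, 1030),
                   strrep("ACGTAC", 5))
  tal <- tally_from_alignments(sam, m2)
  expect_true(all(tal$depth == 0))
})

test_that("site fractions follow the count arithmetic", {
  cnt <- zero_counts(1); cnt[1, "C"] <- 983L; cnt[1, "T"] <- 17L
  tal <- make_tally("C", cnt)
  sf <- site_fraction(tal, 1)
  expect_equal(sf$fraction, 0.017)
  expect_equal(sf$depth, 1000L)

  cnt2 <- zero_counts(1); cnt2[1, "C"] <- 100L
  expect_equal(site_fraction(make_tally("C", cnt2), 1)$fraction, 0)
  cnt3 <- zero_counts(1); cnt3[1, "T"] <- 100L
  expect_equal(site_fraction(make_tally("C", cnt3), 1)$fraction, 1)
  # ambiguous calls sit in the denominator by default, not with the option off
  cnt4 <- zero_counts(1); cnt4[1, "C"] <- 90L; cnt4[1, "T"] <- 5L
  cnt4[1, "ambiguous"] <- 5L
  tal4 <- make_tally("C", cnt4)
  expect_equal(site_fraction(tal4, 1)$fraction, 0.05)
  expect_equal(site_fraction(tal4, 1,
                             include_ambiguous_in_depth = FALSE)$fraction,
               5 / 95)
  # zero depth signals an undefined fraction
  expect_warning(sf0 <- site_fraction(make_tally("C", zero_counts(1)), 1),
                 "undefined")
  expect_true(is.na(sf0$fraction))
})

test_that("background pooling sums counts over same-base positions", {
  m <- gene_model("g", "c", "+", c(0, 6), c(0, 6), "CCCCCC")
  cnt <- zero_counts(6)
  cnt[, "C"] <- c(990L, 1000L, 0L, 0L, 0L, 0L)
  cnt[1, "T"] <- 10L
  tal <- make_tally(rep("C", 6), cnt)
  bg <- background_fraction(tal, m, min_depth = 1)
  expect_equal(bg$fraction, 10 / 2000)
  expect_equal(bg$n_positions, 2L)
  # excluding the query site removes its counts from the pool
  bg2 <- background_fraction(tal, m, include_query_site = FALSE, site = 1)
  expect_equal(bg2$fraction, 0)
  expect_error(background_fraction(tal, m, include_query_site = FALSE),
               "site")
  # error-free tally pools to zero
  cnt0 <- zero_counts(6); cnt0[, "C"] <- 100L
  expect_equal(background_fraction(make_tally(rep("C", 6), cnt0), m)$fraction,
               0)
  expect_warning(
    bg3 <- background_fraction(tal, m, min_depth = 5000),
    "no qualifying")
  expect_true(is.na(bg3$fraction))
})

test_that("pooled background approximates a third of the error rate", {
  m <- random_gene_model(seed = 101, n_exons = 1, cds_len = 300, strand = "+")
  eps <- 0.0012
  cfg <- pileup_sim_config(m, depth = 2000, error_rate = eps, seed = 102)
  tal <- simulate_tally(cfg)
  bg <- background_fraction(tal, m, ref_base = "C", edited_base = "T")
  expected <- eps / 3
  se <- sqrt(expected * (1 - expected) / bg$depth)
  expect_lt(abs(bg$fraction - expected), 3 * se)
})

test_that("Yates chi-square matches its closed form and saturates", {
  t0 <- yates_chi_square(5, 95, 5, 95)
  expect_equal(t0$chi2, 0)
  expect_equal(t0$p_value, 1)

  t1 <- yates_chi_square(5, 95, 10, 9990)
  expect_equal(t1$chi2, 128.96499, tolerance = 1e-6)

  # correction clips to zero when |ad - bc| <= N/2
  expect_equal(yates_chi_square(10, 10, 10, 11)$chi2, 0)

  expect_warning(tz <- yates_chi_square(0, 0, 5, 5), "marginal")
  expect_true(is.na(tz$chi2))
  expect_error(yates_chi_square(-1, 1, 1, 1), "non-negative")
})

test_that("Yates chi-square agrees with stats::chisq.test on random tables", {
  withr::with_seed(11, {
    for (i in 1:50) {
      tab <- matrix(sample(1:500, 4, replace = TRUE), 2)
      mine <- yates_chi_square(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
      ref <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
      expect_lt(abs(mine$chi2 - unname(ref$statistic)), 1e-9)
      expect_lt(abs(mine$p_value - ref$p.value), 1e-9)
    }
  })
})

test_that("editing calls flag SNP overlap and detect low-level editing", {
  m <- random_gene_model(seed = 111, n_exons = 2, cds_len = 300, strand = "-")
  csites <- which(strsplit(m$cds_seq, "")[[1]] == "C")
  site <- csites[10]
  cfg <- pileup_sim_config(m, depth = 5000, error_rate = 0.001,
                           edits = stats::setNames(0.017, site), seed = 112)
  tal <- simulate_tally(cfg)
  g1 <- map_cds_to_genome(m, site)$gpos + 1
  call <- call_editing_site(tal, m, site, snp_positions = c(5L, g1))
  expect_true(call$snp_overlap)
  call2 <- call_editing_site(tal, m, site)
  expect_false(call2$snp_overlap)
  expect_lt(call2$p_value, 0.001)
  expect_equal(call2$ref_base, "C")
  se <- sqrt(0.017 * 0.983 / call2$site_depth)
  expect_lt(abs(call2$site_fraction - 0.017), 3 * se)
})

test_that("site fraction recovery spans the observed editing range", {
  m <- random_gene_model(seed = 121, n_exons = 2, cds_len = 300, strand = "-")
  site <- which(strsplit(m$cds_seq, "")[[1]] == "C")[5]
  for (f in c(0.005, 0.02, 0.18, 0.49)) {
    cfg <- pileup_sim_config(m, depth = 5000, error_rate = 0.001,
                             edits = stats::setNames(f, site),
                             seed = round(1000 * f) + 3)
    tal <- simulate_tally(cfg)
    sf <- site_fraction(tal, site)
    expect_lt(abs(sf$fraction - f), 3 * sqrt(f * (1 - f) / 5000))
  }
})

test_that("tally TSV and SNP list files round-trip", {
  m <- random_gene_model(seed = 131, n_exons = 2, cds_len = 90, strand = "+")
  cfg <- pileup_sim_config(m, depth = 20, error_rate = 0.01, seed = 132)
  tal <- simulate_tally(cfg)
  d <- withr::local_tempdir()
  f <- file.path(d, "tally.tsv")
  write_tally(tal, f)
  tal2 <- read_tally(f)
  expect_equal(tal2$A, tal$A)
  expect_equal(tal2$gpos, tal$gpos)

  snp_tsv <- file.path(d, "snp.tsv")
  writeLines(c("chrom\tpos", "chr1\t100", "chr2\t200"), snp_tsv)
  expect_equal(read_snp_positions(snp_tsv), c(100L, 200L))
  expect_equal(read_snp_positions(snp_tsv, chrom = "chr2"), 200L)

  vcf <- file.path(d, "snp.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t150\trs1\tC\tT\t.\t.\t.",
               "chr3\t300\trs2\tG\tA\t.\t.\t."), vcf)
  expect_equal(read_snp_positions(vcf), c(150L, 300L))
  expect_equal(read_snp_positions(vcf, chrom = "chr3"), 300L)
})
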