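# Independent oracles used across the suite. These deliberately re-derive
# results by brute force (per-read recounts, exhaustive enumeration, plain
# string scans) without touching the package's internal code paths.

# 0-based genomic position of each CDS base in transcript order, by a plain
# per-span walk (independent of the package's mapping arithmetic)
oracle_cds_gpos <- function(model) {
  spans <- model$cds_spans
  out <- integer(0)
  if (model$strand == "+") {
    for (i in seq_len(nrow(spans)))
      out <- c(out, spans[i, 1]:(spans[i, 2] - 1L))
  } else {
    for (i in rev(seq_len(nrow(spans))))
      out <- c(out, (spans[i, 2] - 1L):spans[i, 1])
  }
  out
}

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Brute-force recount of a SAM file into the five-category tally, walking
# each read's CIGAR one base at a time.
oracle_recount <- function(sam_path, model, min_bq = 13, min_mapq = 0,
                           drop_dup = TRUE, drop_secondary = TRUE) {
  gmap <- oracle_cds_gpos(model)
  lc <- length(gmap)
  tal <- matrix(0L, nrow = lc, ncol = 5,
                dimnames = list(NULL, c("A", "C", "G", "T", "ambiguous")))
  cds_of <- function(gpos) match(gpos, gmap)
  for (line in readLines(sam_path)) {
    if (startsWith(line, "@")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0) next
    if (drop_dup && bitwAnd(flag, 1024L) != 0) next
    if (drop_secondary && bitwAnd(flag, 256L + 2048L) != 0) next
    if (f[3] != model$chrom) next
    if (as.integer(f[5]) < min_mapq) next
    gpos <- as.integer(f[4]) - 1L  # 0-based
    qpos <- 1L
    bases <- strsplit(f[10], "", fixed = TRUE)[[1]]
    quals <- utf8ToInt(f[11]) - 33L
    toks <- regmatches(f[6], gregexpr("\\d+[MIDNSHP=X]", f[6]))[[1]]
    for (tok in toks) {
      len <- as.integer(sub("[A-Z=]$", "", tok))
      op <- sub("^\\d+", "", tok)
      if (op %in% c("M", "=", "X")) {
        for (k in seq_len(len)) {
          cp <- cds_of(gpos)
          if (!is.na(cp)) {
            b <- bases[qpos]
            if (!b %in% c("A", "C", "G", "T")) {
              tal[cp, "ambiguous"] <- tal[cp, "ambiguous"] + 1L
            } else if (quals[qpos] >= min_bq) {
              if (model$strand == "-") b <- ORACLE_COMP[[b]]
              tal[cp, b] <- tal[cp, b] + 1L
            }
          }
          gpos <- gpos + 1L
          qpos <- qpos + 1L
        }
      } else if (op %in% c("D", "N")) {
        for (k in seq_len(len)) {
          cp <- cds_of(gpos)
          if (!is.na(cp)) tal[cp, "ambiguous"] <- tal[cp, "ambiguous"] + 1L
          gpos <- gpos + 1L
        }
      } else if (op %in% c("I", "S")) {
        qpos <- qpos + len
      }
    }
  }
  tal
}

# Exhaustive signed-rank two-sided p over all 2^n sign assignments (n <= ~12)
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% r
  min(1, 2 * min(mean(ws <= w + 1e-9), mean(ws >= w - 1e-9)))
}

# Exhaustive Mann-Whitney tail probabilities over all group assignments
oracle_mwu_p <- function(a, b, one_sided = FALSE) {
  na <- length(a)
  r <- rank(c(a, b))
  ra <- sum(r[seq_len(na)])
  sets <- utils::combn(length(r), na)
  sums <- apply(sets, 2, function(ix) sum(r[ix]))
  lower <- mean(sums <= ra + 1e-9)
  upper <- mean(sums >= ra - 1e-9)
  if (one_sided) min(lower, upper) else min(1, 2 * min(lower, upper))
}

# Minimal hand-built tally for estimator unit tests
make_tally <- function(ref, counts, start_pos = 1L) {
  n <- length(ref)
  stopifnot(nrow(counts) == n)
  out <- data.frame(cds_pos = seq.int(start_pos, length.out = n),
                    gpos = seq.int(1000L, length.out = n),
                    ref = ref,
                    A = counts[, "A"], C = counts[, "C"],
                    G = counts[, "G"], T = counts[, "T"],
                    ambiguous = if ("ambiguous" %in% colnames(counts))
                      counts[, "ambiguous"] else 0L,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out$depth <- out$A + out$C + out$G + out$T + out$ambiguous
  class(out) <- c("base_call_tally", "data.frame")
  out
}

zero_counts <- function(n) {
  matrix(0L, nrow = n, ncol = 5,
         dimnames = list(NULL, c("A", "C", "G", "T", "ambiguous")))
}

# mirror of a model: same CDS on the flipped strand of the reversed chromosome
mirror_model <- function(model) {
  L <- model$chrom_len
  flip <- function(m) {
    out <- cbind(L - m[, 2], L - m[, 1])
    out[rev(seq_len(nrow(out))), , drop = FALSE]
  }
  gene_model(model$gene_id, model$chrom,
             if (model$strand == "+") "-" else "+",
             flip(model$exons), flip(model$cds_spans), model$cds_seq,
             chrom_len = L)
}
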