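#' Wilcoxon matched-pairs signed-rank test (exact with ties)
#'
#' Zero differences are dropped; absolute differences are mid-ranked. For
#' n <= `exact_limit` pairs the two-sided p-value is exact over all 2^n
#' sign assignments (computed by a generating-function convolution, which
#' enumerates the full sign-assignment distribution); above it a normal
#' approximation with tie correction is used.
#'
#' @param x,y paired measurement vectors of equal length.
#' @param exact_limit largest n for the exact distribution (default 25).
#' @return a `paired_comparison` list: `n` (pairs used), `statistic` (V =
#'   sum of positive ranks), `p_two_sided`, `direction` (sign of the
#'   median difference), `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_limit = 25L) {
  if (length(x) != length(y)) stop("x and y must be paired")
  d <- x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    stop(structure(class = c("degenerate_test", "error", "condition"),
                   list(message = "all differences are zero: test degenerate",
                        call = sys.call())))
  if (n < 3) stop("need at least 3 non-zero differences")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_limit) {
    # distribution of W over all 2^n sign assignments; 2x ranks to keep
    # mid-ranks integral
    p <- signed_rank_tail_probs(2 * r, 2 * w)
    p_two <- min(1, 2 * min(p$lower, p$upper))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu) / sqrt(sigma2)
    p_two <- 2 * pnorm(-abs(z))
    method <- "normal_approx"
  }
  structure(list(n = n, statistic = w, p_two_sided = p_two,
                 direction = sign(median(d)), method = method),
            class = "paired_comparison")
}

# exact lower/upper tail probabilities P(W <= w), P(W >= w) for the
# signed-rank sum over all sign assignments of integer ranks `r2`
signed_rank_tail_probs <- function(r2, w2) {
  total <- sum(r2)
  counts <- numeric(total + 1)  # counts[s + 1] = #assignments with W = s
  counts[1] <- 1
  for (ri in r2) {
    shifted <- c(rep(0, ri), counts[seq_len(total + 1 - ri)])
    counts <- counts + shifted
  }
  nall <- sum(counts)
  idx <- 0:total
  list(lower = sum(counts[idx <= w2]) / nall,
       upper = sum(counts[idx >= w2]) / nall)
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison> n = %d, V = %g, p = %.4g (%s), direction %+d\n",
              x$n, x$statistic, x$p_two_sided, x$method, x$direction))
  invisible(x)
}

#' Mann-Whitney U test (exact with ties)
#'
#' For combined sample sizes up to `exact_limit` the p-value is exact over
#' all choose(n_a + n_b, n_a) group assignments of the (mid-)ranks,
#' computed by dynamic programming over the rank multiset; above it a
#' tie-corrected normal approximation is used. The one-sided p-value is
#' taken in the direction of the observed shift.
#'
#' @param a,b measurement vectors for the two groups.
#' @param one_sided report the one-sided p-value (default two-sided).
#' @param exact_limit largest combined n for the exact distribution
#'   (default 20).
#' @return list with `u` (U statistic for group a), `p_value`, `method`.
#' @export
mann_whitney_u <- function(a, b, one_sided = FALSE, exact_limit = 20L) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("both groups need at least 2 values")
  r <- rank(c(a, b))
  ra <- sum(r[seq_len(na)])
  u <- ra - na * (na + 1) / 2
  n <- na + nb
  if (n <= exact_limit) {
    p <- rank_sum_tail_probs(2 * r, na, 2 * ra)
    lower <- p$lower; upper <- p$upper
    method <- "exact"
  } else {
    mu <- na * (nb) / 2
    ties <- table(r)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u - mu) / sqrt(sigma2)
    lower <- pnorm(z); upper <- pnorm(-z) + 0  # P(U<=u), P(U>=u) approx
    method <- "normal_approx"
  }
  p_value <- if (one_sided) min(lower, upper)
             else min(1, 2 * min(lower, upper))
  list(u = u, p_value = p_value, method = method)
}

# exact tail probabilities of the rank sum of a size-na subset of the
# integer rank multiset r2 (doubled mid-ranks)
rank_sum_tail_probs <- function(r2, na, ra2) {
  total <- sum(r2)
  # dp[k + 1, s + 1] = #subsets of size k with rank sum s
  dp <- matrix(0, nrow = na + 1, ncol = total + 1)
  dp[1, 1] <- 1
  for (ri in r2) {
    for (k in rev(seq_len(na))) {
      shifted <- c(rep(0, ri), dp[k, seq_len(total + 1 - ri)])
      dp[k + 1, ] <- dp[k + 1, ] + shifted
    }
  }
  counts <- dp[na + 1, ]
  nall <- sum(counts)
  idx <- 0:total
  list(lower = sum(counts[idx <= ra2]) / nall,
       upper = sum(counts[idx >= ra2]) / nall)
}

#' Pearson product-moment correlation
#'
#' Thin validating wrapper around [stats::cor()]: requires at least 3
#' observations and non-zero variance in both vectors.
#'
#' @param x,y numeric vectors.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete observations")
  if (var(x) == 0 || var(y) == 0) stop("zero variance: correlation undefined")
  stats::cor(x, y)
}

#' Linear extrapolation of the editing rate to a pure cell population
#'
#' Ordinary least squares of the editing fraction on the cell fraction
#' (e.g. CD14+ monocyte percentage), with the point estimate taken at a
#' cell fraction of 1.0. The result is flagged as an extrapolation when
#' 1.0 lies outside the observed cell-fraction range.
#'
#' @param editing editing fractions.
#' @param cell_fraction matching cell-type fractions in \[0, 1\].
#' @return list with `prediction` (editing at cell fraction 1),
#'   `slope`, `intercept`, `r`, `n`, `extrapolated`.
#' @export
extrapolate_pure_population <- function(editing, cell_fraction) {
  ok <- stats::complete.cases(editing, cell_fraction)
  editing <- editing[ok]; cell_fraction <- cell_fraction[ok]
  if (length(editing) < 3) stop("need at least 3 points")
  if (var(cell_fraction) == 0) stop("degenerate design: cell_fraction constant")
  fit <- lm(editing ~ cell_fraction)
  b <- unname(coef(fit))
  list(prediction = b[1] + b[2] * 1.0,
       slope = b[2], intercept = b[1],
       r = pearson_correlation(cell_fraction, editing),
       n = length(editing),
       extrapolated = max(cell_fraction) < 1.0)
}

#' Read a donor-level editing table
#'
#' TSV columns: `donor_id`, `condition` (uncultured / normoxia / hypoxia),
#' `day`, `compartment`, `editing_fraction`, optional `cd14_fraction`.
#'
#' @param path file path.
#' @return data.frame of donor measurements.
#' @export
read_donor_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("donor_id", "condition", "day", "compartment", "editing_fraction")
  if (!all(need %in% names(x)))
    stop("donor table must have columns: ", paste(need, collapse = ", "))
  bad <- x$editing_fraction < 0 | x$editing_fraction > 1
  if (any(bad, na.rm = TRUE)) stop("editing_fraction outside [0, 1]")
  x
}
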