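# Anderson-Darling goodness-of-fit machinery: the one-sample statistic with
# parametric-bootstrap calibration (parameters re-estimated per replicate),
# and the Scholz-Stephens k-sample statistic with its asymptotic P value.

# One-sample A2 against a fully specified cdf.
ad_statistic <- function(x, cdf) {
  n <- length(x)
  u <- cdf(sort(x))
  eps <- 1e-12
  u <- pmin(pmax(u, eps), 1 - eps)
  i <- seq_len(n)
  -n - mean((2 * i - 1) * (log(u) + log(1 - rev(u))))
}

#' One-sample Anderson-Darling test with parametric bootstrap
#'
#' Tests whether a sample is consistent with a fitted DFE family.  Because
#' the family's parameters were estimated from the very same data, the null
#' distribution of the A-squared statistic is calibrated by a parametric
#' bootstrap in which the parameters are re-estimated for every simulated
#' replicate.
#'
#' @param sample the data: an [extract_exceedances()] object or positive
#'   numeric vector (n >= 2).
#' @param fit a `dfe_fit` for one of the supported families (exponential,
#'   gamma, weibull, gpd), normally fitted on the same sample.
#' @param B bootstrap replicates (default 999).
#' @param seed integer seed.
#' @return list with `statistic` (A2), `p`, `B`.
#' @export
ad_one_sample <- function(sample, fit, B = 999L, seed = NULL) {
  x <- exceedance_values(sample)
  n <- length(x)
  if (n < 2L) stop("insufficient data: need at least 2 observations")
  stopifnot(inherits(fit, "dfe_fit"))
  if (!is.null(seed)) set.seed(seed)
  a2 <- ad_statistic(x, dfe_cdf(fit))
  a2b <- vapply(seq_len(B), function(b) {
    xb <- dfe_simulate(fit, n)
    fb <- tryCatch(dfe_refit(fit$family, xb), error = function(e) NULL)
    if (is.null(fb)) return(NA_real_)
    ad_statistic(xb, dfe_cdf(fb))
  }, 0)
  a2b <- a2b[is.finite(a2b)]
  list(statistic = a2, p = (1 + sum(a2b >= a2)) / (length(a2b) + 1),
       B = length(a2b))
}

# Scholz-Stephens asymptotic quantile surface: the standardized statistic's
# null quantile at probability p is b0 + b1/sqrt(m) + b2/m with m = k - 1.
ss_quantile_table <- function(m) {
  p <- c(0.75, 0.90, 0.95, 0.975, 0.99)
  b0 <- c(0.675, 1.281, 1.645, 1.960, 2.326)
  b1 <- c(-0.245, 0.250, 0.678, 1.149, 1.822)
  b2 <- c(-0.105, -0.305, -0.362, -0.391, -0.396)
  data.frame(p = p, q = b0 + b1 / sqrt(m) + b2 / m)
}

# Interpolate/extrapolate the upper-tail probability of the standardized
# statistic T from the five tabulated quantiles, on the logit scale
# (monotone spline inside the table, linear continuation outside).
ss_pvalue <- function(tkn, m) {
  tab <- ss_quantile_table(m)
  lg <- log((1 - tab$p) / tab$p)  # logit of the tail probability
  f <- splinefun(tab$q, lg, method = "monoH.FC")
  if (tkn < tab$q[1L]) {
    slope <- (lg[2L] - lg[1L]) / (tab$q[2L] - tab$q[1L])
    y <- lg[1L] + slope * (tkn - tab$q[1L])
  } else if (tkn > tab$q[5L]) {
    slope <- (lg[5L] - lg[4L]) / (tab$q[5L] - tab$q[4L])
    y <- lg[5L] + slope * (tkn - tab$q[5L])
  } else {
    y <- f(tkn)
  }
  min(max(plogis(y), 1e-10), 1)
}

#' k-sample Anderson-Darling test (Scholz-Stephens)
#'
#' Tests whether k samples arise from a single (unspecified) continuous
#' distribution.  Uses the tie-adjusted (midrank) version of the
#' Scholz-Stephens rank statistic, their finite-sample variance formula for
#' standardization, and the asymptotic null quantile surface for the P value.
#' With ties handled by midranks, passing the same sample twice yields the
#' statistic's minimum (0).
#'
#' @param samples list of k >= 2 numeric vectors, each with n >= 5
#'   observations.
#' @return list with `statistic` (the tie-adjusted A2kN), `t` (standardized
#'   statistic), `p` (asymptotic), `k`, `n` (per-sample sizes), `sigma`.
#' @examples
#' set.seed(1)
#' ad_k_sample(list(rexp(50, 5), rexp(50, 5)))$p
#' @export
ad_k_sample <- function(samples) {
  if (!is.list(samples) || length(samples) < 2L) {
    stop("at least 2 samples are required")
  }
  k <- length(samples)
  n <- lengths(samples)
  if (any(n < 5L)) stop("each sample must have at least 5 observations")
  pooled <- unlist(samples, use.names = FALSE)
  N <- length(pooled)
  z <- sort(unique(pooled))
  L <- length(z)
  lj <- as.numeric(table(match(pooled, z)))           # multiplicities
  # per-sample counts at each distinct value
  fij <- vapply(samples, function(s) {
    tabulate(match(s, z), nbins = L)
  }, numeric(L))
  cum_l <- cumsum(lj)
  Baj <- cum_l - lj / 2                               # midrank pooled count
  a2 <- 0
  for (i in seq_len(k)) {
    fi <- fij[, i]
    Maij <- cumsum(fi) - fi / 2
    denom <- Baj * (N - Baj) - N * lj / 4
    term <- (lj / N) * (N * Maij - n[i] * Baj)^2 / denom
    term[denom <= 0] <- 0                             # only at the extremes
    a2 <- a2 + sum(term) / n[i]
  }
  a2 <- a2 * (N - 1) / N
  # Scholz-Stephens variance of the statistic under the null
  H <- sum(1 / n)
  h <- sum(1 / seq_len(N - 1))
  ii <- seq_len(N - 2)
  g <- sum(vapply(ii, function(i) {
    jj <- seq(i + 1, N - 1)
    sum(1 / ((N - i) * jj))
  }, 0))
  a <- (4 * g - 6) * (k - 1) + (10 - 6 * g) * H
  b <- (2 * g - 4) * k^2 + 8 * h * k +
    (2 * g - 14 * h - 4) * H - 8 * h + 4 * g - 6
  cc <- (6 * h + 2 * g - 2) * k^2 + (4 * h - 4 * g + 6) * k +
    (2 * h - 6) * H + 4 * h
  d <- (2 * h + 6) * k^2 - 4 * h * k
  var_a2 <- (a * N^3 + b * N^2 + cc * N + d) /
    ((N - 1) * (N - 2) * (N - 3))
  sigma <- sqrt(var_a2)
  tkn <- (a2 - (k - 1)) / sigma
  list(statistic = a2, t = tkn, p = ss_pvalue(tkn, k - 1), k = k, n = n,
       sigma = sigma)
}
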