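# The four Wald-ratio-based causal estimators. Per-SNP Wald ratios
# ratio_j = Gamma_j / gamma_j with first-order delta SE se_Gamma_j/|gamma_j|
# give weights w_j = gamma_j^2 / se_Gamma_j^2; IVW is their inverse-variance
# meta-analysis (equivalently, weighted regression of Gamma on gamma through
# the origin with weights 1/se_Gamma^2). MR-Egger frees the intercept as a
# directional-pleiotropy probe; the weighted median tolerates up to 50%
# invalid weight; MR-PRESSO lives in presso.R.

# shared constructor for one estimate row: CI, p and OR from beta/se
new_mr_estimate <- function(method, beta, se, n_snp, dist = c("normal", "t"),
                            df = NA_real_, conf_level = 0.95) {
  dist <- match.arg(dist)
  alpha <- 1 - conf_level
  if (dist == "t") {
    crit <- stats::qt(1 - alpha / 2, df)
    pvalue <- 2 * stats::pt(-abs(beta / se), df)
  } else {
    crit <- stats::qnorm(1 - alpha / 2)
    pvalue <- two_sided_p(beta, se)
  }
  data.frame(method = method, beta = beta, se = se,
             ci_low = beta - crit * se, ci_high = beta + crit * se,
             pvalue = pvalue, n_snp = n_snp,
             odds_ratio = as_odds_ratio(beta),
             stringsAsFactors = FALSE)
}

new_heterogeneity <- function(method, Q, df) {
  p <- stats::pchisq(Q, df, lower.tail = FALSE)
  data.frame(method = method, Q = Q, df = df, pvalue = p,
             no_heterogeneity = p > 0.05, stringsAsFactors = FALSE)
}

#' Per-SNP Wald ratio estimates
#'
#' The per-instrument causal estimate `Gamma/gamma` with, by default, the
#' first-order delta-method standard error `se_Gamma/|gamma|` (the
#' summary-data MR standard, ignoring uncertainty in `gamma`); a second-order
#' version adding the `Gamma² se_gamma² / gamma⁴` term is available.
#' Instruments with `gamma == 0` have no defined ratio and are skipped with a
#' warning.
#'
#' @param set An `instrument_set`.
#' @param second_order Use the second-order delta SE (default `FALSE`).
#' @return Data frame with `snp_id`, `ratio`, `se_ratio`, `weight`
#'   (`1/se_ratio²`).
#' @export
wald_ratios <- function(set, second_order = FALSE) {
  stopifnot(inherits(set, "instrument_set"))
  r <- set$records
  zero <- r$gamma == 0
  if (all(zero)) stop("all instruments have gamma = 0; no Wald ratio defined")
  if (any(zero)) {
    warning(sprintf("%d instrument(s) with gamma = 0 skipped", sum(zero)))
    r <- r[!zero, , drop = FALSE]
  }
  se <- if (second_order) {
    sqrt(r$se_Gamma^2 / r$gamma^2 + r$Gamma^2 * r$se_gamma^2 / r$gamma^4)
  } else {
    r$se_Gamma / abs(r$gamma)
  }
  data.frame(snp_id = r$snp_id, ratio = r$Gamma / r$gamma, se_ratio = se,
             weight = 1 / se^2, stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted (IVW) estimate
#'
#' The weighted mean of per-SNP Wald ratios with weights
#' `w_j = gamma_j²/se_Gamma_j²` — identical to weighted least squares of
#' `Gamma` on `gamma` through the origin with weights `1/se_Gamma²`. The
#' fixed-effect SE is `sqrt(1/sum(w))`; the multiplicative random-effects
#' model (the default, the dominant two-sample MR convention) inflates it by
#' `sqrt(max(1, Q/(n-1)))` so between-SNP heterogeneity widens, and never
#' narrows, the interval. P-values are two-sided normal.
#'
#' @param set An `instrument_set` with at least 2 usable instruments.
#' @param model `"random"` (multiplicative random effects, default) or
#'   `"fixed"`.
#' @return List with `estimate` (one-row data frame, see [mr_fit()]) and
#'   `heterogeneity` (Cochran's Q on `n-1` df).
#' @export
ivw <- function(set, model = c("random", "fixed")) {
  model <- match.arg(model)
  ratios <- wald_ratios(set)
  n <- nrow(ratios)
  if (n < 2) stop("IVW requires at least 2 instruments")
  w <- ratios$weight
  beta <- sum(w * ratios$ratio) / sum(w)
  Q <- sum(w * (ratios$ratio - beta)^2)
  se <- sqrt(1 / sum(w))
  if (model == "random") se <- se * sqrt(max(1, Q / (n - 1)))
  list(estimate = new_mr_estimate("IVW", beta, se, n),
       heterogeneity = new_heterogeneity("IVW", Q, n - 1))
}

#' MR-Egger regression
#'
#' Weighted least squares of `Gamma` on `gamma` with a free intercept and
#' weights `1/se_Gamma²`, after orienting every instrument to a positive
#' exposure effect (jointly negating `gamma` and `Gamma` where needed, which
#' leaves all outputs invariant to the arbitrary sign of the effect allele).
#' The slope is the pleiotropy-adjusted causal estimate; a non-zero intercept
#' indicates directional pleiotropy. Standard errors from the unscaled
#' weighted regression are inflated by `sqrt(max(1, Q_Egger/(n-2)))`;
#' p-values use the t distribution on `n-2` df, material at the small
#' instrument counts common in practice.
#'
#' @param set An `instrument_set` with at least 3 instruments.
#' @return List with `slope` and `intercept` estimate rows and
#'   `heterogeneity` (Egger's Q on `n-2` df).
#' @export
mr_egger <- function(set) {
  stopifnot(inherits(set, "instrument_set"))
  r <- set$records[set$records$gamma != 0, , drop = FALSE]
  n <- nrow(r)
  if (n < 3) stop("MR-Egger requires at least 3 instruments")
  sgn <- sign(r$gamma)
  x <- r$gamma * sgn
  y <- r$Gamma * sgn
  w <- 1 / r$se_Gamma^2
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swxx * swy - swx * swxy) / det
  resid <- y - intercept - slope * x
  Q <- sum(w * resid^2)
  infl <- sqrt(max(1, Q / (n - 2)))
  se_slope <- sqrt(sw / det) * infl
  se_int <- sqrt(swxx / det) * infl
  list(slope = new_mr_estimate("Egger-slope", slope, se_slope, n, dist = "t", df = n - 2),
       intercept = new_mr_estimate("Egger-intercept", intercept, se_int, n,
                                   dist = "t", df = n - 2),
       heterogeneity = new_heterogeneity("Egger", Q, n - 2))
}

# interpolated weighted median of ratios at cumulative standardized weight 0.5
.weighted_median_point <- function(ratio, weight) {
  ord <- order(ratio)
  r <- ratio[ord]; w <- weight[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimate
#'
#' The weighted median of per-SNP Wald ratios: sort ratios ascending, form
#' cumulative standardized weights `s_j = (sum_{k<=j} w_k - w_j/2) / sum(w)`,
#' and linearly interpolate the ratio at `s = 0.5`. Consistent when
#' instruments carrying at least half the weight are valid. The SE comes from
#' a seeded parametric bootstrap: `(gamma_j, Gamma_j)` are resampled from
#' normal distributions centred on their observed values with their observed
#' SEs, and the weighted median recomputed per draw.
#'
#' @param set An `instrument_set` with at least 3 instruments.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed; mandatory for reproducibility.
#' @return One-row estimate data frame (see [mr_fit()]).
#' @export
weighted_median <- function(set, n_boot = 1000, seed) {
  stopifnot(inherits(set, "instrument_set"))
  if (missing(seed) || is.null(seed)) stop("weighted_median requires an explicit seed")
  r <- set$records[set$records$gamma != 0, , drop = FALSE]
  n <- nrow(r)
  if (n < 3) stop("weighted median requires at least 3 instruments")
  ratio <- r$Gamma / r$gamma
  weight <- r$gamma^2 / r$se_Gamma^2
  est <- .weighted_median_point(ratio, weight)
  set.seed(seed)
  g_star <- matrix(stats::rnorm(n_boot * n, mean = rep(r$gamma, each = n_boot),
                                sd = rep(r$se_gamma, each = n_boot)), nrow = n_boot)
  G_star <- matrix(stats::rnorm(n_boot * n, mean = rep(r$Gamma, each = n_boot),
                                sd = rep(r$se_Gamma, each = n_boot)), nrow = n_boot)
  boots <- vapply(seq_len(n_boot), function(b) {
    g <- g_star[b, ]; G <- G_star[b, ]
    ok <- g != 0
    .weighted_median_point(G[ok] / g[ok], g[ok]^2 / r$se_Gamma[ok]^2)
  }, numeric(1))
  se <- stats::sd(boots)
  new_mr_estimate("WM", est, se, n)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_j (ratio_j - beta_ref)²` over per-SNP Wald ratios, chi-square
#' on `n-1` df under homogeneity. The conventional "no significant
#' heterogeneity" reading (`p > 0.05`) is reported as a flag.
#'
#' @param ratios Data frame from [wald_ratios()] (needs `ratio`, `weight`).
#' @param beta_ref Reference causal estimate (usually the IVW beta).
#' @return One-row data frame with `Q`, `df`, `pvalue`, `no_heterogeneity`.
#' @export
cochran_q <- function(ratios, beta_ref) {
  stopifnot(is.data.frame(ratios), nrow(ratios) >= 2)
  Q <- sum(ratios$weight * (ratios$ratio - beta_ref)^2)
  new_heterogeneity("IVW", Q, nrow(ratios) - 1)
}
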