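#' Fit two-sample Mendelian randomization models
#'
#' The central fitting function: runs the requested causal estimators on a
#' harmonized instrument set and returns a classed model object with the
#' usual accessor methods. IVW is the primary estimator; MR-Egger (slope and
#' pleiotropy intercept) and the weighted median are sensitivity analyses,
#' with Cochran's Q heterogeneity statistics for IVW and Egger. MR-PRESSO is
#' run separately via [mr_presso()] because of its simulation cost.
#'
#' @param set An `instrument_set` from [harmonize()] / [select_instruments()].
#' @param methods Estimators to run; any of `"ivw"`, `"egger"`,
#'   `"weighted_median"`.
#' @param model IVW error model, `"random"` (multiplicative random effects,
#'   default) or `"fixed"`.
#' @param n_boot Bootstrap replicates for the weighted-median SE.
#' @param seed Seed for the weighted-median bootstrap (mandatory when
#'   `"weighted_median"` is requested).
#' @return An object of class `mr_fit`: list with `estimates` (one row per
#'   method: beta, se, 95% CI, p, n_snp, odds ratio), `heterogeneity`,
#'   `instruments` (the input set) and `call`. Methods: [print.mr_fit()],
#'   [summary.mr_fit()], [coef.mr_fit()], [confint.mr_fit()],
#'   [plot.mr_fit()].
#' @examples
#' sim <- simulate_mediation_gwas(simulation_config(seed = 7))
#' iset <- select_instruments(sim$exposure, sim$outcome, ld = sim$ld)
#' fit <- mr_fit(iset, seed = 1)
#' fit
#' coef(fit)
#' @export
mr_fit <- function(set, methods = c("ivw", "egger", "weighted_median"),
                   model = c("random", "fixed"), n_boot = 1000, seed = NULL) {
  stopifnot(inherits(set, "instrument_set"))
  methods <- match.arg(methods, c("ivw", "egger", "weighted_median"),
                       several.ok = TRUE)
  model <- match.arg(model)
  est <- list(); het <- list()
  if ("ivw" %in% methods) {
    fit <- ivw(set, model = model)
    est$ivw <- fit$estimate
    het$ivw <- fit$heterogeneity
  }
  if ("egger" %in% methods) {
    fit <- mr_egger(set)
    est$egger <- fit$slope
    est$egger_int <- fit$intercept
    het$egger <- fit$heterogeneity
  }
  if ("weighted_median" %in% methods) {
    if (is.null(seed)) stop("mr_fit needs a seed for the weighted-median bootstrap")
    est$wm <- weighted_median(set, n_boot = n_boot, seed = seed)
  }
  structure(list(estimates = do.call(rbind, unname(est)),
                 heterogeneity = if (length(het)) do.call(rbind, unname(het)) else NULL,
                 instruments = set, model = model,
                 outcome_binary = identical(set$outcome_type, "binary"),
                 call = match.call()),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Two-sample MR: %s -> %s (%d instruments, IVW model: %s)\n",
              x$instruments$exposure_name, x$instruments$outcome_name,
              nrow(x$instruments$records), x$model))
  df <- x$estimates
  if (!x$outcome_binary) df$odds_ratio <- NULL
  print(format(df, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @describeIn mr_fit Estimates plus heterogeneity statistics and a
#'   directional-pleiotropy verdict from the Egger intercept.
#' @param object,x An `mr_fit`.
#' @param ... Unused.
#' @export
summary.mr_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  if (!is.null(x$fit$heterogeneity)) {
    cat("\nHeterogeneity (Cochran's Q):\n")
    print(format(x$fit$heterogeneity, digits = digits), row.names = FALSE)
  }
  int <- x$fit$estimates[x$fit$estimates$method == "Egger-intercept", ]
  if (nrow(int)) {
    verdict <- if (int$pvalue < 0.05) "evidence of directional pleiotropy" else
      "no evidence of directional pleiotropy"
    cat(sprintf("\nEgger intercept %.4g (p = %.3g): %s\n", int$beta, int$pvalue, verdict))
  }
  invisible(x)
}

#' @describeIn mr_fit Named vector of causal estimates (one per method).
#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$estimates$beta, object$estimates$method)
}

#' @describeIn mr_fit 95% (or `level`) confidence intervals per method.
#' @param parm Methods to include (default all).
#' @param level Confidence level.
#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  df <- object$estimates
  if (!missing(parm)) df <- df[df$method %in% parm, , drop = FALSE]
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(df$beta - z * df$se, df$beta + z * df$se)
  dimnames(out) <- list(df$method,
                        sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100))
  out
}

#' @describeIn mr_fit Scatter of SNP-outcome vs SNP-exposure effects with the
#'   fitted IVW (through the origin) and Egger lines.
#' @export
plot.mr_fit <- function(x, ...) {
  r <- x$instruments$records
  sgn <- sign(r$gamma)
  g <- r$gamma * sgn; G <- r$Gamma * sgn
  graphics::plot(g, G, xlab = "SNP effect on exposure (oriented)",
                 ylab = "SNP effect on outcome",
                 main = sprintf("%s -> %s", x$instruments$exposure_name,
                                x$instruments$outcome_name), ...)
  graphics::segments(g, G - 1.96 * r$se_Gamma, g, G + 1.96 * r$se_Gamma,
                     col = "grey70")
  est <- x$estimates
  if ("IVW" %in% est$method) {
    graphics::abline(0, est$beta[est$method == "IVW"], col = "steelblue", lwd = 2)
  }
  if (all(c("Egger-slope", "Egger-intercept") %in% est$method)) {
    graphics::abline(est$beta[est$method == "Egger-intercept"],
                     est$beta[est$method == "Egger-slope"],
                     col = "firebrick", lwd = 2, lty = 2)
  }
  invisible(x)
}
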