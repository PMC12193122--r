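# Two-step MR mediation: the total effect c (exposure -> outcome), step-1
# effect a (exposure -> mediator) and step-2 effect b (mediator -> outcome)
# combine into the indirect effect a*b by the product-of-coefficients method,
# with the Aroian standard error (the Sobel SE plus its second-order term)
# and the mediated proportion (a*b)/c.

#' Aroian standard error of a product of coefficients
#'
#' `sqrt(b² se_a² + a² se_b² + se_a² se_b²)` — the Sobel standard error with
#' the second-order `se_a² se_b²` term included, hence never smaller than the
#' Sobel SE (equal only when one SE is zero, which is disallowed).
#'
#' @param a,b Step coefficients.
#' @param se_a,se_b Their standard errors (must be positive).
#' @return The Aroian SE of `a*b`.
#' @examples
#' aroian_se(0.5, 0.1, 0.2, 0.05)
#' @export
aroian_se <- function(a, se_a, b, se_b) {
  if (any(se_a <= 0) || any(se_b <= 0)) stop("standard errors must be positive")
  sqrt(b^2 * se_a^2 + a^2 * se_b^2 + se_a^2 * se_b^2)
}

# accept an mr_fit (its IVW row), a one-row estimate data frame, a list or a
# numeric c(beta, se)
as_mr_estimate <- function(x) {
  if (inherits(x, "mr_fit")) {
    row <- x$estimates[x$estimates$method == "IVW", ]
    if (!nrow(row)) stop("mr_fit object carries no IVW estimate")
    return(list(beta = row$beta, se = row$se, pvalue = row$pvalue))
  }
  if (is.data.frame(x)) {
    return(list(beta = x$beta[1], se = x$se[1],
                pvalue = if (!is.null(x$pvalue)) x$pvalue[1] else two_sided_p(x$beta[1], x$se[1])))
  }
  if (is.list(x)) {
    stopifnot(!is.null(x$beta), !is.null(x$se))
    return(list(beta = x$beta, se = x$se,
                pvalue = x$pvalue %||% two_sided_p(x$beta, x$se)))
  }
  if (is.numeric(x) && length(x) >= 2) {
    return(list(beta = x[1], se = x[2], pvalue = two_sided_p(x[1], x[2])))
  }
  stop("cannot interpret estimate input")
}

#' Product-of-coefficients mediation with Aroian standard errors
#'
#' Combines the total effect `c`, the exposure-to-mediator effect `a` and the
#' mediator-to-outcome effect `b` into the indirect effect `a*b`, its Aroian
#' SE, a two-sided normal p-value, a 95% normal CI, and the mediated
#' proportion `a*b/c` — reported signed and as an absolute percentage, since
#' inconsistent mediation (indirect and total effects of opposite sign) is
#' common and published tables print the absolute share. A zero total effect
#' leaves the proportion undefined (`NA`, flagged) while all other fields are
#' still returned.
#'
#' @param c_est,a_est,b_est Estimates of c, a and b: each an [mr_fit()] (its
#'   IVW row is used), a one-row estimate data frame, a `list(beta=, se=)`,
#'   or a numeric `c(beta, se)`. All three must come from the same
#'   harmonization conventions.
#' @param exposure,mediator,outcome Optional pathway labels.
#' @param conf_level Confidence level for the indirect-effect CI.
#' @return An object of class `mediation_result` with fields `c`, `se_c`,
#'   `p_c`, `a`, `se_a`, `b`, `se_b`, `indirect`, `se_indirect`,
#'   `ci_indirect`, `p_indirect`, `proportion`, `proportion_abs` (percent)
#'   and `significant` (`p_indirect < 0.05`).
#' @examples
#' mediate(c(0.704, 0.332), c(-0.43, 0.1), c(0.2, 0.05))
#' @export
mediate <- function(c_est, a_est, b_est, exposure = NULL, mediator = NULL,
                    outcome = NULL, conf_level = 0.95) {
  ce <- as_mr_estimate(c_est)
  ae <- as_mr_estimate(a_est)
  be <- as_mr_estimate(b_est)
  indirect <- ae$beta * be$beta
  se_ind <- aroian_se(ae$beta, ae$se, be$beta, be$se)
  z <- indirect / se_ind
  p_ind <- 2 * stats::pnorm(-abs(z))
  crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (ce$beta == 0) {
    warning("total effect is zero; mediated proportion undefined")
    prop <- NA_real_; prop_abs <- NA_real_
  } else {
    prop <- indirect / ce$beta
    prop_abs <- abs(prop) * 100
  }
  structure(list(
    exposure = exposure, mediator = mediator, outcome = outcome,
    c = ce$beta, se_c = ce$se, p_c = ce$pvalue,
    a = ae$beta, se_a = ae$se,
    b = be$beta, se_b = be$se,
    indirect = indirect, se_indirect = se_ind,
    ci_indirect = c(indirect - crit * se_ind, indirect + crit * se_ind),
    p_indirect = p_ind,
    proportion = prop, proportion_abs = prop_abs,
    significant = p_ind < 0.05
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, digits = 4, ...) {
  path <- paste(c(x$exposure %||% "exposure", x$mediator %||% "mediator",
                  x$outcome %||% "outcome"), collapse = " -> ")
  cat("Two-step MR mediation:", path, "\n")
  cat(sprintf("  total effect c    = %.*g (se %.3g, p %.3g)\n", digits, x$c, x$se_c, x$p_c))
  cat(sprintf("  a (exp->med)      = %.*g (se %.3g)\n", digits, x$a, x$se_a))
  cat(sprintf("  b (med->out)      = %.*g (se %.3g)\n", digits, x$b, x$se_b))
  cat(sprintf("  indirect a*b      = %.*g (Aroian se %.3g, 95%% CI %.3g to %.3g, p %.3g)\n",
              digits, x$indirect, x$se_indirect, x$ci_indirect[1], x$ci_indirect[2],
              x$p_indirect))
  if (is.na(x$proportion)) {
    cat("  mediated proportion undefined (c = 0)\n")
  } else {
    cat(sprintf("  mediated proportion = %.*g (|%.2f%%| of total)\n", digits,
                x$proportion, x$proportion_abs))
  }
  invisible(x)
}

#' Two-sided p-value from a point estimate and its confidence interval
#'
#' Audit utility for published tables that print an effect with a 95% CI but
#' no SE: the SE is back-calculated as `(ci_high - ci_low)/(2 * 1.96)` and a
#' two-sided normal p returned.
#'
#' @param effect Point estimate.
#' @param ci_low,ci_high 95% confidence bounds (`ci_low < ci_high` required).
#' @return Two-sided normal p-value.
#' @examples
#' pvalue_from_ci(-0.086, -0.144, -0.028)
#' @export
pvalue_from_ci <- function(effect, ci_low, ci_high) {
  if (any(ci_low >= ci_high)) stop("degenerate confidence interval (ci_low >= ci_high)")
  se <- (ci_high - ci_low) / (2 * stats::qnorm(0.975))
  two_sided_p(effect, se)
}

#' Summarize mediation pathways into a publication-style table
#'
#' Accepts either a list of [mediate()] results or a data frame of published
#' pathway rows (columns `outcome`, `exposure`, `mediator`, `p_indirect`, and
#' optionally `total_beta`, `indirect_beta`, `proportion_pct`). Rows are
#' sorted by outcome then exposure; counts of significant pathways
#' (`p_indirect < alpha`) and of distinct mediators among them are attached.
#'
#' @param results List of `mediation_result` objects or a data frame.
#' @param alpha Significance threshold (default 0.05).
#' @return A data frame of class `pathway_table` with attributes
#'   `n_significant` and `n_mediators`.
#' @export
pathway_table <- function(results, alpha = 0.05) {
  if (is.data.frame(results)) {
    df <- results
    stopifnot(all(c("outcome", "exposure", "mediator", "p_indirect") %in% names(df)))
  } else {
    stopifnot(length(results) >= 1,
              all(vapply(results, inherits, logical(1), "mediation_result")))
    df <- do.call(rbind, lapply(results, function(r) {
      data.frame(outcome = r$outcome %||% NA_character_,
                 exposure = r$exposure %||% NA_character_,
                 mediator = r$mediator %||% NA_character_,
                 total_beta = r$c, total_se = r$se_c,
                 indirect_beta = r$indirect,
                 indirect_lo = r$ci_indirect[1], indirect_hi = r$ci_indirect[2],
                 p_indirect = r$p_indirect,
                 proportion_pct = r$proportion_abs,
                 stringsAsFactors = FALSE)
    }))
  }
  df <- df[order(df$outcome, df$exposure), , drop = FALSE]
  rownames(df) <- NULL
  df$significant <- df$p_indirect < alpha
  structure(df, class = c("pathway_table", "data.frame"),
            n_significant = sum(df$significant),
            n_mediators = length(unique(df$mediator[df$significant])))
}

#' @export
print.pathway_table <- function(x, digits = 4, ...) {
  cat(sprintf("Mediation pathways: %d total, %d significant involving %d distinct mediator(s)\n",
              nrow(x), attr(x, "n_significant"), attr(x, "n_mediators")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
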