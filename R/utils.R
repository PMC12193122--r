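#' @keywords internal
"_PACKAGE"

# base complement lookup for strand handling
.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

`%||%` <- function(a, b) if (is.null(a)) b else a

is_palindromic_pair <- function(a1, a2) {
  unname(.COMPLEMENT[a1] == a2)
}

#' Convert a log-odds effect to an odds ratio
#'
#' Causal effects on binary outcomes are estimated on the log-odds scale;
#' published forest plots report them as odds ratios. This is the conversion
#' used throughout the package when `trait_type` of the outcome is binary.
#'
#' @param beta Effect estimate on the log-odds scale.
#' @return `exp(beta)`, the odds ratio per unit of exposure.
#' @examples
#' as_odds_ratio(0.989)
#' @export
as_odds_ratio <- function(beta) exp(beta)

#' Mediated proportion of a total effect
#'
#' The share of a total effect flowing through a mediator: the indirect
#' (product-of-coefficients) effect divided by the total effect. Published
#' mediation tables report the absolute percentage even when the indirect and
#' total effects have opposite signs (inconsistent mediation), so both the
#' signed fraction and the absolute percentage are returned.
#'
#' @param indirect Indirect effect `a * b`.
#' @param total Total effect `c`.
#' @return List with `proportion` (signed fraction `indirect/total`) and
#'   `proportion_abs` (absolute value, as a percentage). Both are `NA` with a
#'   warning when `total` is zero.
#' @examples
#' mediated_proportion(-0.086, 0.704)
#' @export
mediated_proportion <- function(indirect, total) {
  stopifnot(is.numeric(indirect), is.numeric(total), length(indirect) == length(total))
  prop <- indirect / total
  if (any(total == 0)) {
    warning("total effect is zero; mediated proportion undefined")
    prop[total == 0] <- NA_real_
  }
  list(proportion = prop, proportion_abs = abs(prop) * 100)
}

# two-sided normal p-value from an estimate and its SE
two_sided_p <- function(beta, se) 2 * stats::pnorm(-abs(beta / se))

# p-values of simulated z-scores, kept strictly inside (0, 1]
p_from_z <- function(z) pmax(2 * stats::pnorm(-abs(z)), 1e-300)
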