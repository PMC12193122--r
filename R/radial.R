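# Radial-MR outlier pruning: each instrument's contribution
# Q_j = w_j (ratio_j - beta_IVW)^2 is chi-square(1) under homogeneity, so
# SNPs with small per-SNP p are flagged as pleiotropic outliers. Removal is
# batch-wise with re-fitting between iterations.

#' Radial-MR outlier filtering
#'
#' Iteratively fits IVW with first-order radial weights, computes each SNP's
#' Q contribution `Q_j = w_j (ratio_j - beta)²` with its chi-square(1) upper
#' tail p-value, removes every SNP with `p_j < alpha` in a batch, and repeats
#' until no SNP is removed or `max_iter` is reached (`max_iter = 1` gives a
#' single-pass filter). A removal that would leave fewer than 2 SNPs is not
#' performed and triggers a warning. The per-SNP Q contributions of the final
#' iteration always sum to the total Cochran's Q of the surviving set.
#'
#' @param set An `instrument_set` with at least 3 instruments.
#' @param alpha Per-SNP significance threshold (default 0.05).
#' @param max_iter Maximum pruning iterations (default 10).
#' @return List with `set` (filtered `instrument_set`) and `radial`
#'   (class `radial_result`): `per_snp_q` data frame for the survivors,
#'   `total_q`, cumulative `removed` ids and `iterations` used.
#' @export
radial_filter <- function(set, alpha = 0.05, max_iter = 10) {
  stopifnot(inherits(set, "instrument_set"))
  if (nrow(set$records) < 3) stop("radial filtering requires at least 3 instruments")
  removed <- character(0)
  iter <- 0L
  current <- set
  repeat {
    iter <- iter + 1L
    ratios <- suppressWarnings(wald_ratios(current))
    w <- ratios$weight
    beta <- sum(w * ratios$ratio) / sum(w)
    qj <- w * (ratios$ratio - beta)^2
    pj <- stats::pchisq(qj, df = 1, lower.tail = FALSE)
    out <- pj < alpha
    per_snp <- data.frame(snp_id = ratios$snp_id, q = qj, pvalue = pj,
                          stringsAsFactors = FALSE)
    if (!any(out) || iter >= max_iter) break
    if (nrow(current$records) - sum(out) < 2) {
      warning("radial filtering stopped: removal would leave fewer than 2 instruments")
      break
    }
    removed <- c(removed, ratios$snp_id[out])
    current$records <- current$records[!(current$records$snp_id %in% ratios$snp_id[out]), ,
                                       drop = FALSE]
  }
  current$provenance <- c(current$provenance, dropped_radial = length(removed))
  rownames(current$records) <- NULL
  radial <- structure(list(per_snp_q = per_snp, total_q = sum(per_snp$q),
                           removed = removed, iterations = iter),
                      class = "radial_result")
  list(set = current, radial = radial)
}

#' @export
print.radial_result <- function(x, ...) {
  cat(sprintf("Radial-MR filter: %d SNP(s) removed in %d iteration(s); total Q = %.3f\n",
              length(x$removed), x$iterations, x$total_q))
  if (length(x$removed)) cat("removed:", paste(x$removed, collapse = ", "), "\n")
  invisible(x)
}
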