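# Synthetic GWAS summary statistics under a mediation structural model:
# exposure -> mediator -> outcome plus a direct path. Exposure instruments
# carry true effects gamma_j on the exposure, a*gamma_j on the mediator and
# (c_direct + a*b)*gamma_j + alpha_j on the outcome, where alpha_j is
# horizontal pleiotropy (balanced, directional, or planted outliers). A
# disjoint panel instruments the mediator with effects delta_k and b*delta_k
# on the outcome. Standard errors follow the standardized-trait
# approximation se = 1/sqrt(2 p (1-p) n).

.PALINDROMIC_PAIRS <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
.NONPAL_PAIRS <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                      c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))

#' Configuration for the summary-statistics simulator
#'
#' Defaults describe a well-powered desk-scale study: 50 exposure and 30
#' mediator instruments measured in GWAS of 200,000 samples each, strong
#' instruments (`gamma_sd = 0.1` SD per allele, mean F around 800), modest
#' structural effects `a = b = c_direct = 0.05` (mediated proportion
#' `a*b/(c_direct + a*b)` of about 4.8%, within the range typical of
#' cytokine-mediated lifestyle effects), no pleiotropy, no LD (pre-pruned
#' panels) and 15% palindromic variants.
#'
#' @param n_snp_exposure,n_snp_mediator Instrument-panel sizes.
#' @param n_exp,n_med,n_out GWAS sample sizes for the exposure, mediator and
#'   outcome datasets.
#' @param eaf_range Range of effect-allele frequencies, inside (0, 1).
#' @param gamma_sd SD of true instrument effects (SD units per allele copy).
#' @param a True exposure-to-mediator effect.
#' @param b True mediator-to-outcome effect (log-odds per mediator SD).
#' @param c_direct Direct exposure-to-outcome effect; the total effect is
#'   `c_direct + a*b`.
#' @param pleiotropy_sd,pleiotropy_mean SD and mean of per-SNP horizontal
#'   pleiotropy on the outcome. The mean acts in the exposure-increasing
#'   allele frame (each SNP's pleiotropic shift carries the sign of its
#'   `gamma`), so directional pleiotropy survives the orientation step of
#'   MR-Egger and its intercept estimates `pleiotropy_mean`.
#' @param n_outliers Number of planted outlier instruments.
#' @param outlier_alpha Pleiotropy magnitude assigned to planted outliers
#'   (log-odds, exposure-increasing frame).
#' @param ld_block_size SNPs per LD block (1 = independent panels).
#' @param ld_within_r2 Pairwise r² declared within a block.
#' @param frac_palindromic Fraction of SNPs given palindromic (A/T or C/G)
#'   allele pairs.
#' @param seed Integer seed; mandatory, every draw is reproducible from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_snp_exposure = 50, n_snp_mediator = 30,
                              n_exp = 200000, n_med = 200000, n_out = 200000,
                              eaf_range = c(0.05, 0.95), gamma_sd = 0.1,
                              a = 0.05, b = 0.05, c_direct = 0.05,
                              pleiotropy_sd = 0, pleiotropy_mean = 0,
                              n_outliers = 0, outlier_alpha = 0.1,
                              ld_block_size = 1, ld_within_r2 = 0.5,
                              frac_palindromic = 0.15, seed) {
  if (missing(seed)) stop("simulation_config requires an explicit seed")
  stopifnot(n_snp_exposure >= 1, n_snp_mediator >= 1,
            n_exp > 0, n_med > 0, n_out > 0,
            length(eaf_range) == 2, eaf_range[1] > 0, eaf_range[2] < 1,
            eaf_range[1] < eaf_range[2],
            gamma_sd > 0, pleiotropy_sd >= 0,
            n_outliers >= 0, n_outliers <= n_snp_exposure,
            ld_block_size >= 1, ld_within_r2 >= 0, ld_within_r2 <= 1,
            frac_palindromic >= 0, frac_palindromic <= 1,
            is.numeric(seed), length(seed) == 1)
  structure(as.list(environment()), class = "simulation_config")
}

.sample_alleles <- function(n, frac_palindromic) {
  n_pal <- round(frac_palindromic * n)
  pal <- rep(FALSE, n)
  if (n_pal > 0) pal[sample.int(n, n_pal)] <- TRUE
  ea <- character(n); oa <- character(n)
  for (i in seq_len(n)) {
    pair <- if (pal[i]) .PALINDROMIC_PAIRS[[sample.int(4, 1)]] else
      .NONPAL_PAIRS[[sample.int(8, 1)]]
    ea[i] <- pair[1]; oa[i] <- pair[2]
  }
  list(ea = ea, oa = oa, pal = pal)
}

# re-express a table's rows with swapped allele order and/or complementary
# strand, so harmonization has real work to do
.scramble_representation <- function(df, pal) {
  n <- nrow(df)
  swap <- stats::runif(n) < 0.3
  comp <- !pal & stats::runif(n) < 0.2
  ea <- df$effect_allele; oa <- df$other_allele
  tmp <- ea[swap]; ea[swap] <- oa[swap]; oa[swap] <- tmp
  df$beta[swap] <- -df$beta[swap]
  df$eaf[swap] <- 1 - df$eaf[swap]
  ea[comp] <- .COMPLEMENT[ea[comp]]
  oa[comp] <- .COMPLEMENT[oa[comp]]
  df$effect_allele <- ea; df$other_allele <- oa
  df
}

.assoc_rows <- function(ids, chrom, pos, ea, oa, eaf, true_beta, n_sample) {
  se <- 1 / sqrt(2 * eaf * (1 - eaf) * n_sample)
  beta_hat <- true_beta + stats::rnorm(length(ids), 0, se)
  data.frame(snp_id = ids, chrom = chrom, pos = pos,
             effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta_hat, se = se, pvalue = p_from_z(beta_hat / se),
             n = n_sample, stringsAsFactors = FALSE)
}

#' Simulate exposure, mediator and outcome GWAS summary statistics
#'
#' Draws one realisation of the mediation structural model described in
#' [simulation_config()] and returns the three summary-statistics tables, an
#' LD table, and the generative truth against which recovery is tested. The
#' exposure table holds both panels (the mediator panel with null exposure
#' effects); the mediator and outcome tables likewise cover all SNPs, with
#' allele representations randomly swapped or strand-complemented so the
#' harmonization step is exercised. P-values are two-sided normal, floored
#' at 1e-300 to stay within (0, 1].
#'
#' @param config A [simulation_config()].
#' @return List with `exposure`, `mediator`, `outcome` ([gwas_table()]s),
#'   `ld` ([ld_from_pairs()]) and `truth` (class `simulation_truth`: per-SNP
#'   true `gamma`, `alpha`, `delta`, scalars `a`, `b`, `c_direct`, `c_total`,
#'   planted `outliers`).
#' @examples
#' sim <- simulate_mediation_gwas(simulation_config(seed = 1))
#' sim$exposure
#' @export
simulate_mediation_gwas <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cf <- config
  set.seed(cf$seed)

  n_e <- cf$n_snp_exposure
  n_m <- cf$n_snp_mediator
  ids_e <- sprintf("rs1%05d", seq_len(n_e))
  ids_m <- sprintf("rs2%05d", seq_len(n_m))

  # positions: LD blocks sit together (1 kb spacing), blocks 1 Mb apart
  block_e <- ceiling(seq_len(n_e) / cf$ld_block_size)
  block_m <- ceiling(seq_len(n_m) / cf$ld_block_size)
  pos_e <- block_e * 1e6 + (seq_len(n_e) - 1) %% cf$ld_block_size * 1000
  pos_m <- 5e8 + block_m * 1e6 + (seq_len(n_m) - 1) %% cf$ld_block_size * 1000

  al_e <- .sample_alleles(n_e, cf$frac_palindromic)
  al_m <- .sample_alleles(n_m, cf$frac_palindromic)
  eaf_e <- stats::runif(n_e, cf$eaf_range[1], cf$eaf_range[2])
  eaf_m <- stats::runif(n_m, cf$eaf_range[1], cf$eaf_range[2])

  gamma <- stats::rnorm(n_e, 0, cf$gamma_sd)
  delta <- stats::rnorm(n_m, 0, cf$gamma_sd)

  alpha <- if (cf$pleiotropy_mean != 0 || cf$pleiotropy_sd > 0) {
    sign(gamma) * (cf$pleiotropy_mean + stats::rnorm(n_e, 0, cf$pleiotropy_sd))
  } else rep(0, n_e)
  outlier_ids <- character(0)
  if (cf$n_outliers > 0) {
    # plant outliers among strong, non-palindromic instruments so they enter
    # the analyzed set: a pleiotropic SNP that never passes selection cannot
    # test outlier detection
    eligible <- which(!al_e$pal & abs(gamma) >= stats::median(abs(gamma)))
    if (length(eligible) < cf$n_outliers) eligible <- seq_len(n_e)
    out_idx <- eligible[sample.int(length(eligible), cf$n_outliers)]
    alpha[out_idx] <- sign(gamma[out_idx]) * cf$outlier_alpha
    outlier_ids <- ids_e[out_idx]
  }
  c_total <- cf$c_direct + cf$a * cf$b

  ids <- c(ids_e, ids_m)
  pos <- c(pos_e, pos_m)
  ea <- c(al_e$ea, al_m$ea); oa <- c(al_e$oa, al_m$oa)
  pal <- c(al_e$pal, al_m$pal)
  eaf <- c(eaf_e, eaf_m)

  exposure_df <- .assoc_rows(ids, "1", pos, ea, oa, eaf,
                             c(gamma, rep(0, n_m)), cf$n_exp)
  mediator_df <- .assoc_rows(ids, "1", pos, ea, oa, eaf,
                             c(cf$a * gamma, delta), cf$n_med)
  outcome_df <- .assoc_rows(ids, "1", pos, ea, oa, eaf,
                            c(c_total * gamma + alpha, cf$b * delta), cf$n_out)
  mediator_df <- .scramble_representation(mediator_df, pal)
  outcome_df <- .scramble_representation(outcome_df, pal)

  ld <- .block_ld(list(list(ids = ids_e, block = block_e),
                       list(ids = ids_m, block = block_m)),
                  cf$ld_block_size, cf$ld_within_r2)

  truth <- structure(list(
    a = cf$a, b = cf$b, c_direct = cf$c_direct, c_total = c_total,
    gamma = stats::setNames(gamma, ids_e),
    alpha = stats::setNames(alpha, ids_e),
    delta = stats::setNames(delta, ids_m),
    outliers = outlier_ids, seed = cf$seed
  ), class = "simulation_truth")

  list(
    exposure = gwas_table(exposure_df, "sim_exposure", "continuous", validate = FALSE),
    mediator = gwas_table(mediator_df, "sim_mediator", "continuous", validate = FALSE),
    outcome = gwas_table(outcome_df, "sim_outcome", "binary", validate = FALSE),
    ld = ld, truth = truth
  )
}

.block_ld <- function(panels, block_size, r2) {
  pairs <- data.frame(snp_a = character(0), snp_b = character(0), r2 = numeric(0),
                      stringsAsFactors = FALSE)
  if (block_size > 1 && r2 > 0) {
    for (p in panels) {
      for (blk in unique(p$block)) {
        members <- p$ids[p$block == blk]
        if (length(members) < 2) next
        cmb <- utils::combn(members, 2)
        pairs <- rbind(pairs, data.frame(snp_a = cmb[1, ], snp_b = cmb[2, ],
                                         r2 = r2, stringsAsFactors = FALSE))
      }
    }
  }
  ld_from_pairs(pairs)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("Simulation truth: a = %.4g, b = %.4g, c_direct = %.4g, c_total = %.4g\n",
              x$a, x$b, x$c_direct, x$c_total))
  cat(sprintf("  %d exposure / %d mediator instruments, %d planted outlier(s)\n",
              length(x$gamma), length(x$delta), length(x$outliers)))
  invisible(x)
}

#' Write simulation truth to JSON
#'
#' @param truth A `simulation_truth`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @seealso [read_truth()]
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "simulation_truth"))
  x <- unclass(truth)
  # keep per-SNP vectors as id -> value maps so names survive JSON
  for (f in c("gamma", "alpha", "delta")) x[[f]] <- as.list(x[[f]])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read simulation truth from JSON
#' @param path Path written by [write_truth()].
#' @return A `simulation_truth`.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("gamma", "alpha", "delta")) x[[f]] <- unlist(x[[f]])
  x$outliers <- as.character(x$outliers %||% character(0))
  structure(x, class = "simulation_truth")
}
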