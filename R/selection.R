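# Instrument selection: the filter cascade that turns raw exposure and
# outcome summary statistics into an analysis-ready, allele-harmonized
# instrument set. Stages: genome-wide significance filter -> LD clumping ->
# outcome-association exclusion -> harmonization -> weak-instrument (F)
# filter -> radial outlier pruning (see radial_filter). Every stage records
# how many SNPs it dropped, so provenance counts always sum.

#' Instrument-selection configuration
#'
#' Thresholds for the selection cascade. All inequalities are strict, exactly
#' as conventionally printed: a SNP is genome-wide significant when
#' `p < p_exposure`, clumped away when `r² > clump_r2`, excluded when its
#' outcome `p < p_outcome_exclude`, and weak when `F < f_min`.
#'
#' @param p_exposure Exposure significance threshold (default `5e-8`).
#' @param clump_r2 LD r² above which a SNP is clumped away (default `0.01`).
#' @param clump_window_kb Distance window, in kb, for the position-based
#'   fallback when pairwise r² is unavailable (default `10`).
#' @param p_outcome_exclude Threshold below which a direct outcome association
#'   disqualifies an instrument (default `5e-8`).
#' @param f_min Minimum per-SNP F statistic `(beta/se)²` (default `10`).
#' @param palindromic_maf_limit Minor-allele-frequency limit below which a
#'   palindromic SNP may be oriented by allele-frequency agreement; at or
#'   above it the frequencies are too close to 0.5 to be informative and the
#'   SNP is dropped (default `0.42`).
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(p_exposure = 5e-8, clump_r2 = 0.01,
                             clump_window_kb = 10, p_outcome_exclude = 5e-8,
                             f_min = 10, palindromic_maf_limit = 0.42) {
  stopifnot(p_exposure > 0, p_exposure <= 1,
            clump_r2 >= 0, clump_r2 <= 1,
            clump_window_kb > 0,
            p_outcome_exclude > 0, p_outcome_exclude <= 1,
            f_min >= 0,
            palindromic_maf_limit > 0, palindromic_maf_limit <= 0.5)
  structure(list(p_exposure = p_exposure, clump_r2 = clump_r2,
                 clump_window_kb = clump_window_kb,
                 p_outcome_exclude = p_outcome_exclude, f_min = f_min,
                 palindromic_maf_limit = palindromic_maf_limit),
            class = "selection_config")
}

.add_provenance <- function(tab, stage, dropped) {
  tab$provenance <- c(tab$provenance, stats::setNames(dropped, stage))
  tab
}

#' Keep genome-wide-significant exposure SNPs
#'
#' @param table A `gwas_table` of exposure associations.
#' @param cfg A [selection_config()].
#' @return Filtered `gwas_table` (records with `pvalue < cfg$p_exposure`).
#'   An empty result triggers a warning, not an error.
#' @export
filter_exposure_significant <- function(table, cfg = selection_config()) {
  stopifnot(inherits(table, "gwas_table"), inherits(cfg, "selection_config"))
  keep <- table$data$pvalue < cfg$p_exposure
  out <- table
  out$data <- table$data[keep, , drop = FALSE]
  rownames(out$data) <- NULL
  if (nrow(out$data) == 0) {
    warning(sprintf("no SNPs reach p < %g for '%s'", cfg$p_exposure, table$trait_name))
  }
  .add_provenance(out, "dropped_not_significant", sum(!keep))
}

#' Greedy LD clumping
#'
#' Repeatedly takes the remaining SNP with the smallest p-value (ties broken
#' lexicographically by id) as an index SNP and removes every other remaining
#' SNP in LD with it (`r² > cfg$clump_r2`). When a pair's r² is unavailable
#' but both SNPs carry positions, same-chromosome SNPs within
#' `cfg$clump_window_kb` of the index are removed instead. With neither LD
#' nor positions the table is returned unchanged with a prominent warning.
#'
#' @param table A `gwas_table`, typically already significance-filtered.
#' @param ld An [ld_from_pairs()] / [read_ld()] object, or `NULL`.
#' @param cfg A [selection_config()].
#' @return Clumped `gwas_table` of index SNPs, in selection order.
#' @export
clump <- function(table, ld = NULL, cfg = selection_config()) {
  stopifnot(inherits(table, "gwas_table"))
  df <- table$data
  if (nrow(df) <= 1) return(.add_provenance(table, "dropped_clumped", 0L))
  have_ld <- !is.null(ld)
  have_pos <- !all(is.na(df$pos))
  if (!have_ld && !have_pos) {
    warning("no LD information and no positions: clumping skipped, instruments may be correlated")
    return(.add_provenance(table, "dropped_clumped", 0L))
  }
  ord <- order(df$pvalue, df$snp_id)
  df <- df[ord, , drop = FALSE]
  remaining <- rep(TRUE, nrow(df))
  keep_idx <- integer(0)
  for (i in seq_len(nrow(df))) {
    if (!remaining[i]) next
    keep_idx <- c(keep_idx, i)
    remaining[i] <- FALSE
    others <- which(remaining)
    if (!length(others)) break
    r2 <- if (have_ld) ld_r2(ld, df$snp_id[i], df$snp_id[others]) else rep(0, length(others))
    dep <- r2 > cfg$clump_r2
    # distance fallback where r2 gave no signal and positions exist
    if (have_pos) {
      no_r2 <- !dep & (if (have_ld) r2 == 0 else TRUE)
      near <- no_r2 &
        !is.na(df$pos[others]) & !is.na(df$pos[i]) &
        !is.na(df$chrom[others]) & !is.na(df$chrom[i]) &
        df$chrom[others] == df$chrom[i] &
        abs(df$pos[others] - df$pos[i]) < cfg$clump_window_kb * 1000
      dep <- dep | near
    }
    remaining[others[dep]] <- FALSE
  }
  out <- table
  out$data <- df[keep_idx, , drop = FALSE]
  rownames(out$data) <- NULL
  .add_provenance(out, "dropped_clumped", nrow(table$data) - length(keep_idx))
}

#' Exclude instruments directly associated with the outcome
#'
#' Instruments with a genome-wide-significant direct outcome association
#' (`p < cfg$p_outcome_exclude`) are removed: such SNPs plausibly act on the
#' outcome through pathways other than the exposure. SNPs absent from the
#' outcome table cannot be assessed and are retained (absence is not evidence
#' of association); their count is reported.
#'
#' @param exposure,outcome `gwas_table`s.
#' @param cfg A [selection_config()].
#' @return Filtered exposure `gwas_table`.
#' @export
exclude_outcome_associated <- function(exposure, outcome, cfg = selection_config()) {
  stopifnot(inherits(exposure, "gwas_table"), inherits(outcome, "gwas_table"))
  out_p <- outcome$data$pvalue[match(exposure$data$snp_id, outcome$data$snp_id)]
  unassessed <- is.na(out_p)
  if (any(unassessed)) {
    message(sprintf("%d SNP(s) absent from outcome table retained unassessed",
                    sum(unassessed)))
  }
  drop <- !unassessed & out_p < cfg$p_outcome_exclude
  out <- exposure
  out$data <- exposure$data[!drop, , drop = FALSE]
  rownames(out$data) <- NULL
  .add_provenance(out, "dropped_outcome_associated", sum(drop))
}

#' Harmonize exposure and outcome associations onto a shared effect allele
#'
#' For each SNP present in both tables the outcome association is re-expressed
#' relative to the exposure's effect allele: matching orientations are copied;
#' swapped effect/other alleles negate the outcome beta and reflect its EAF;
#' complementary-strand representations are mapped through the base complement
#' first. Palindromic SNPs (A/T or C/G), whose strand cannot be resolved from
#' alleles alone, are oriented by allele-frequency agreement when both EAFs
#' are present and both minor-allele frequencies fall below
#' `cfg$palindromic_maf_limit`; otherwise they are dropped. Incompatible
#' allele pairs are dropped. Per-SNP instrument strength `F = (gamma/se)²`
#' is computed for every retained record.
#'
#' @param exposure,outcome `gwas_table`s sharing at least one SNP id
#'   (zero overlap is an error).
#' @param cfg A [selection_config()].
#' @return An object of class `instrument_set`: exposure/outcome names, a
#'   data frame of harmonized records (`snp_id`, `gamma`, `se_gamma`, `Gamma`,
#'   `se_Gamma`, `eaf_exposure`, `eaf_outcome`, `pvalue_exposure`, `f_stat`,
#'   `palindromic`, `flipped`), and accumulated provenance counts.
#' @export
harmonize <- function(exposure, outcome, cfg = selection_config()) {
  stopifnot(inherits(exposure, "gwas_table"), inherits(outcome, "gwas_table"))
  shared <- intersect(exposure$data$snp_id, outcome$data$snp_id)
  if (!length(shared)) stop("no shared SNPs between exposure and outcome tables")
  ex <- exposure$data[match(shared, exposure$data$snp_id), ]
  ou <- outcome$data[match(shared, outcome$data$snp_id), ]

  n <- length(shared)
  keep <- rep(TRUE, n)
  flipped <- rep(FALSE, n)
  drop_reason <- rep(NA_character_, n)
  Gamma <- ou$beta
  eaf_out <- ou$eaf

  pal <- is_palindromic_pair(ex$effect_allele, ex$other_allele)
  for (i in seq_len(n)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]
    if (ea_y == ea_x && oa_y == oa_x) {
      flip <- FALSE
    } else if (ea_y == oa_x && oa_y == ea_x) {
      flip <- TRUE
    } else if (!pal[i] && .COMPLEMENT[ea_y] == ea_x && .COMPLEMENT[oa_y] == oa_x) {
      flip <- FALSE
    } else if (!pal[i] && .COMPLEMENT[ea_y] == oa_x && .COMPLEMENT[oa_y] == ea_x) {
      flip <- TRUE
    } else {
      keep[i] <- FALSE; drop_reason[i] <- "incompatible_alleles"; next
    }
    e_out <- if (flip && !is.na(ou$eaf[i])) 1 - ou$eaf[i] else ou$eaf[i]
    g_out <- if (flip) -ou$beta[i] else ou$beta[i]
    if (pal[i]) {
      # strand ambiguity: orient by EAF agreement, demand informative MAFs
      if (is.na(ex$eaf[i]) || is.na(e_out)) {
        keep[i] <- FALSE; drop_reason[i] <- "palindromic_no_eaf"; next
      }
      maf_x <- min(ex$eaf[i], 1 - ex$eaf[i])
      maf_y <- min(e_out, 1 - e_out)
      if (maf_x >= cfg$palindromic_maf_limit || maf_y >= cfg$palindromic_maf_limit) {
        keep[i] <- FALSE; drop_reason[i] <- "palindromic_ambiguous_maf"; next
      }
      if (abs(ex$eaf[i] - e_out) >= abs(ex$eaf[i] - (1 - e_out))) {
        flip <- !flip
        g_out <- -g_out
        e_out <- 1 - e_out
      }
    }
    flipped[i] <- flip
    Gamma[i] <- g_out
    eaf_out[i] <- e_out
  }

  rec <- data.frame(
    snp_id = shared, gamma = ex$beta, se_gamma = ex$se,
    Gamma = Gamma, se_Gamma = ou$se,
    eaf_exposure = ex$eaf, eaf_outcome = eaf_out,
    pvalue_exposure = ex$pvalue,
    f_stat = (ex$beta / ex$se)^2,
    palindromic = pal, flipped = flipped,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(rec) <- NULL

  drops <- table(drop_reason[!keep])
  drop_counts <- if (length(drops)) {
    stats::setNames(as.integer(drops), paste0("dropped_", names(drops)))
  } else integer(0)
  prov <- c(exposure$provenance,
            dropped_unmatched = nrow(exposure$data) - n,
            drop_counts)
  structure(list(exposure_name = exposure$trait_name,
                 outcome_name = outcome$trait_name,
                 outcome_type = outcome$trait_type,
                 records = rec, provenance = prov),
            class = "instrument_set")
}

#' Construct an instrument set from pre-harmonized records
#'
#' For data already aligned to a shared effect allele (e.g. exported from
#' another harmonization tool). `f_stat` is computed, and `palindromic` /
#' `flipped` default to `FALSE` when absent.
#'
#' @param records Data frame with at least `snp_id`, `gamma`, `se_gamma`,
#'   `Gamma`, `se_Gamma`.
#' @param exposure_name,outcome_name Trait labels.
#' @param outcome_type `"binary"` or `"continuous"`.
#' @return An `instrument_set`.
#' @export
instrument_set <- function(records, exposure_name = "exposure",
                           outcome_name = "outcome",
                           outcome_type = c("binary", "continuous")) {
  outcome_type <- match.arg(outcome_type)
  stopifnot(is.data.frame(records),
            all(c("snp_id", "gamma", "se_gamma", "Gamma", "se_Gamma") %in% names(records)))
  if (anyDuplicated(records$snp_id)) stop("snp_id must be unique")
  stopifnot(all(records$se_gamma > 0), all(records$se_Gamma > 0))
  records$f_stat <- (records$gamma / records$se_gamma)^2
  if (is.null(records$palindromic)) records$palindromic <- FALSE
  if (is.null(records$flipped)) records$flipped <- FALSE
  structure(list(exposure_name = exposure_name, outcome_name = outcome_name,
                 outcome_type = outcome_type, records = records,
                 provenance = c(input = nrow(records))),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Harmonized instruments: %s -> %s, %d SNP(s)\n",
              x$exposure_name, x$outcome_name, nrow(x$records)))
  if (nrow(x$records)) print(utils::head(x$records, 6))
  invisible(x)
}

#' Number of instruments in a set
#' @param x An `instrument_set`.
#' @return Integer count.
#' @export
n_instruments <- function(x) {
  stopifnot(inherits(x, "instrument_set"))
  nrow(x$records)
}

#' Remove weak instruments
#'
#' Drops instruments whose per-SNP F statistic `(gamma/se_gamma)²` falls below
#' `cfg$f_min` (strictly), the conventional guard against weak-instrument
#' bias. A boundary value of exactly `f_min` is retained.
#'
#' @param set An `instrument_set`.
#' @param cfg A [selection_config()].
#' @return Filtered `instrument_set`.
#' @export
filter_weak <- function(set, cfg = selection_config()) {
  stopifnot(inherits(set, "instrument_set"))
  keep <- set$records$f_stat >= cfg$f_min
  out <- set
  out$records <- set$records[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  out$provenance <- c(set$provenance, dropped_weak = sum(!keep))
  out
}

#' Run the full instrument-selection cascade
#'
#' Convenience wrapper applying, in order: exposure significance filter, LD
#' clumping, outcome-association exclusion, harmonization, weak-instrument
#' filter, and (optionally) radial outlier pruning.
#'
#' @param exposure,outcome `gwas_table`s.
#' @param ld Optional LD lookup for clumping.
#' @param cfg A [selection_config()].
#' @param radial Apply [radial_filter()] after the F filter (default `TRUE`).
#' @param radial_alpha Per-SNP heterogeneity significance level for radial
#'   pruning (default `0.05`).
#' @return An `instrument_set` ready for [mr_fit()].
#' @export
select_instruments <- function(exposure, outcome, ld = NULL,
                               cfg = selection_config(), radial = TRUE,
                               radial_alpha = 0.05) {
  sig <- filter_exposure_significant(exposure, cfg)
  cl <- clump(sig, ld, cfg)
  ex <- exclude_outcome_associated(cl, outcome, cfg)
  set <- harmonize(ex, outcome, cfg)
  set <- filter_weak(set, cfg)
  if (radial && nrow(set$records) >= 3) {
    rad <- radial_filter(set, alpha = radial_alpha)
    set <- rad$set
    set$radial <- rad$radial
  }
  set
}
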