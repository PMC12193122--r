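# GWAS summary-statistics tables: the format boundary for every pipeline
# stage. A gwas_table wraps one trait's per-SNP associations (alleles, EAF,
# beta, SE, p, N) plus trait metadata; all downstream modules consume it.

.GWAS_COLUMNS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pvalue", "n")

.DEFAULT_COLUMN_MAP <- c(
  snp_id = "SNP", chrom = "chrom", pos = "pos",
  effect_allele = "effect_allele", other_allele = "other_allele",
  eaf = "eaf", beta = "beta", se = "se", pvalue = "pval", n = "n"
)

.MANDATORY_FIELDS <- c("snp_id", "effect_allele", "other_allele", "beta", "se", "pvalue")

#' Construct a GWAS summary-statistics table
#'
#' Validates per-variant association records and wraps them with trait
#' metadata. Rows violating the record invariants (non-SNV or identical
#' alleles, non-positive SE, p outside (0, 1], EAF outside (0, 1), duplicate
#' SNP id) are dropped with a reported count; alleles are upper-cased. When
#' both beta/SE and p are present their mutual consistency under a two-sided
#' normal is checked with tolerance and inconsistencies raise a warning, never
#' an error, so imported values are carried through unaltered.
#'
#' @param data Data frame with (a subset of) columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`.
#'   Missing optional columns are filled with `NA`.
#' @param trait_name Trait label.
#' @param trait_type `"continuous"` (effects in SD units) or `"binary"`
#'   (effects on the log-odds scale; odds ratios reported downstream).
#' @param validate Set `FALSE` to skip row validation (internal use for
#'   already-validated data).
#' @return An object of class `gwas_table`: a list with `trait_name`,
#'   `trait_type`, `data` (validated data frame) and a `provenance` record of
#'   dropped-row counts.
#' @seealso [read_gwas_table()], [write_gwas_table()]
#' @export
gwas_table <- function(data, trait_name, trait_type = c("continuous", "binary"),
                       validate = TRUE) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(data))
  for (col in .GWAS_COLUMNS) {
    if (is.null(data[[col]])) data[[col]] <- NA
  }
  data <- data[.GWAS_COLUMNS]
  data$snp_id <- as.character(data$snp_id)
  data$chrom <- as.character(data$chrom)
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele <- toupper(as.character(data$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n")) {
    data[[col]] <- suppressWarnings(as.numeric(data[[col]]))
  }
  dropped <- 0L
  if (validate && nrow(data)) {
    snv <- data$effect_allele %in% names(.COMPLEMENT) &
      data$other_allele %in% names(.COMPLEMENT)
    ok <- snv &
      data$effect_allele != data$other_allele &
      !is.na(data$beta) & is.finite(data$beta) &
      !is.na(data$se) & data$se > 0 &
      !is.na(data$pvalue) & data$pvalue > 0 & data$pvalue <= 1 &
      (is.na(data$eaf) | (data$eaf > 0 & data$eaf < 1)) &
      !is.na(data$snp_id) & nzchar(data$snp_id)
    ok[is.na(ok)] <- FALSE
    if (any(snv & !ok, na.rm = TRUE) || any(!snv)) {
      n_indel <- sum(!snv)
      if (n_indel > 0) {
        warning(sprintf("%d non-SNV (indel/invalid-allele) rows dropped", n_indel))
      }
    }
    dropped <- sum(!ok)
    if (dropped > 0) {
      message(sprintf("gwas_table('%s'): dropped %d invalid row(s)", trait_name, dropped))
    }
    data <- data[ok, , drop = FALSE]
    dup <- duplicated(data$snp_id)
    if (any(dup)) {
      message(sprintf("gwas_table('%s'): dropped %d duplicate snp_id row(s)",
                      trait_name, sum(dup)))
      dropped <- dropped + sum(dup)
      data <- data[!dup, , drop = FALSE]
    }
    .check_zp_consistency(data, trait_name)
  }
  rownames(data) <- NULL
  structure(
    list(trait_name = trait_name, trait_type = trait_type, data = data,
         provenance = c(input = nrow(data) + dropped, dropped_invalid = dropped)),
    class = "gwas_table"
  )
}

# |z| implied by p vs |beta/se|: warn (not error) on gross inconsistency.
.check_zp_consistency <- function(data, trait_name) {
  idx <- !is.na(data$beta) & !is.na(data$se) & !is.na(data$pvalue) &
    data$pvalue > 1e-280 & data$pvalue < 1
  if (!any(idx)) return(invisible())
  z_obs <- abs(data$beta[idx] / data$se[idx])
  z_p <- stats::qnorm(data$pvalue[idx] / 2, lower.tail = FALSE)
  bad <- abs(z_obs - z_p) > 0.5 & abs(z_obs - z_p) > 0.2 * pmax(z_obs, z_p)
  if (any(bad)) {
    warning(sprintf(
      "gwas_table('%s'): %d row(s) have p-values inconsistent with beta/se under a two-sided normal",
      trait_name, sum(bad)))
  }
  invisible()
}

#' @export
print.gwas_table <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s trait), %d variants\n",
              x$trait_name, x$trait_type, nrow(x$data)))
  if (nrow(x$data)) print(utils::head(x$data, 6))
  invisible(x)
}

#' Number of variant records in a GWAS table
#' @param x A `gwas_table`.
#' @return Integer count of records.
#' @export
n_records <- function(x) {
  stopifnot(inherits(x, "gwas_table"))
  nrow(x$data)
}

#' Read a GWAS summary-statistics file
#'
#' Reads a tab- or comma-separated table with a header row into a validated
#' [gwas_table()]. Column names vary across summary-statistics dialects, so a
#' mapping from internal field names to file column names can be supplied;
#' unmapped fields fall back to the defaults `SNP`, `chrom`, `pos`,
#' `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#'
#' @param path File path.
#' @param column_map Named character vector mapping internal field names
#'   (e.g. `pvalue`) to the file's column names (e.g. `P`). Merged over the
#'   defaults.
#' @param trait_name,trait_type Trait metadata, see [gwas_table()].
#' @return A `gwas_table`.
#' @export
read_gwas_table <- function(path, column_map = NULL, trait_name = basename(path),
                            trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""), check.names = FALSE,
                           comment.char = "")
  map <- .DEFAULT_COLUMN_MAP
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(map))
    if (length(bad)) stop("unknown field(s) in column_map: ", paste(bad, collapse = ", "))
    map[names(column_map)] <- column_map
  }
  missing_mand <- .MANDATORY_FIELDS[!(map[.MANDATORY_FIELDS] %in% names(raw))]
  if (length(missing_mand)) {
    stop(sprintf("mandatory column(s) missing from %s: %s", path,
                 paste(sprintf("%s (expected '%s')", missing_mand, map[missing_mand]),
                       collapse = ", ")))
  }
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (field in names(map)) {
    out[[field]] <- if (map[[field]] %in% names(raw)) raw[[map[[field]]]] else NA
  }
  gwas_table(out, trait_name = trait_name, trait_type = trait_type)
}

#' Write a GWAS table to a tab-separated file
#'
#' Writes the canonical column layout (readable back with default settings);
#' missing values become blank cells. Numeric values are written at full
#' precision so write-then-read is the identity on valid tables.
#'
#' @param table A `gwas_table`.
#' @param path Output path (UTF-8 TSV).
#' @return Invisibly, `path`.
#' @export
write_gwas_table <- function(table, path) {
  stopifnot(inherits(table, "gwas_table"))
  df <- table$data
  out <- data.frame(SNP = df$snp_id, chrom = df$chrom, pos = .fmt_num(df$pos),
                    effect_allele = df$effect_allele, other_allele = df$other_allele,
                    eaf = .fmt_num(df$eaf), beta = .fmt_num(df$beta),
                    se = .fmt_num(df$se), pval = .fmt_num(df$pvalue),
                    n = .fmt_num(df$n), stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "", fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) stop("cannot write to ", path, ": ", conditionMessage(e)))
  invisible(path)
}

.fmt_num <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  out[ok] <- formatC(x[ok], digits = 17, format = "g")
  out
}
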