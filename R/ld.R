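# Pairwise LD (r^2) lookup used by greedy clumping. Stored as a symmetric
# pair-list keyed on sorted SNP ids; absent pairs read as r^2 = 0 and
# self-pairs as 1, so a missing LD panel degrades gracefully to "independent".

#' Build an LD lookup from a pair list
#'
#' @param pairs Data frame with columns `snp_a`, `snp_b`, `r2` (values in
#'   \[0, 1\]). Symmetry is implied; each unordered pair need appear once.
#' @return An object of class `ld_info`.
#' @seealso [read_ld()], [ld_r2()]
#' @export
ld_from_pairs <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("snp_a", "snp_b", "r2") %in% names(pairs)))
  r2 <- as.numeric(pairs$r2)
  if (any(is.na(r2)) || any(r2 < 0 | r2 > 1)) stop("r2 values must lie in [0, 1]")
  a <- as.character(pairs$snp_a)
  b <- as.character(pairs$snp_b)
  key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  lookup <- r2
  names(lookup) <- key
  lookup <- lookup[!duplicated(names(lookup))]
  structure(list(lookup = lookup), class = "ld_info")
}

#' Build an LD lookup from a labelled square matrix
#'
#' @param m Square numeric matrix of r² values with identical row and column
#'   names (SNP ids).
#' @return An object of class `ld_info`.
#' @export
ld_from_matrix <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m))) {
    stop("LD matrix must carry identical row and column SNP-id labels")
  }
  idx <- which(upper.tri(m), arr.ind = TRUE)
  ld_from_pairs(data.frame(
    snp_a = rownames(m)[idx[, 1]],
    snp_b = colnames(m)[idx[, 2]],
    r2 = m[idx],
    stringsAsFactors = FALSE
  ))
}

#' Read LD information from file
#'
#' Accepts either a three-column pair list (`snp_a`, `snp_b`, `r2`) or a
#' labelled square matrix, both tab-separated. The two representations of the
#' same LD structure produce identical lookups.
#'
#' @param path File path.
#' @return An object of class `ld_info`.
#' @export
read_ld <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (all(c("snp_a", "snp_b", "r2") %in% names(raw))) {
    return(ld_from_pairs(raw))
  }
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- as.character(raw[[1]])
  storage.mode(m) <- "double"
  ld_from_matrix(m)
}

#' Look up pairwise r² with symmetric, defaulting semantics
#'
#' @param ld An `ld_info` object (or `NULL`, in which case every pair reads 0).
#' @param a,b SNP ids (vectorised over `b`).
#' @return r² values: 1 for self-pairs, the stored value for known pairs,
#'   0 otherwise.
#' @export
ld_r2 <- function(ld, a, b) {
  if (is.null(ld)) return(ifelse(a == b, 1, 0))
  stopifnot(inherits(ld, "ld_info"))
  key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  out <- unname(ld$lookup[key])
  out[is.na(out)] <- 0
  out[a == b] <- 1
  out
}

#' @export
print.ld_info <- function(x, ...) {
  cat(sprintf("LD lookup: %d stored pair(s)\n", length(x$lookup)))
  invisible(x)
}
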