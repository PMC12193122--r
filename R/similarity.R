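# Fingerprint-based candidate triage: rank score-bearing candidate molecules
# by Tanimoto similarity to approved reference drugs. The file contract is
# fingerprint-agnostic (on-bit index lists or hex strings of any fixed
# width); an optional SMILES path uses the OpenBabel FP2 path fingerprint
# when the chemistry toolkit is installed.

#' Construct a molecular fingerprint
#'
#' @param molecule_id Identifier.
#' @param bits Integer vector of on-bit indices, 0-based, within
#'   `[0, nbits)`. Duplicates are collapsed (set semantics).
#' @param nbits Fingerprint width (default 2048).
#' @return An object of class `fingerprint`.
#' @export
fingerprint <- function(molecule_id, bits, nbits = 2048) {
  bits <- sort(unique(as.integer(bits)))
  if (length(bits) && (min(bits) < 0 || max(bits) >= nbits)) {
    stop("bit indices must lie in [0, nbits)")
  }
  structure(list(molecule_id = as.character(molecule_id), bits = bits,
                 nbits = as.integer(nbits)), class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("fingerprint %s: %d/%d bits on\n", x$molecule_id,
              length(x$bits), x$nbits))
  invisible(x)
}

#' Tanimoto similarity coefficient
#'
#' `|A ∩ B| / |A ∪ B|` over on-bit sets; defined as 0 when both sets are
#' empty. Requires equal fingerprint widths.
#'
#' @param a,b `fingerprint` objects of the same width.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "fingerprint"), inherits(b, "fingerprint"))
  if (a$nbits != b$nbits) stop("fingerprint widths differ")
  inter <- length(intersect(a$bits, b$bits))
  uni <- length(a$bits) + length(b$bits) - inter
  if (uni == 0) return(0)
  inter / uni
}

#' Read fingerprints from a tab-separated file
#'
#' Expects columns `id` and `bits`, plus an optional `score` column carrying
#' an upstream binding score. `bits` is either a comma/semicolon-separated
#' list of 0-based on-bit indices or a hex string of length `nbits/4`.
#'
#' @param path File path.
#' @param nbits Fingerprint width.
#' @return List with `fingerprints` (list of [fingerprint()]) and `scores`
#'   (named numeric, `NA` when no score column).
#' @export
read_fingerprints <- function(path, nbits = 2048) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("id", "bits") %in% names(raw)))
  fps <- lapply(seq_len(nrow(raw)), function(i) {
    fingerprint(raw$id[i], .parse_bits(raw$bits[i], nbits), nbits)
  })
  scores <- if ("score" %in% names(raw)) {
    stats::setNames(as.numeric(raw$score), raw$id)
  } else {
    stats::setNames(rep(NA_real_, nrow(raw)), raw$id)
  }
  list(fingerprints = fps, scores = scores)
}

.parse_bits <- function(s, nbits) {
  s <- trimws(s)
  if (!nzchar(s)) return(integer(0))
  if (!grepl("[,;]", s) && grepl("^[0-9A-Fa-f]+$", s) && nchar(s) == nbits / 4) {
    nib <- strtoi(strsplit(s, "")[[1]], 16L)
    bits <- integer(0)
    for (k in 0:3) bits <- c(bits, which(bitwAnd(nib, bitwShiftL(1L, 3L - k)) > 0) * 4L - 4L + k)
    return(sort(bits))
  }
  as.integer(strsplit(s, "[,;]\\s*")[[1]])
}

#' Fingerprint a molecule from its SMILES string
#'
#' Convenience wrapper around the OpenBabel FP2 path-based fingerprint
#' (1024 bits) provided by the ChemmineOB package; errors with a clear
#' message when the toolkit is not installed. Any other fingerprinter can be
#' used by building [fingerprint()] objects directly.
#'
#' @param molecule_id Identifier.
#' @param smiles SMILES string.
#' @return A 1024-bit [fingerprint()].
#' @export
fingerprint_from_smiles <- function(molecule_id, smiles) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("fingerprint_from_smiles needs the ChemmineOB package; ",
         "supply precomputed fingerprints instead")
  }
  vec <- ChemmineOB::fingerprint_OB(ChemmineOB::forEachMol("SMILES", smiles, identity),
                                    "FP2")
  fingerprint(molecule_id, which(as.numeric(vec) != 0) - 1L, nbits = length(vec))
}

#' Rank candidate molecules by similarity to reference drugs
#'
#' Computes each candidate's best Tanimoto match across the reference set and
#' returns hits sorted by similarity (descending), ties broken by candidate
#' score (descending) then candidate id, truncated to `top_k`. Candidate
#' scores (e.g. upstream binding probabilities) are carried through, never
#' computed here.
#'
#' @param candidates List of [fingerprint()]s.
#' @param references Non-empty list of [fingerprint()]s.
#' @param scores Optional named numeric of candidate scores (by molecule id).
#' @param top_k Maximum hits returned (default all).
#' @return Data frame with `candidate_id`, `reference_id`, `tanimoto`,
#'   `candidate_score`.
#' @export
screen_candidates <- function(candidates, references, scores = NULL, top_k = Inf) {
  stopifnot(length(candidates) >= 1, length(references) >= 1)
  hits <- do.call(rbind, lapply(candidates, function(cand) {
    sims <- vapply(references, function(ref) tanimoto(cand, ref), numeric(1))
    best <- which.max(sims)
    data.frame(candidate_id = cand$molecule_id,
               reference_id = references[[best]]$molecule_id,
               tanimoto = sims[best],
               candidate_score = if (!is.null(scores)) {
                 unname(scores[cand$molecule_id])
               } else NA_real_,
               stringsAsFactors = FALSE)
  }))
  score_key <- ifelse(is.na(hits$candidate_score), -Inf, hits$candidate_score)
  ord <- order(-hits$tanimoto, -score_key, hits$candidate_id)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  utils::head(hits, top_k)
}
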