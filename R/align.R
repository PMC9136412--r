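#' Percent identity between two protein sequences
#'
#' Global ends-free alignment (match +1, mismatch 0, affine gaps: open
#' \eqn{-10}, extend \eqn{-0.5} per residue, end gaps free). Identity is
#' 100 x matches / aligned columns, where the aligned-column count covers
#' internal gap columns but excludes the free end gaps. Traceback ties are
#' broken deterministically: diagonal, then up, then left.
#'
#' Tie-breaking alone would make the identity of co-optimal alignments
#' depend on argument order, so the pair is canonicalised (lexicographic
#' order) before aligning; identity is therefore exactly symmetric.
#'
#' @param a,b Amino-acid sequences (single strings).
#' @param details Return the full list (`score`, `matches`, `columns`,
#'   `identity`) instead of the identity alone.
#' @return Percent identity in `[0, 100]`, or a list if `details = TRUE`.
#' @export
pairwise_identity <- function(a, b, details = FALSE) {
  stopifnot(is.character(a), is.character(b), nzchar(a), nzchar(b))
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  res <- align_overlap_affine(a, b)
  if (details) res else res$identity
}

#' Screen a protein database against the reference conglutins
#'
#' Every database sequence whose best percent identity to any reference is
#' at least `threshold` is returned, annotated with the best-identity
#' reference. This replaces a BLASTp search at desk scale with exhaustive
#' pairwise alignment against the 16 references.
#'
#' @param db A protein record table (the candidate database).
#' @param refs A reference set, as returned by [generate_reference_set()]
#'   or any protein record table with a `subfamily` column.
#' @param threshold Identity threshold in percent, in `(0, 100]`.
#' @return A data.frame with columns `id`, `best_ref`, `identity` for
#'   retained candidates.
#' @export
screen_candidates <- function(db, refs, threshold = 75) {
  stopifnot(threshold > 0, threshold <= 100)
  if (nrow(db) == 0)
    return(data.frame(id = character(0), best_ref = character(0),
                      identity = numeric(0)))
  ref_id <- if ("subfamily" %in% names(refs)) refs$subfamily else refs$id
  best <- t(vapply(db$sequence, function(s) {
    ids <- vapply(refs$sequence, function(r)
      align_overlap_affine(s, r)$identity, numeric(1))
    k <- which.max(ids)
    c(k, ids[k])
  }, numeric(2)))
  out <- data.frame(id = db$id, best_ref = ref_id[best[, 1]],
                    identity = best[, 2], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[out$identity >= threshold, , drop = FALSE]
}
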