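tryptic_sites <- function(sequence) {
  # positions i such that cleavage occurs after residue i:
  # residue i is K or R and residue i+1 (if any) is not P
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  i <- which(chars %in% c("K", "R"))
  i[i == n | chars[pmin(i + 1L, n)] != "P"]
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K/R except when the next residue is P, enumerates
#' all products with up to `max_missed` internal missed cleavages, and
#' filters to the configured length range.
#'
#' @param sequence Protein sequence (single string).
#' @param parent_id Identifier recorded for each peptide.
#' @param max_missed Maximum internal missed cleavages.
#' @param min_len,max_len Peptide length bounds (residues), inclusive.
#' @return A data.frame with columns `sequence`, `parent_id`, `start`,
#'   `end` (1-based inclusive) and `missed_cleavages`.
#' @export
digest <- function(sequence, parent_id = "protein", max_missed = 1,
                   min_len = 8, max_len = 30) {
  empty <- data.frame(sequence = character(0), parent_id = character(0),
                      start = integer(0), end = integer(0),
                      missed_cleavages = integer(0))
  if (!nzchar(sequence)) return(empty)
  n <- nchar(sequence)
  sites <- tryptic_sites(sequence)
  bounds <- c(0L, sites[sites < n], n)  # fragment boundaries
  nfrag <- length(bounds) - 1L
  out <- list()
  for (i in seq_len(nfrag)) {
    for (mc in 0:max_missed) {
      j <- i + mc
      if (j > nfrag) break
      s <- bounds[i] + 1L; e <- bounds[j + 1L]
      len <- e - s + 1L
      if (len < min_len || len > max_len) next
      out[[length(out) + 1L]] <- data.frame(
        sequence = substr(sequence, s, e), parent_id = parent_id,
        start = s, end = e, missed_cleavages = mc,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else empty
}

#' Is a peptide fully tryptic in its parent protein?
#'
#' TRUE iff the peptide occurs in the parent with (a) its N-terminus at
#' the protein start or preceded by K/R with the peptide's first residue
#' not P, and (b) its C-terminal residue K/R with the following residue
#' not P, or at the protein C-terminus. Any qualifying occurrence
#' suffices.
#'
#' @param peptide Peptide sequence.
#' @param parent Parent protein sequence.
#' @return Logical scalar.
#' @export
is_fully_tryptic <- function(peptide, parent) {
  if (!nzchar(peptide) || !nzchar(parent)) return(FALSE)
  np <- nchar(peptide); n <- nchar(parent)
  occ <- as.integer(gregexpr(paste0("(?=", peptide, ")"), parent,
                             perl = TRUE)[[1]])
  if (occ[1] < 1) return(FALSE)
  last <- substr(peptide, np, np)
  first <- substr(peptide, 1, 1)
  for (s in occ) {
    e <- s + np - 1L
    ok_n <- s == 1L ||
      (substr(parent, s - 1L, s - 1L) %in% c("K", "R") && first != "P")
    ok_c <- e == n ||
      (last %in% c("K", "R") && substr(parent, e + 1L, e + 1L) != "P")
    # an internal C-terminus must itself be a cleavage site
    if (e < n && !(last %in% c("K", "R"))) ok_c <- FALSE
    if (ok_n && ok_c) return(TRUE)
  }
  FALSE
}
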