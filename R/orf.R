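#' Predict open reading frames from transcripts
#'
#' Scans all six reading frames of each transcript for ATG-to-stop open
#' reading frames and translates those whose coding length (excluding the
#' stop codon) is at least `min_nt` nucleotides. By default only the
#' longest ORF per stop codon per frame is reported (first ATG after the
#' previous stop); `all_orfs = TRUE` emits every internal ATG as well.
#' Candidate ORFs containing `N` are skipped.
#'
#' @param transcripts A data.frame with columns `id` and `sequence`
#'   (nucleotides over `A`,`C`,`G`,`T`,`N`), or a named character vector.
#' @param min_nt Minimum coding length in nucleotides, excluding the stop
#'   codon.
#' @param all_orfs Report nested ORFs (internal ATGs) as well.
#' @return A protein record table; the description carries the strand,
#'   frame and coordinates of each ORF on its transcript.
#' @export
predict_orfs <- function(transcripts, min_nt = 150, all_orfs = FALSE) {
  if (is.character(transcripts))
    transcripts <- data.frame(id = names(transcripts) %||%
                                paste0("tx", seq_along(transcripts)),
                              sequence = unname(transcripts),
                              stringsAsFactors = FALSE)
  out <- vector("list", nrow(transcripts))
  for (i in seq_len(nrow(transcripts)))
    out[[i]] <- orfs_one(transcripts$id[i],
                         toupper(transcripts$sequence[i]),
                         min_nt, all_orfs)
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- protein_records(character(0), character(0))
  res
}

orfs_one <- function(id, seq, min_nt, all_orfs) {
  if (!nzchar(seq)) stop("empty transcript sequence: ", id)
  if (grepl("[^ACGTN]", seq))
    stop("non-nucleotide characters in transcript ", id)
  hits <- list()
  n <- nchar(seq)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(s = seq)
    for (off in 0:2) {
      ncod <- (nchar(s) - off) %/% 3L
      if (ncod < 2L) next
      codons <- substring(s, off + 1L + 3L * (seq_len(ncod) - 1L),
                          off + 3L * seq_len(ncod))
      aa <- translate_codons(codons)
      stops <- which(aa == "*")
      prev <- 0L
      for (st in stops) {
        atgs <- which(codons == "ATG")
        atgs <- atgs[atgs > prev & atgs < st]
        if (length(atgs)) {
          starts <- if (all_orfs) atgs else atgs[1]
          for (a in starts) {
            coding_nt <- 3L * (st - a)
            if (coding_nt < min_nt) next
            pep <- paste(aa[a:(st - 1L)], collapse = "")
            if (grepl("X", pep, fixed = TRUE)) next  # N in ORF
            nt_start <- off + 3L * (a - 1L) + 1L
            nt_end <- off + 3L * st  # includes stop codon
            hits[[length(hits) + 1L]] <- data.frame(
              id = sprintf("%s_orf%s%d_%d", id, strand, off + 1L, nt_start),
              description = sprintf(
                "strand=%s frame=%d start=%d end=%d coding_nt=%d",
                strand, off + 1L, nt_start, nt_end, coding_nt),
              sequence = pep, stringsAsFactors = FALSE)
          }
        }
        prev <- st
      }
    }
  }
  if (length(hits)) do.call(rbind, hits) else NULL
}

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

translate_codons <- function(codons) {
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"  # codons containing N
  aa
}

#' Remove exact-sequence duplicates from a protein database
#'
#' Records whose sequence is byte-identical to an earlier record are
#' dropped; the first-seen id is retained. The number of removed records
#' is attached as attribute `"removed"`.
#'
#' @param records A protein record table.
#' @return The deduplicated table, with `attr(, "removed")` set.
#' @export
dedupe <- function(records) {
  stopifnot(is.data.frame(records), "sequence" %in% names(records))
  keep <- !duplicated(records$sequence)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- sum(!keep)
  out
}
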