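#' Scan sequences for exact linear-epitope matches
#'
#' Exact substring matching (100% identity) of each epitope against each
#' sequence; every occurrence is reported, including overlapping ones.
#'
#' @param records A protein record table.
#' @param epitopes Character vector of epitope peptides.
#' @return A data.frame with columns `id`, `epitope`, `start` (1-based).
#' @export
scan_epitopes <- function(records, epitopes) {
  stopifnot(length(epitopes) > 0, all(nzchar(epitopes)))
  out <- list()
  for (e in epitopes) {
    # lookahead regex reports overlapping occurrences
    rx <- paste0("(?=", e, ")")
    for (i in seq_len(nrow(records))) {
      m <- gregexpr(rx, records$sequence[i], perl = TRUE)[[1]]
      if (m[1] > 0)
        out[[length(out) + 1L]] <- data.frame(
          id = records$id[i], epitope = e, start = as.integer(m),
          stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(id = character(0), epitope = character(0),
                  start = integer(0))
}
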