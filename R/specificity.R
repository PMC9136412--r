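#' Peptide specificity against a background proteome
#'
#' Finds every background protein containing the peptide as a fully
#' tryptic substring (see [is_fully_tryptic()]) and summarises the result:
#' a single conglutin parent makes the peptide `unique`; several conglutin
#' parents make it a protein `group` (e.g. the beta4,6 group); any
#' non-target parent makes it `nonspecific`; no parent at all is reported
#' as `absent`.
#'
#' @param peptide Peptide sequence.
#' @param background Protein record table (the background proteome).
#' @param targets Named character vector mapping target protein ids to
#'   their subfamily (or group) label; background ids absent from this map
#'   are non-target proteins.
#' @return A list with `status` (`unique`, `group`, `nonspecific`,
#'   `absent`), `parents` (ids containing the peptide) and `target` (label
#'   or comma-separated sorted group label, `NA` if not specific).
#' @export
peptide_specificity <- function(peptide, background, targets) {
  hit <- vapply(seq_len(nrow(background)), function(i)
    is_fully_tryptic(peptide, background$sequence[i]), logical(1))
  parents <- background$id[hit]
  if (length(parents) == 0)
    return(list(status = "absent", parents = character(0),
                target = NA_character_))
  if (any(!parents %in% names(targets)))
    return(list(status = "nonspecific", parents = parents,
                target = NA_character_))
  labels <- sort(unique(unname(targets[parents])))
  list(status = if (length(labels) == 1) "unique" else "group",
       parents = parents,
       target = paste(labels, collapse = ","))
}
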