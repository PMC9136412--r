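#' Construct a protein record table
#'
#' Protein databases are represented throughout the package as plain data
#' frames with columns `id`, `description` and `sequence` (uppercase
#' amino-acid letters, the 20 standard residues plus `X`).
#'
#' @param id Character vector of unique identifiers.
#' @param sequence Character vector of amino-acid sequences.
#' @param description Optional character vector of free-text descriptions.
#' @return A `data.frame` with columns `id`, `description`, `sequence`.
#' @export
protein_records <- function(id, sequence, description = "") {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence))
    stop("'id' and 'sequence' must have the same length")
  if (anyDuplicated(id))
    stop("duplicate record ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (length(sequence) && any(!nzchar(sequence)))
    stop("empty sequences are not allowed")
  data.frame(id = id, description = rep_len(as.character(description),
                                            length(id)),
             sequence = sequence, stringsAsFactors = FALSE)
}

#' Read a FASTA file into a protein record table
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] that tolerates
#' wrapped or unwrapped lines and Windows line endings, normalises residues
#' to uppercase, and reports malformed headers with their line number.
#'
#' @param path Path to a FASTA file.
#' @return A protein record table (see [protein_records()]).
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) && !startsWith(lines[nonempty[1]], ">"))
    stop("malformed FASTA header at line ", nonempty[1],
         ": expected a line starting with '>'")
  x <- Biostrings::readAAStringSet(path)
  nm <- names(x)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  protein_records(id = id, sequence = as.character(x), description = desc)
}

#' Write a protein record table to FASTA
#'
#' @param records A protein record table.
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  stopifnot(is.data.frame(records),
            all(c("id", "sequence") %in% names(records)))
  header <- ifelse(nzchar(records$description %||% ""),
                   paste0(">", records$id, " ", records$description),
                   paste0(">", records$id))
  out <- character(0)
  for (i in seq_len(nrow(records))) {
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    out <- c(out, header[i], substring(s, starts,
                                       pmin(starts + width - 1L, nchar(s))))
  }
  writeLines(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
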