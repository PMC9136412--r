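DEFAULT_ALLOWED_MODS <- c("Carbamidomethyl(C)", "Oxidation(M)",
                          "Gln->pyro-Glu(N-term)")

parse_mods <- function(s) {
  # "Oxidation(M); Carbamidomethyl(C)" -> normalised tokens; NA/"" -> none
  if (is.na(s) || !nzchar(trimws(s)) || identical(trimws(s), "-"))
    return(character(0))
  toks <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  if (any(!grepl("^[^()]+\\([^()]+\\)$", toks))) return(NULL)  # malformed
  tolower(gsub("\\s+", "", toks))
}

#' Filter discovery-peptide observations
#'
#' Removes rows carrying any modification outside the allowed set, rows
#' below the confidence threshold, and (if an `fdr` column is present and
#' `fdr_max` given) rows above the FDR cutoff. Rows with unparseable
#' modification strings are rejected with a warning. Removal counts per
#' reason are attached as `attr(, "removed")`.
#'
#' @param obs A data.frame with columns `accession`, `peptide`,
#'   `modifications`, `confidence`, `protein_id` (and optionally `fdr`).
#' @param allowed_mods Character vector of allowed modification tokens,
#'   `Name(site)` syntax, case-insensitive.
#' @param min_confidence Minimum identification confidence, in `[0, 1]`.
#' @param fdr_max Optional FDR cutoff applied to an `fdr` column.
#' @return The filtered data.frame with a `removed` attribute.
#' @export
filter_observations <- function(obs, allowed_mods = DEFAULT_ALLOWED_MODS,
                                min_confidence = 0.99, fdr_max = NULL) {
  allowed <- tolower(gsub("\\s+", "", allowed_mods))
  reason <- rep(NA_character_, nrow(obs))
  for (i in seq_len(nrow(obs))) {
    toks <- parse_mods(obs$modifications[i])
    if (is.null(toks)) {
      warning("unparseable modification string in row ", i, ": ",
              obs$modifications[i])
      reason[i] <- "unparseable modification"
    } else if (any(!toks %in% allowed)) {
      reason[i] <- "disallowed modification"
    }
  }
  low <- is.na(reason) & obs$confidence < min_confidence
  reason[low] <- "low confidence"
  if (!is.null(fdr_max) && "fdr" %in% names(obs)) {
    high <- is.na(reason) & obs$fdr > fdr_max
    reason[high] <- "high FDR"
  }
  out <- obs[is.na(reason), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- table(reason[!is.na(reason)])
  out
}

#' Cross-accession peptide presence matrix
#'
#' @param obs Filtered observation table (see [filter_observations()]).
#' @param accessions Character vector: the full accession panel.
#' @return A logical matrix, peptides (bare sequence, modifications
#'   collapsed) by accessions; `TRUE` iff the peptide was observed at
#'   least once in that accession.
#' @export
presence_matrix <- function(obs, accessions) {
  bad <- setdiff(unique(obs$accession), accessions)
  if (length(bad))
    stop("observations from accessions outside the panel: ",
         paste(bad, collapse = ", "))
  peptides <- sort(unique(obs$peptide))
  m <- matrix(FALSE, length(peptides), length(accessions),
              dimnames = list(peptides, accessions))
  if (nrow(obs)) m[cbind(obs$peptide, obs$accession)] <- TRUE
  m
}

#' Identification-frequency classes
#'
#' The six frequency classes partition `1..n_accessions` as 1-5, 6-15,
#' 16-25, 26-35, 36-40, 41-`n`. (The third-last/second-last boundary is
#' the corrected non-overlapping form of the published grouping, whose
#' printed classes 26-35 and 35-40 overlap at 35.)
#'
#' @param n_accessions Size of the accession panel (>= 41).
#' @return A data.frame with columns `label`, `lo`, `hi`.
#' @export
frequency_classes <- function(n_accessions = 46) {
  stopifnot(n_accessions >= 41)
  hi <- c(5L, 15L, 25L, 35L, 40L, as.integer(n_accessions))
  lo <- c(1L, head(hi, -1) + 1L)
  data.frame(label = paste0(lo, "-", hi), lo = lo, hi = hi,
             stringsAsFactors = FALSE)
}

#' Assign identification-frequency classes
#'
#' @param count Integer vector of accession counts (1-based).
#' @param n_accessions Size of the accession panel.
#' @return A factor of class labels with levels in class order.
#' @export
assign_frequency_class <- function(count, n_accessions = 46) {
  cls <- frequency_classes(n_accessions)
  if (any(count < 1 | count > n_accessions))
    stop("counts must be in 1..", n_accessions)
  idx <- findInterval(count, cls$lo)
  factor(cls$label[idx], levels = cls$label)
}

#' Map peptides onto reference sequences
#'
#' Exact substring (100% identity) mapping of each peptide onto each
#' reference; every occurrence is reported, including overlapping ones.
#'
#' @param peptides Character vector of peptide sequences, or a data.frame
#'   with columns `peptide` and `class`.
#' @param refs Reference protein record table.
#' @return A data.frame with columns `reference`, `start`, `end` (1-based
#'   inclusive), `peptide`, `class` (`NA` when no classes were supplied).
#'   Per-reference residue coverage fractions are attached as
#'   `attr(, "coverage")`.
#' @export
map_to_references <- function(peptides, refs) {
  if (is.data.frame(peptides)) {
    cls <- as.character(peptides$class)
    peptides <- peptides$peptide
  } else cls <- rep(NA_character_, length(peptides))
  ref_id <- if ("subfamily" %in% names(refs)) refs$subfamily else refs$id
  out <- list()
  covered <- lapply(nchar(refs$sequence), function(n) logical(n))
  names(covered) <- ref_id
  for (k in seq_along(peptides)) {
    p <- peptides[k]
    for (i in seq_len(nrow(refs))) {
      m <- gregexpr(paste0("(?=", p, ")"), refs$sequence[i],
                    perl = TRUE)[[1]]
      if (m[1] < 1) next
      for (s in as.integer(m)) {
        e <- s + nchar(p) - 1L
        covered[[i]][s:e] <- TRUE
        out[[length(out) + 1L]] <- data.frame(
          reference = ref_id[i], start = s, end = e, peptide = p,
          class = cls[k], stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(reference = character(0), start = integer(0),
                         end = integer(0), peptide = character(0),
                         class = character(0))
  attr(res, "coverage") <- vapply(covered, mean, numeric(1))
  res
}

#' Export a peptide coverage table as BED-like intervals
#'
#' @param mapping Result of [map_to_references()].
#' @return A data.frame with 0-based half-open intervals: `chrom`,
#'   `start`, `end`, `name` (peptide), `score` (class label).
#' @export
coverage_bed <- function(mapping) {
  data.frame(chrom = mapping$reference, start = mapping$start - 1L,
             end = mapping$end, name = mapping$peptide,
             score = mapping$class, stringsAsFactors = FALSE)
}
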