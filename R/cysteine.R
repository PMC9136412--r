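#' Parse a cysteine-skeleton pattern
#'
#' Patterns are written in the gap-token grammar used for seed-storage
#' protein cysteine skeletons: `C` is a cysteine, `X` exactly one
#' non-cysteine residue, `Xn` one or more non-cysteine residues, and
#' adjacent `C`s mean a zero-length gap. Internally the pattern is reduced
#' to a vector of gap constraints between consecutive cysteines.
#'
#' @param pattern A pattern string, e.g. `"CXnC"` or the delta-conglutin
#'   skeleton `"CXnCXnCCXnCXCXnCXnCXnC"`.
#' @return An object of class `cys_pattern` with elements `n_cys`,
#'   `gap_min`, `gap_max` (one entry per inter-cysteine gap).
#' @export
cys_pattern <- function(pattern) {
  if (inherits(pattern, "cys_pattern")) return(pattern)
  chars <- strsplit(pattern, "")[[1]]
  tokens <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    if (chars[i] == "C") { tokens <- c(tokens, "C"); i <- i + 1L }
    else if (chars[i] == "X") {
      if (i < length(chars) && chars[i + 1L] == "n") {
        tokens <- c(tokens, "Xn"); i <- i + 2L
      } else { tokens <- c(tokens, "X"); i <- i + 1L }
    } else stop("unrecognised pattern character: ", chars[i])
  }
  ci <- which(tokens == "C")
  if (length(ci) < 2) stop("pattern must contain at least two C tokens")
  if (ci[1] != 1L || ci[length(ci)] != length(tokens))
    stop("pattern must start and end with C")
  gap_min <- gap_max <- integer(length(ci) - 1L)
  for (k in seq_len(length(ci) - 1L)) {
    between <- tokens[seq(ci[k] + 1L, length.out = ci[k + 1L] - ci[k] - 1L)]
    if (length(between) > 1L)
      stop("at most one gap token between consecutive C tokens")
    if (length(between) == 0L) { gap_min[k] <- 0L; gap_max[k] <- 0L }
    else if (between == "X") { gap_min[k] <- 1L; gap_max[k] <- 1L }
    else { gap_min[k] <- 1L; gap_max[k] <- NA_integer_ }  # Xn: >= 1
  }
  structure(list(pattern = pattern, n_cys = length(ci),
                 gap_min = gap_min, gap_max = gap_max),
            class = "cys_pattern")
}

#' Match a cysteine-skeleton pattern against a sequence
#'
#' The cysteine positions of the sequence are reduced to an inter-cysteine
#' gap vector. In windowed mode (the default) the pattern matches if any
#' contiguous run of cysteines satisfies its gap constraints; exact mode
#' requires the full cysteine skeleton of the sequence to match the
#' pattern.
#'
#' @param sequence Amino-acid sequence (single string).
#' @param pattern A `cys_pattern` or pattern string (see [cys_pattern()]).
#' @param windowed Windowed (any run) or exact (full skeleton) matching.
#' @return A list with `match` (logical) and `positions` (1-based cysteine
#'   positions of the first matching window, or `integer(0)`).
#' @export
match_cys_pattern <- function(sequence, pattern, windowed = TRUE) {
  pat <- cys_pattern(pattern)
  pos <- which(strsplit(sequence, "")[[1]] == "C")
  k <- pat$n_cys
  no <- list(match = FALSE, positions = integer(0))
  if (length(pos) < k) return(no)
  gaps <- diff(pos) - 1L
  ok_gap <- function(g, lo, hi) g >= lo & (is.na(hi) | g <= hi)
  if (windowed) {
    for (t in seq_len(length(pos) - k + 1L)) {
      g <- gaps[seq(t, length.out = k - 1L)]
      if (all(ok_gap(g, pat$gap_min, pat$gap_max)))
        return(list(match = TRUE, positions = pos[seq(t, length.out = k)]))
    }
    no
  } else {
    if (length(pos) == k && all(ok_gap(gaps, pat$gap_min, pat$gap_max)))
      list(match = TRUE, positions = pos)
    else no
  }
}

#' Scan sequences for a gap-token motif
#'
#' General motif matching in the same grammar as [cys_pattern()] but with
#' arbitrary residue letters: literal residues match themselves, `X`
#' matches exactly one residue and `Xn` one or more residues of any kind.
#' Used for the semi-conserved beta-conglutin motifs (e.g. `"HYXnR"`),
#' which are reported as annotations, not used as classification gates.
#'
#' @param records A protein record table.
#' @param motif Motif string in the gap-token grammar.
#' @return A data.frame with one row per sequence with a match: `id`,
#'   `motif`, `start` (1-based position of the first match).
#' @export
scan_motif <- function(records, motif) {
  rx <- gsub("Xn", ".+?", motif, fixed = TRUE)
  rx <- gsub("X(?!n)", ".", rx, perl = TRUE)
  hit <- regexpr(rx, records$sequence, perl = TRUE)
  keep <- hit > 0
  data.frame(id = records$id[keep],
             motif = rep_len(motif, sum(keep)),
             start = as.integer(hit[keep]), stringsAsFactors = FALSE)
}
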