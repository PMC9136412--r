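#' Select marker peptides for targeted quantitation
#'
#' Applies the five selection gates in order: (1) specificity to a target
#' protein or protein group, (2) fully tryptic, (3) identification
#' confidence at least `confidence_min`, (4) only allowed modifications,
#' (5) signal-to-noise above `s2n_min`. Survivors with replicate CV above
#' `cv_max` are then dropped, and per target the remainder are ranked by
#' CV ascending, then median intensity descending, keeping the top
#' `top_k`. Every rejection is logged in `attr(, "rejections")`.
#'
#' @param candidates A data.frame with columns `peptide`, `target`,
#'   `specificity` (status from [peptide_specificity()]), `fully_tryptic`
#'   (logical), `confidence`, `mods_ok` (logical), `s2n`,
#'   `median_intensity`, `cv_percent` and optionally `n_transitions`.
#' @param quant Optional abundance set (see [abundance_set()]) used to
#'   compute `median_intensity` (median of accession means) and
#'   `cv_percent` (median replicate CV) when those columns are absent.
#' @param s2n_min Signal-to-noise gate (exclusive lower bound).
#' @param confidence_min Identification-confidence gate (inclusive).
#' @param cv_max Maximum replicate CV (%) retained after the five gates.
#' @param top_k Markers kept per target after ranking.
#' @return The selected marker table, with a `rejections` attribute
#'   logging peptide and failed gate.
#' @export
select_markers <- function(candidates, quant = NULL, s2n_min = 5,
                           confidence_min = 0.95, cv_max = 20,
                           top_k = Inf) {
  x <- candidates
  if (!is.null(quant) &&
      !all(c("median_intensity", "cv_percent") %in% names(x))) {
    acc_means <- accession_means(quant)
    cvs <- replicate_cv(quant)
    x$median_intensity <-
      apply(acc_means[x$peptide, , drop = FALSE], 1, median, na.rm = TRUE)
    x$cv_percent <-
      apply(cvs[x$peptide, , drop = FALSE], 1, median, na.rm = TRUE)
  }
  if (is.null(x$cv_percent)) x$cv_percent <- NA_real_
  if (is.null(x$median_intensity)) x$median_intensity <- 0
  gates <- list(
    specificity = x$specificity %in% c("unique", "group"),
    `fully tryptic` = as.logical(x$fully_tryptic),
    confidence = x$confidence >= confidence_min,
    modifications = as.logical(x$mods_ok),
    `signal to noise` = x$s2n > s2n_min,
    `replicate CV` = is.na(x$cv_percent) | x$cv_percent <= cv_max
  )
  reject_gate <- rep(NA_character_, nrow(x))
  alive <- rep(TRUE, nrow(x))
  for (g in names(gates)) {
    fail <- alive & !gates[[g]]
    reject_gate[fail] <- g
    alive <- alive & gates[[g]]
  }
  kept <- x[alive, , drop = FALSE]
  # per-target ranking: CV ascending, then median intensity descending
  sel <- unlist(lapply(split(seq_len(nrow(kept)), kept$target),
                       function(idx) {
    o <- order(kept$cv_percent[idx], -kept$median_intensity[idx])
    idx[o][seq_len(min(top_k, length(idx)))]
  }), use.names = FALSE)
  ranked_out <- setdiff(seq_len(nrow(kept)), sel)
  out <- kept[sort(sel), , drop = FALSE]
  rownames(out) <- NULL
  rej <- data.frame(
    peptide = c(x$peptide[!is.na(reject_gate)], kept$peptide[ranked_out]),
    gate = c(reject_gate[!is.na(reject_gate)],
             rep("ranked below top_k", length(ranked_out))),
    stringsAsFactors = FALSE)
  attr(out, "rejections") <- rej
  out
}

#' Build an MRM transition table
#'
#' One row per transition, with retention-time scheduling windows of
#' `schedule_window_s` seconds centred on each marker's expected retention
#' time. Markers with fewer than `min_transitions` transitions are
#' excluded with a warning. Transitions are abstract labelled channels:
#' supply them via `transitions` (columns `peptide`, `label`) or let the
#' function synthesise `n_transitions` labels per marker.
#'
#' @param markers Marker table with columns `peptide`, `target` and
#'   optionally `n_transitions` and `rt` (minutes). Missing retention
#'   times are spread evenly over 10-40 minutes in table order.
#' @param transitions Optional data.frame of supplied transitions.
#' @param min_transitions Minimum transitions per retained marker.
#' @param schedule_window_s Scheduling window width, seconds.
#' @return A data.frame with columns `peptide`, `target`, `transition`,
#'   `rt`, `window_start`, `window_end` (minutes).
#' @export
build_transition_table <- function(markers, transitions = NULL,
                                   min_transitions = 3,
                                   schedule_window_s = 60) {
  m <- markers
  if (is.null(m$rt))
    m$rt <- seq(10, 40, length.out = max(nrow(m), 2))[seq_len(nrow(m))]
  if (is.null(transitions)) {
    if (is.null(m$n_transitions))
      stop("markers need 'n_transitions' when no transition list is given")
    transitions <- do.call(rbind, lapply(seq_len(nrow(m)), function(i)
      data.frame(peptide = m$peptide[i],
                 label = paste0("y", seq(3, length.out = m$n_transitions[i])),
                 stringsAsFactors = FALSE)))
  }
  counts <- table(transitions$peptide)
  low <- names(counts)[counts < min_transitions]
  low <- c(low, setdiff(m$peptide, names(counts)))
  if (length(low))
    warning("markers excluded with fewer than ", min_transitions,
            " transitions: ", paste(low, collapse = ", "))
  keep <- m[!m$peptide %in% low & m$peptide %in% names(counts), ,
            drop = FALSE]
  half <- schedule_window_s / 60 / 2
  out <- merge(keep[, c("peptide", "target", "rt")],
               transitions, by = "peptide", sort = FALSE)
  data.frame(peptide = out$peptide, target = out$target,
             transition = out$label, rt = out$rt,
             window_start = out$rt - half, window_end = out$rt + half,
             stringsAsFactors = FALSE)
}
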