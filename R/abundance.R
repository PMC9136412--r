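#' Build an abundance set from a long peak-area table
#'
#' The package's quantitation container: a peptide x run matrix of
#' positive peak areas plus per-run metadata (accession, replicate, batch,
#' injection order). Runs are keyed as `<accession>_r<replicate>`.
#'
#' @param long A data.frame with columns `peptide`, `accession`,
#'   `replicate`, `batch`, `injection_order`, `area`.
#' @return An object of class `abundance_set`: list with `areas` (matrix)
#'   and `runs` (data.frame).
#' @export
abundance_set <- function(long) {
  need <- c("peptide", "accession", "replicate", "batch",
            "injection_order", "area")
  stopifnot(all(need %in% names(long)))
  run_id <- paste0(long$accession, "_r", long$replicate)
  runs <- unique(data.frame(run_id = run_id, accession = long$accession,
                            replicate = long$replicate, batch = long$batch,
                            injection_order = long$injection_order,
                            stringsAsFactors = FALSE))
  runs <- runs[order(runs$injection_order), , drop = FALSE]
  rownames(runs) <- NULL
  if (anyDuplicated(runs$run_id))
    stop("inconsistent run metadata: duplicated run ids")
  if (anyDuplicated(runs$injection_order))
    stop("injection orders must be unique")
  if (length(unique(table(runs$accession))) > 1)
    stop("every accession must have the same replicate count")
  peptides <- sort(unique(long$peptide))
  m <- matrix(NA_real_, length(peptides), nrow(runs),
              dimnames = list(peptides, runs$run_id))
  m[cbind(long$peptide, run_id)] <- long$area
  if (any(m[!is.na(m)] <= 0)) stop("peak areas must be positive")
  structure(list(areas = m, runs = runs), class = "abundance_set")
}

#' @export
print.abundance_set <- function(x, ...) {
  cat("abundance_set:", nrow(x$areas), "peptides x", ncol(x$areas),
      "runs (", length(unique(x$runs$accession)), "accessions,",
      length(unique(x$runs$batch)), "batches )\n")
  invisible(x)
}

#' Log10 peak areas of an abundance set
#' @param x An `abundance_set`.
#' @return Numeric matrix of log10 areas.
#' @export
log_areas <- function(x) {
  stopifnot(inherits(x, "abundance_set"))
  log10(x$areas)
}

#' Per-accession mean areas
#' @param x An `abundance_set`.
#' @return Peptide x accession matrix of mean linear-scale areas over
#'   replicates.
#' @export
accession_means <- function(x) {
  stopifnot(inherits(x, "abundance_set"))
  acc <- unique(x$runs$accession)
  out <- vapply(acc, function(a)
    rowMeans(x$areas[, x$runs$run_id[x$runs$accession == a],
                     drop = FALSE]),
    numeric(nrow(x$areas)))
  if (is.null(dim(out)))
    out <- matrix(out, nrow = 1, dimnames = list(rownames(x$areas), acc))
  out
}

#' Remove the batch effect from peak areas
#'
#' Per peptide, fits by least squares on the log10 scale
#' `value = intercept + beta * injection_order + batch effects` with
#' sum-to-zero batch coding, and subtracts only the fitted batch terms;
#' the injection-order covariate and residual structure are retained.
#' Within-batch contrasts are unchanged.
#'
#' @param x An `abundance_set` with at least two batches, each with at
#'   least two runs.
#' @return An `abundance_set` whose areas are the corrected values mapped
#'   back to the linear scale (`10^corrected`); the fitted per-batch
#'   log10 effects are attached as `attr(, "batch_effects")` (peptides x
#'   batches).
#' @export
remove_batch_effect <- function(x) {
  stopifnot(inherits(x, "abundance_set"))
  batch <- factor(x$runs$batch)
  if (nlevels(batch) < 2) stop("need at least 2 batches")
  if (any(table(batch) < 2)) stop("every batch needs at least 2 runs")
  y <- log_areas(x)
  if (anyNA(y)) stop("missing areas; apply an imputation policy first")
  contrasts(batch) <- contr.sum(nlevels(batch))
  B <- model.matrix(~batch)[, -1, drop = FALSE]
  X <- cbind(intercept = 1, injection = x$runs$injection_order, B)
  fit <- lm.fit(X, t(y))
  coefs <- fit$coefficients
  if (is.null(dim(coefs)))
    coefs <- matrix(coefs, ncol = 1,
                    dimnames = list(names(coefs), rownames(y)))
  beta_batch <- t(coefs[colnames(B), , drop = FALSE])
  corrected <- y - beta_batch %*% t(B)
  out <- x
  out$areas <- 10^corrected
  # fitted per-batch log10 effects, columns in batch level order
  attr(out, "batch_effects") <-
    `colnames<-`(beta_batch %*% t(contr.sum(nlevels(batch))),
                 levels(batch))
  attr(out, "injection_effects") <- coefs["injection", ]
  out
}

#' Replicate coefficient of variation
#'
#' @param x An `abundance_set` (linear-scale areas).
#' @return Peptide x accession matrix of CV percentages
#'   (100 x sample sd / mean over replicates); `NA` where the mean is 0
#'   or replicates are missing.
#' @export
replicate_cv <- function(x) {
  stopifnot(inherits(x, "abundance_set"))
  acc <- unique(x$runs$accession)
  out <- vapply(acc, function(a) {
    m <- x$areas[, x$runs$run_id[x$runs$accession == a], drop = FALSE]
    if (ncol(m) < 2) stop("need >= 2 replicates per accession")
    mu <- rowMeans(m)
    s <- apply(m, 1, sd)
    ifelse(is.na(mu) | mu == 0, NA_real_, 100 * s / mu)
  }, numeric(nrow(x$areas)))
  if (is.null(dim(out)))
    out <- matrix(out, nrow = 1, dimnames = list(rownames(x$areas), acc))
  out
}

#' Percent-of-average normalisation
#'
#' @param values Numeric vector of per-accession values (means over
#'   replicates).
#' @return `100 * values / mean(values)`; the output always averages 100.
#' @export
percent_of_average <- function(values) {
  if (length(values) < 1) stop("need at least one accession")
  m <- mean(values)
  if (!is.finite(m) || m == 0)
    stop("percent-of-average undefined: mean of values is 0 or not finite")
  100 * values / m
}

family_of_target <- function(target) {
  fams <- unique(sub("[0-9].*$", "", strsplit(target, ",")[[1]]))
  if (length(fams) != 1)
    stop("marker target spans multiple families: ", target)
  fams
}

#' Family- and subfamily-level conglutin profiles
#'
#' Sums the per-accession mean areas of the marker peptides belonging to
#' each conglutin family (peptides assigned to a protein group contribute
#' to the group's family), then converts each family's totals to percent
#' of the panel average. Subfamily/group-level percent profiles are
#' computed the same way per target.
#'
#' @param x An `abundance_set` containing the marker peptides.
#' @param marker_map Named character vector: peptide -> target subfamily
#'   or comma-separated group label (e.g. `"beta4,beta6"`), or a
#'   data.frame with columns `peptide` and `target`.
#' @return A list of class `conglutin_profile` with elements `family`
#'   (family x accession percent matrix), `subfamily` (target x accession
#'   percent matrix) and `family_total` (raw summed areas).
#' @export
family_abundance <- function(x, marker_map) {
  if (is.data.frame(marker_map))
    marker_map <- setNames(marker_map$target, marker_map$peptide)
  peptides <- rownames(x$areas)
  missing <- setdiff(peptides, names(marker_map))
  if (length(missing))
    stop("unmapped marker peptides: ", paste(missing, collapse = ", "))
  am <- accession_means(x)
  target <- unname(marker_map[peptides])
  fam <- vapply(target, family_of_target, character(1))
  sum_by <- function(groups) {
    t(vapply(split(seq_along(groups), groups), function(idx)
      colSums(am[idx, , drop = FALSE]), numeric(ncol(am))))
  }
  fam_tot <- sum_by(fam)
  sub_tot <- sum_by(target)
  structure(list(
    family = t(apply(fam_tot, 1, percent_of_average)),
    subfamily = t(apply(sub_tot, 1, percent_of_average)),
    family_total = fam_tot), class = "conglutin_profile")
}

#' Missing-value policy before multivariate analysis
#'
#' Drops peptides missing in more than `max_missing` of the runs and
#' imputes the remaining missing cells with half the peptide's minimum
#' observed value.
#'
#' @param mat Peptide x run numeric matrix (linear scale), `NA` = missing.
#' @param max_missing Maximum tolerated missing fraction per peptide.
#' @return The imputed matrix, possibly with fewer rows.
#' @export
impute_matrix <- function(mat, max_missing = 0.5) {
  frac <- rowMeans(is.na(mat))
  mat <- mat[frac <= max_missing, , drop = FALSE]
  for (i in seq_len(nrow(mat))) {
    na <- is.na(mat[i, ])
    if (any(na)) mat[i, na] <- min(mat[i, !na]) / 2
  }
  mat
}
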