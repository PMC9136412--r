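#' Batch-corrected conglutin profiling run
#'
#' The quantitation-side pipeline in one call: batch correction on the
#' log10 scale, replicate-CV report, subfamily/family relative-abundance
#' profiles, PCA and hierarchical clustering of the accession-level
#' peptide matrix, and (optionally) per-family ANOVA + Dunnett
#' comparisons of family percentages against a control accession group.
#'
#' @param abundance An [abundance_set()] of marker-peptide peak areas.
#' @param marker_map Named vector or data.frame mapping peptide ->
#'   target subfamily/group (see [family_abundance()]).
#' @param control Optional: a character vector of accession ids treated
#'   as the comparison groups' control in Dunnett testing of family
#'   percentages (one group per accession is only sensible with
#'   replicate-level profiles, so the test here compares accession
#'   groups defined by `groups`).
#' @param groups Optional named vector accession -> group label for the
#'   Dunnett step; ignored when `control` is `NULL`.
#' @return List with `corrected` (abundance set), `cv` (peptide x
#'   accession CV matrix), `profile` (see [family_abundance()]), `pca`,
#'   `hca`, and `dunnett` (or `NULL`).
#' @export
run_profiling <- function(abundance, marker_map, control = NULL,
                          groups = NULL) {
  corrected <- remove_batch_effect(abundance)
  cv <- replicate_cv(corrected)
  profile <- family_abundance(corrected, marker_map)
  m <- t(log10(accession_means(corrected)))  # accessions x peptides
  pca <- pca_profiles(m)
  hca <- hca_profiles(m)
  dunnett <- NULL
  if (!is.null(control) && !is.null(groups)) {
    dunnett <- lapply(rownames(profile$family), function(fam) {
      acc <- colnames(profile$family)
      anova_dunnett(profile$family[fam, acc], groups[acc], control)
    })
    names(dunnett) <- rownames(profile$family)
  }
  list(corrected = corrected, cv = cv, profile = profile, pca = pca,
       hca = hca, dunnett = dunnett)
}

parse_cli_args <- function(args, defaults) {
  out <- defaults
  i <- 1L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    key <- gsub("-", "_", key)
    if (!key %in% names(out)) stop("unknown option --", args[i])
    out[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `db build`, `annotate classify`, `conserve map`,
#' `assay select`, `quant run`. Invoke from `Rscript -e
#' 'conglutinr::conglutin_cli()'` or the `inst/cli/conglutin` script.
#'
#' @param args Command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Invisibly, the main result object of the subcommand.
#' @export
conglutin_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 2) {
    message("usage: conglutin <db|annotate|conserve|assay|quant> ",
            "<subcommand> [--options]")
    return(invisible(NULL))
  }
  cmd <- paste(args[1], args[2])
  rest <- args[-(1:2)]
  res <- switch(cmd,
    "db build" = {
      o <- parse_cli_args(rest, list(transcripts = NULL, proteins = NULL,
                                     min_orf_nt = "150", out = "db.fasta"))
      recs <- NULL
      if (!is.null(o$transcripts))
        recs <- predict_orfs(read_fasta(o$transcripts),
                             min_nt = as.integer(o$min_orf_nt))
      if (!is.null(o$proteins))
        recs <- rbind(recs, read_fasta(o$proteins))
      if (is.null(recs)) stop("need --transcripts and/or --proteins")
      dd <- dedupe(recs)
      write_fasta(dd, o$out)
      message("db build: ", nrow(recs), " in, ", nrow(dd), " out, ",
              attr(dd, "removed"), " duplicates removed")
      dd
    },
    "annotate classify" = {
      o <- parse_cli_args(rest, list(db = NULL, refs = NULL,
                                     domains = NULL,
                                     identity_threshold = "75",
                                     out = "classification.tsv"))
      db <- read_fasta(o$db)
      refs <- read_fasta(o$refs)
      refs$subfamily <- refs$id
      dom <- if (!is.null(o$domains)) read.delim(o$domains) else NULL
      cl <- classify(db, refs, as.numeric(o$identity_threshold), dom)
      write.table(cl[, c("id", "status", "family", "subfamily",
                         "identity")],
                  o$out, sep = "\t", quote = FALSE, row.names = FALSE)
      cl
    },
    "conserve map" = {
      o <- parse_cli_args(rest, list(obs = NULL, refs = NULL,
                                     accessions = NULL,
                                     min_confidence = "0.99",
                                     out = "coverage.tsv"))
      obs <- read.delim(o$obs, stringsAsFactors = FALSE)
      refs <- read_fasta(o$refs)
      acc <- if (is.null(o$accessions)) unique(obs$accession)
             else strsplit(o$accessions, ",")[[1]]
      f <- filter_observations(obs,
                               min_confidence = as.numeric(o$min_confidence))
      pm <- presence_matrix(f, acc)
      cls <- assign_frequency_class(rowSums(pm), length(acc))
      mp <- map_to_references(
        data.frame(peptide = rownames(pm), class = cls), refs)
      write.table(mp, o$out, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      mp
    },
    "assay select" = {
      o <- parse_cli_args(rest, list(candidates = NULL, s2n_min = "5",
                                     top_k = "Inf", cv_max = "20",
                                     out = "markers.tsv"))
      cand <- read.delim(o$candidates, stringsAsFactors = FALSE)
      sel <- select_markers(cand, s2n_min = as.numeric(o$s2n_min),
                            cv_max = as.numeric(o$cv_max),
                            top_k = as.numeric(o$top_k))
      write.table(sel, o$out, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      sel
    },
    "quant run" = {
      o <- parse_cli_args(rest, list(abundance = NULL, markers = NULL,
                                     out = "profile"))
      long <- read.delim(o$abundance, stringsAsFactors = FALSE)
      mm <- read.delim(o$markers, stringsAsFactors = FALSE)
      res <- run_profiling(abundance_set(long), mm)
      write.table(t(res$profile$family),
                  paste0(o$out, "_family_percent.tsv"), sep = "\t",
                  quote = FALSE)
      write.table(res$pca$scores, paste0(o$out, "_pca_scores.tsv"),
                  sep = "\t", quote = FALSE)
      writeLines(res$hca$newick, paste0(o$out, "_hca.nwk"))
      res
    },
    stop("unknown subcommand: ", cmd))
  invisible(res)
}
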