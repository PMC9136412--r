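sample_aa <- function(n, exclude_c = FALSE) {
  p <- AA_FREQS
  if (exclude_c) p <- p[names(p) != "C"] / sum(p[names(p) != "C"])
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

plant_cys <- function(sequence, positions) {
  chars <- strsplit(sequence, "")[[1]]
  chars[positions] <- "C"
  paste(chars, collapse = "")
}

# Point-mutate `n_mut` positions. Cysteine positions are never touched,
# substitutions never introduce a cysteine, and positions outside the
# given domain windows are exhausted first, so planted identity can be
# lowered without destroying the structural features.
mutate_sequence <- function(sequence, n_mut, domains = NULL) {
  chars <- strsplit(sequence, "")[[1]]
  ok <- which(chars != "C")
  in_dom <- rep(FALSE, length(chars))
  if (!is.null(domains) && nrow(domains))
    for (r in seq_len(nrow(domains)))
      in_dom[domains$start[r]:domains$end[r]] <- TRUE
  pool <- c(sample(ok[!in_dom[ok]]), sample(ok[in_dom[ok]]))
  if (n_mut > length(pool))
    stop("cannot place ", n_mut, " mutations outside cysteines")
  sub_from <- setdiff(AA_LETTERS, "C")
  for (p in pool[seq_len(n_mut)]) {
    chars[p] <- sample(setdiff(sub_from, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' The default 46-accession panel (16 domesticated, 30 wild)
#' @return Character vector `D1..D16`, `W1..W30`.
#' @export
default_accessions <- function() c(paste0("D", 1:16), paste0("W", 1:30))

#' Generate the 16 synthetic reference conglutins
#'
#' Emits 3 alpha, 7 beta, 4 delta and 2 gamma reference sequences with
#' the family-diagnostic structural features planted: alpha and gamma
#' carry `CXnC` cysteine pairs, beta sequences contain no cysteine at
#' all, and delta sequences carry the nine-cysteine prolamin skeleton.
#' beta6 is generated as a 97.8%-identity variant of beta4 and delta3 as
#' a 98.7%-identity variant of delta1, mirroring the near-identical
#' subfamily pairs that force protein-group quantitation. The attached
#' domain table places two `cupin_1` windows for alpha (36-201, 405-552)
#' and beta (180-330, 390-551), `TAXi_N` (62-237) and `TAXi_C` (269-430)
#' for gamma, and a `tryp_alpha_amyl` domain for delta2.
#'
#' @param seed RNG seed; generation is bit-reproducible under a fixed
#'   seed.
#' @return A protein record table with extra columns `subfamily` and
#'   `family`, and the domain table as `attr(, "domains")`.
#' @export
generate_reference_set <- function(seed = 1) {
  with_seed(seed, {
    lens <- c(alpha = 570L, beta = 560L, delta = 150L, gamma = 450L)
    cys <- list(alpha = c(12L, 18L, 370L, 376L),
                beta = integer(0),
                delta = c(15L, 25L, 35L, 36L, 45L, 47L, 60L, 75L, 90L),
                gamma = c(20L, 30L, 250L, 258L))
    recs <- list(); doms <- list()
    for (i in seq_len(nrow(CONGLUTIN_SUBFAMILIES))) {
      sf <- CONGLUTIN_SUBFAMILIES$subfamily[i]
      fam <- CONGLUTIN_SUBFAMILIES$family[i]
      dom <- FAMILY_DOMAIN_WINDOWS[[fam]]
      if (identical(sf, "delta2"))
        dom <- data.frame(name = "tryp_alpha_amyl", start = 25L,
                          end = 140L)
      if (sf == "beta6") {
        base <- recs[["beta4"]]$sequence
        s <- mutate_sequence(base, round(nchar(base) * 0.022), dom)
      } else if (sf == "delta3") {
        base <- recs[["delta1"]]$sequence
        s <- mutate_sequence(base, 2L, dom)
      } else {
        s <- sample_aa(lens[[fam]], exclude_c = TRUE)
        s <- plant_cys(s, cys[[fam]])
      }
      recs[[sf]] <- data.frame(
        id = sf, description = paste0("synthetic ", fam,
                                      "-conglutin reference"),
        sequence = s, subfamily = sf, family = fam,
        stringsAsFactors = FALSE)
      if (!is.null(dom))
        doms[[sf]] <- cbind(id = sf, dom, stringsAsFactors = FALSE)
    }
    refs <- do.call(rbind, recs)
    rownames(refs) <- NULL
    attr(refs, "domains") <- do.call(rbind, c(doms,
                                              make.row.names = FALSE))
    refs
  })
}

#' Domain table of a reference set
#' @param refs Result of [generate_reference_set()].
#' @return Data.frame with columns `id`, `name`, `start`, `end`.
#' @export
ref_domains <- function(refs) attr(refs, "domains")

#' Generate a candidate protein database with known ground truth
#'
#' Variants are point-mutated copies of the references at a controlled
#' planted identity, decoys are residue-frequency-matched random
#' sequences rejection-sampled until their identity to every reference is
#' below 70% (a clear margin under the 75% screen), and duplicates are
#' exact copies of existing entries.
#'
#' @param refs Reference set from [generate_reference_set()].
#' @param n_variants,n_decoys,n_duplicates Entry counts (>= 0).
#' @param identity Planted percent identity of the variants, in
#'   `[0, 100]`.
#' @param seed RNG seed.
#' @return A list with `db` (protein record table), `domains`
#'   (domain-annotation rows for the variants) and `truth` (list with
#'   `family_assignments`, `planted_identity`, `decoys`, `duplicates`).
#' @export
generate_candidate_db <- function(refs, n_variants = 20, n_decoys = 10,
                                  n_duplicates = 2, identity = 90,
                                  seed = 1) {
  if (identity < 0 || identity > 100)
    stop("planted identity must be in [0, 100]")
  stopifnot(n_variants >= 0, n_decoys >= 0, n_duplicates >= 0)
  rdom <- ref_domains(refs)
  with_seed(seed, {
    recs <- list(); doms <- list()
    fa <- list(); pid <- numeric(0)
    for (v in seq_len(n_variants)) {
      i <- (v - 1L) %% nrow(refs) + 1L
      id <- sprintf("var%02d", v)
      dom <- rdom[rdom$id == refs$id[i], , drop = FALSE]
      L <- nchar(refs$sequence[i])
      s <- mutate_sequence(refs$sequence[i],
                           round(L * (1 - identity / 100)), dom)
      recs[[id]] <- data.frame(
        id = id, description = paste0("variant of ", refs$subfamily[i]),
        sequence = s, stringsAsFactors = FALSE)
      if (nrow(dom)) { dom$id <- id; doms[[id]] <- dom }
      fa[[id]] <- data.frame(id = id, family = refs$family[i],
                             subfamily = refs$subfamily[i],
                             stringsAsFactors = FALSE)
      pid[id] <- identity
    }
    for (d in seq_len(n_decoys)) {
      id <- sprintf("decoy%02d", d)
      repeat {
        s <- sample_aa(nchar(sample(refs$sequence, 1)))
        best <- max(vapply(refs$sequence, function(r)
          align_overlap_affine(s, r)$identity, numeric(1)))
        if (best < 70) break
      }
      recs[[id]] <- data.frame(id = id, description = "decoy",
                               sequence = s, stringsAsFactors = FALSE)
    }
    dup_src <- character(0)
    if (n_duplicates > 0) {
      if (length(recs) == 0) stop("no entries to duplicate")
      src <- sample(names(recs), n_duplicates, replace = TRUE)
      for (k in seq_len(n_duplicates)) {
        id <- sprintf("dup%02d", k)
        recs[[id]] <- data.frame(
          id = id, description = paste0("duplicate of ", src[k]),
          sequence = recs[[src[k]]]$sequence, stringsAsFactors = FALSE)
      }
      dup_src <- src
    }
    db <- do.call(rbind, c(recs, make.row.names = FALSE))
    list(db = db,
         domains = if (length(doms)) do.call(rbind, c(doms,
                     make.row.names = FALSE)) else NULL,
         truth = list(
           family_assignments = do.call(rbind, c(fa,
             make.row.names = FALSE)),
           planted_identity = pid,
           decoys = grep("^decoy", db$id, value = TRUE),
           duplicates = if (n_duplicates > 0)
             data.frame(id = sprintf("dup%02d", seq_len(n_duplicates)),
                        source = dup_src, stringsAsFactors = FALSE)
             else NULL))
  })
}

#' Generate per-accession peptide identification tables
#'
#' Draws a pool of tryptic peptides from the reference sequences,
#' assigns each to one of the six identification-frequency classes, and
#' emits observation rows in a number of accessions sampled uniformly
#' inside the class interval. Extra rows exercising the downstream
#' filters are added: duplicated observations with confidence below
#' threshold or with a disallowed modification, plus junk peptides whose
#' every row is filterable.
#'
#' @param refs Reference set.
#' @param accessions Accession panel (default the 46-accession panel).
#' @param class_counts Named integer vector: peptides per frequency
#'   class. The default mirrors a 244-peptide panel: 42 peptides in
#'   class 1-5, 30 in 6-15, 30 in 16-25, 28 in 26-35, 28 in 36-40 and
#'   86 in 41-46 (scaled down proportionally if the reference digest
#'   yields fewer peptides).
#' @param seed RNG seed.
#' @return A list with `obs` (columns `accession`, `peptide`,
#'   `modifications`, `confidence`, `protein_id`) and `truth` (designed
#'   `classes`, `counts`, `presence` matrix and `class_counts`).
#' @export
generate_identification_tables <- function(refs,
                                           accessions = default_accessions(),
                                           class_counts = NULL,
                                           seed = 1) {
  cls <- frequency_classes(length(accessions))
  if (is.null(class_counts))
    class_counts <- setNames(c(42L, 30L, 30L, 28L, 28L, 86L), cls$label)
  stopifnot(all(names(class_counts) %in% cls$label))
  with_seed(seed, {
    pool <- unique(unlist(lapply(seq_len(nrow(refs)), function(i)
      digest(refs$sequence[i], refs$id[i])$sequence)))
    n_need <- sum(class_counts)
    if (length(pool) < n_need) {
      scale <- length(pool) / n_need
      class_counts <- pmax(1L, floor(class_counts * scale))
    }
    pool <- sample(pool)
    peptides <- pool[seq_len(sum(class_counts))]
    classes <- rep(names(class_counts), class_counts)
    first_parent <- vapply(peptides, function(p)
      refs$id[grepl(p, refs$sequence, fixed = TRUE)][1], character(1))
    rows <- list(); counts <- integer(0)
    for (k in seq_along(peptides)) {
      b <- cls[cls$label == classes[k], ]
      cnt <- sample(b$lo:b$hi, 1)
      counts[peptides[k]] <- cnt
      accs <- sample(accessions, cnt)
      has_m <- grepl("M", peptides[k], fixed = TRUE)
      mods <- ifelse(has_m & runif(cnt) < 0.2, "Oxidation(M)", "")
      rows[[k]] <- data.frame(
        accession = accs, peptide = peptides[k], modifications = mods,
        confidence = round(runif(cnt, 0.991, 0.9999), 4),
        protein_id = unname(first_parent[k]), stringsAsFactors = FALSE)
    }
    obs <- do.call(rbind, rows)
    # duplicated rows that the filters must remove
    idx <- sample(nrow(obs), max(1, round(0.08 * nrow(obs))))
    lowconf <- obs[idx, ]; lowconf$confidence <- 0.94
    idx2 <- sample(nrow(obs), max(1, round(0.05 * nrow(obs))))
    badmod <- obs[idx2, ]; badmod$modifications <- "Phospho(S)"
    # junk peptides: all of their rows are filterable
    junk <- replicate(10, sample_aa(12))
    junk_rows <- do.call(rbind, lapply(seq_along(junk), function(j) {
      accs <- sample(accessions, sample(3:8, 1))
      half <- seq_along(accs) <= length(accs) / 2
      data.frame(accession = accs, peptide = junk[j],
                 modifications = ifelse(half, "Phospho(S)", ""),
                 confidence = ifelse(half, 0.995, 0.93),
                 protein_id = "junk", stringsAsFactors = FALSE)
    }))
    obs_all <- rbind(obs, lowconf, badmod, junk_rows)
    obs_all <- obs_all[sample(nrow(obs_all)), , drop = FALSE]
    rownames(obs_all) <- NULL
    presence <- presence_matrix(obs, accessions)
    list(obs = obs_all,
         truth = list(classes = setNames(classes, peptides),
                      counts = counts, presence = presence,
                      class_counts = class_counts))
  })
}

#' Default suppression design: beta2-beta6 lost in D1-D6
#'
#' @param factor Suppression factor (fraction of baseline abundance).
#' @return Data.frame with columns `accession`, `subfamily`, `factor`.
#' @export
default_suppression <- function(factor = 0.01) {
  g <- expand.grid(accession = paste0("D", 1:6),
                   subfamily = paste0("beta", 2:6),
                   stringsAsFactors = FALSE)
  g$factor <- factor
  g
}

#' Generate an MRM peak-area matrix with planted effects
#'
#' Log10 abundance of each run is the sum of a per-peptide baseline, a
#' per-accession genotype effect, a suppression term for the planted
#' (accession, subfamily) pairs, a per-batch offset, a linear
#' injection-order drift, and log-normal replicate noise whose sigma is
#' chosen so the linear-scale CV equals the target
#' (`sigma = sqrt(log(1 + cv^2))`). Runs are randomised in injection
#' order; the first half of the injection sequence is batch `B1`, the
#' second half `B2`.
#'
#' @param markers Data.frame with columns `peptide` and `target`
#'   (subfamily or comma-separated group label), or a named vector
#'   peptide -> target.
#' @param accessions Accession panel.
#' @param suppressed Suppression design (see [default_suppression()]);
#'   `NULL` for none.
#' @param replicate_cv Target replicate coefficient of variation, percent
#'   (>= 0).
#' @param batch_offsets Length-2 numeric: log10 offset of each batch.
#' @param drift Total log10 drift across the full injection sequence.
#' @param genotype_sd Std. dev. of the per-accession-per-peptide biological
#'   effect (log10).
#' @param n_replicates Technical replicates per accession.
#' @param seed RNG seed.
#' @return List with `abundance` (an [abundance_set()]) and `truth`
#'   (design parameters and the noise-free `log10_design` matrix).
#' @export
generate_abundance_matrix <- function(markers,
                                      accessions = default_accessions(),
                                      suppressed = default_suppression(),
                                      replicate_cv = 10,
                                      batch_offsets = c(0, 0.3),
                                      drift = 0.1, genotype_sd = 0.05,
                                      n_replicates = 3, seed = 1) {
  stopifnot(replicate_cv >= 0, length(batch_offsets) == 2,
            n_replicates >= 2)
  if (is.data.frame(markers))
    markers <- setNames(markers$target, markers$peptide)
  peptides <- names(markers)
  with_seed(seed, {
    n_runs <- length(accessions) * n_replicates
    runs <- expand.grid(replicate = seq_len(n_replicates),
                        accession = accessions,
                        stringsAsFactors = FALSE)
    runs$injection_order <- sample(n_runs)
    runs$batch <- ifelse(runs$injection_order <= ceiling(n_runs / 2),
                         "B1", "B2")
    baseline <- setNames(runif(length(peptides), 5, 6.5), peptides)
    geno <- matrix(rnorm(length(peptides) * length(accessions),
                         0, genotype_sd),
                   length(peptides), length(accessions),
                   dimnames = list(peptides, accessions))
    supp <- matrix(0, length(peptides), length(accessions),
                   dimnames = list(peptides, accessions))
    if (!is.null(suppressed) && nrow(suppressed)) {
      comp <- strsplit(unname(markers), ",")
      for (r in seq_len(nrow(suppressed))) {
        hit <- vapply(comp, function(z)
          suppressed$subfamily[r] %in% z, logical(1))
        a <- suppressed$accession[r]
        if (a %in% accessions)
          supp[hit, a] <- pmin(supp[hit, a],
                               log10(suppressed$factor[r]))
      }
    }
    slope <- if (n_runs > 1) drift / (n_runs - 1) else 0
    design <- matrix(NA_real_, length(peptides), n_runs,
                     dimnames = list(peptides, NULL))
    for (r in seq_len(n_runs)) {
      a <- runs$accession[r]
      design[, r] <- baseline + geno[, a] + supp[, a] +
        batch_offsets[if (runs$batch[r] == "B1") 1 else 2] +
        slope * (runs$injection_order[r] - 1)
    }
    sd10 <- sqrt(log(1 + (replicate_cv / 100)^2)) / log(10)
    noise <- matrix(rnorm(length(design), 0, sd10), nrow(design))
    long <- data.frame(
      peptide = rep(peptides, times = n_runs),
      accession = rep(runs$accession, each = length(peptides)),
      replicate = rep(runs$replicate, each = length(peptides)),
      batch = rep(runs$batch, each = length(peptides)),
      injection_order = rep(runs$injection_order,
                            each = length(peptides)),
      area = 10^(as.vector(design) + as.vector(noise)),
      stringsAsFactors = FALSE)
    ab <- abundance_set(long)
    colnames(design) <- paste0(runs$accession, "_r", runs$replicate)
    list(abundance = ab,
         truth = list(markers = markers, suppressed = suppressed,
                      batch_offsets = batch_offsets, drift = drift,
                      replicate_cv = replicate_cv, baseline = baseline,
                      log10_design = design, runs = runs))
  })
}

#' Generate marker-peptide candidates with a designed selection outcome
#'
#' Draws tryptic peptides from each reference, computes their specificity
#' against the reference panel, and equips a designed number per
#' subfamily with attributes that pass all five selection gates
#' (yielding 22 alpha, 37 beta, 13 delta and 10 gamma survivors by
#' default); a set of additional candidates each violates exactly one
#' gate.
#'
#' @param refs Reference set.
#' @param counts Named integer vector of designed survivors per
#'   subfamily.
#' @param seed RNG seed.
#' @return List with `candidates` (input table for [select_markers()]),
#'   and `truth` (`selected` peptides, `family_counts`, `marker_map`).
#' @export
generate_marker_candidates <- function(refs, counts = NULL, seed = 1) {
  if (is.null(counts))
    counts <- c(alpha1 = 11L, alpha2 = 4L, alpha3 = 7L,
                beta1 = 5L, beta2 = 8L, beta3 = 5L, beta4 = 4L,
                beta5 = 5L, beta6 = 4L, beta7 = 6L,
                delta1 = 3L, delta2 = 4L, delta3 = 3L, delta4 = 3L,
                gamma1 = 6L, gamma2 = 4L)
  targets <- setNames(refs$subfamily, refs$id)
  with_seed(seed, {
    used <- character(0)
    good <- list(); extra <- list()
    for (sf in names(counts)) {
      pep <- digest(refs$sequence[refs$id == sf], sf)
      pep <- pep[!pep$sequence %in% used, , drop = FALSE]
      spec <- lapply(pep$sequence, peptide_specificity, refs, targets)
      ok <- vapply(spec, function(s)
        s$status %in% c("unique", "group"), logical(1))
      pep <- pep[ok, , drop = FALSE]; spec <- spec[ok]
      if (nrow(pep) < counts[[sf]] + 1)
        stop("not enough specific peptides for ", sf)
      take <- sample(nrow(pep), counts[[sf]])
      rest <- setdiff(seq_len(nrow(pep)), take)[1]
      good[[sf]] <- data.frame(
        peptide = pep$sequence[take],
        target = vapply(spec[take], `[[`, character(1), "target"),
        specificity = vapply(spec[take], `[[`, character(1), "status"),
        stringsAsFactors = FALSE)
      extra[[sf]] <- data.frame(
        peptide = pep$sequence[rest],
        target = vapply(spec[rest], `[[`, character(1), "target"),
        specificity = vapply(spec[rest], `[[`, character(1), "status"),
        stringsAsFactors = FALSE)
      used <- c(used, pep$sequence[take], pep$sequence[rest])
    }
    good <- do.call(rbind, c(good, make.row.names = FALSE))
    extra <- do.call(rbind, c(extra, make.row.names = FALSE))
    n <- nrow(good)
    good$fully_tryptic <- TRUE
    good$confidence <- round(runif(n, 0.96, 0.999), 3)
    good$mods_ok <- TRUE
    good$s2n <- round(runif(n, 10, 80), 1)
    good$cv_percent <- round(runif(n, 3, 12), 2)
    good$median_intensity <- round(10^runif(n, 4.5, 6.5))
    good$n_transitions <- sample(3:6, n, replace = TRUE)
    good$rt <- round(runif(n, 8, 40), 2)
    # one designed failure per gate, recycled over the spare peptides
    fails <- c("s2n", "confidence", "mods", "tryptic", "nonspecific",
               "cv")
    extra <- extra[seq_len(min(nrow(extra), length(fails))), ,
                   drop = FALSE]
    m <- nrow(extra)
    extra$fully_tryptic <- TRUE
    extra$confidence <- 0.98
    extra$mods_ok <- TRUE
    extra$s2n <- 50
    extra$cv_percent <- 8
    extra$median_intensity <- 1e5
    extra$n_transitions <- 4L
    extra$rt <- 25
    for (j in seq_len(m)) {
      switch(fails[j],
             s2n = { extra$s2n[j] <- 4 },
             confidence = { extra$confidence[j] <- 0.90 },
             mods = { extra$mods_ok[j] <- FALSE },
             tryptic = { extra$fully_tryptic[j] <- FALSE },
             nonspecific = { extra$specificity[j] <- "nonspecific" },
             cv = { extra$cv_percent[j] <- 35 })
    }
    candidates <- rbind(good, extra)
    candidates <- candidates[sample(nrow(candidates)), , drop = FALSE]
    rownames(candidates) <- NULL
    fam <- vapply(good$target, family_of_target, character(1))
    list(candidates = candidates,
         truth = list(selected = good$peptide,
                      family_counts = table(fam),
                      marker_map = setNames(good$target, good$peptide)))
  })
}

#' Build the full synthetic world for an end-to-end run
#'
#' Convenience wrapper generating references, candidate database,
#' identification tables, marker candidates and the abundance matrix
#' from one seed, returning every input the pipeline consumes together
#' with the combined ground truth.
#'
#' @param seed RNG seed; sub-generators receive derived seeds.
#' @return A list with `refs`, `candidate_db`, `idents`, `markers`,
#'   `abundance` and `truth`.
#' @export
synthetic_world <- function(seed = 1) {
  refs <- generate_reference_set(seed)
  cdb <- generate_candidate_db(refs, seed = seed + 1)
  idents <- generate_identification_tables(refs, seed = seed + 2)
  mc <- generate_marker_candidates(refs, seed = seed + 3)
  ab <- generate_abundance_matrix(
    data.frame(peptide = names(mc$truth$marker_map),
               target = unname(mc$truth$marker_map),
               stringsAsFactors = FALSE), seed = seed + 4)
  list(refs = refs, candidate_db = cdb, idents = idents,
       markers = mc, abundance = ab,
       truth = list(
         family_assignments = cdb$truth$family_assignments,
         planted_identity = cdb$truth$planted_identity,
         suppressed_subfamilies = ab$truth$suppressed,
         batch_offsets = ab$truth$batch_offsets,
         replicate_cv = ab$truth$replicate_cv,
         presence_matrix = idents$truth$presence))
}
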