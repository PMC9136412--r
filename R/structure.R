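count_cys <- function(sequence) {
  lengths(regmatches(sequence, gregexpr("C", sequence, fixed = TRUE)))
}

# Does the candidate's domain table contain `n` rows named `name`, each
# overlapping a distinct printed window by >= `min_frac` of that window?
windows_satisfied <- function(domains, name, windows, min_frac = 0.5) {
  rows <- domains[domains$name == name, , drop = FALSE]
  used <- rep(FALSE, nrow(rows))
  for (w in seq_len(nrow(windows))) {
    w1 <- windows$start[w]; w2 <- windows$end[w]
    need <- min_frac * (w2 - w1 + 1)
    found <- FALSE
    for (r in seq_len(nrow(rows))) {
      if (used[r]) next
      ov <- min(rows$end[r], w2) - max(rows$start[r], w1) + 1
      if (ov >= need) { used[r] <- TRUE; found <- TRUE; break }
    }
    if (!found) return(FALSE)
  }
  TRUE
}

#' Structural validation of a candidate conglutin
#'
#' Applies the family-specific structural rules used to confirm candidates
#' that pass the identity screen:
#' \describe{
#'   \item{alpha}{at least one `CXnC` cysteine pair and two `cupin_1`
#'     domains, each overlapping its expected window (36-201, 405-552) by
#'     at least half the window.}
#'   \item{beta}{zero cysteine residues and two `cupin_1` domains in the
#'     beta windows (180-330, 390-551).}
#'   \item{delta}{the nine-cysteine prolamin skeleton
#'     `CXnCXnCCXnCXCXnCXnCXnC` (windowed match); a `tryp_alpha_amyl`
#'     domain is additionally required only when the best reference is
#'     delta2.}
#'   \item{gamma}{`TAXi_N` and `TAXi_C` domains in their windows (62-237,
#'     269-430) and at least two cysteines before the `TAXi_N` start.}
#' }
#'
#' @param sequence Candidate amino-acid sequence.
#' @param family One of `"alpha"`, `"beta"`, `"delta"`, `"gamma"`.
#' @param domains Domain-annotation rows for this candidate: a data.frame
#'   with columns `name`, `start`, `end` (may have zero rows).
#' @param best_ref Subfamily of the best-identity reference (used for the
#'   delta2 rule); may be `NULL`.
#' @param min_frac Minimum overlap with a printed window, as a fraction of
#'   the window length.
#' @return A list with `pass` (logical) and `trace` (data.frame of rule
#'   names and pass/fail flags).
#' @export
check_structure <- function(sequence, family, domains = NULL,
                            best_ref = NULL, min_frac = 0.5) {
  if (is.null(domains))
    domains <- data.frame(name = character(0), start = integer(0),
                          end = integer(0))
  rules <- character(0); passed <- logical(0)
  add <- function(rule, ok) {
    rules <<- c(rules, rule); passed <<- c(passed, ok)
  }
  if (family == "alpha") {
    add("alpha CXnC pair",
        match_cys_pattern(sequence, "CXnC", windowed = TRUE)$match)
    add("alpha two cupin_1 windows",
        windows_satisfied(domains, "cupin_1",
                          FAMILY_DOMAIN_WINDOWS$alpha, min_frac))
  } else if (family == "beta") {
    add("beta zero-cysteine rule", count_cys(sequence) == 0L)
    add("beta two cupin_1 windows",
        windows_satisfied(domains, "cupin_1",
                          FAMILY_DOMAIN_WINDOWS$beta, min_frac))
  } else if (family == "delta") {
    add("delta cysteine skeleton",
        match_cys_pattern(sequence, DELTA_CYS_PATTERN, windowed = TRUE)$match)
    if (!is.null(best_ref) && identical(best_ref, "delta2"))
      add("delta2 tryp_alpha_amyl domain",
          any(domains$name == "tryp_alpha_amyl"))
  } else if (family == "gamma") {
    gw <- FAMILY_DOMAIN_WINDOWS$gamma
    ok_n <- windows_satisfied(domains, "TAXi_N", gw[gw$name == "TAXi_N", ],
                              min_frac)
    ok_c <- windows_satisfied(domains, "TAXi_C", gw[gw$name == "TAXi_C", ],
                              min_frac)
    add("gamma TAXi_N window", ok_n)
    add("gamma TAXi_C window", ok_c)
    taxi_start <- domains$start[domains$name == "TAXi_N"]
    taxi_start <- if (length(taxi_start)) min(taxi_start)
                  else gw$start[gw$name == "TAXi_N"]
    n_before <- sum(match_positions(sequence, "C") < taxi_start)
    add("gamma >=2 Cys before TAXi_N", n_before >= 2L)
  } else stop("unknown conglutin family: ", family)
  list(pass = all(passed),
       trace = data.frame(rule = rules, passed = passed,
                          stringsAsFactors = FALSE))
}

match_positions <- function(sequence, ch) {
  which(strsplit(sequence, "")[[1]] == ch)
}

#' Classify candidate conglutins in a protein database
#'
#' Composition of the identity screen ([screen_candidates()]) and the
#' structural filter ([check_structure()]). Candidates below the identity
#' threshold are excluded; screened candidates failing the structural
#' rules are returned with status `"rejected"`, the remainder with status
#' `"classified"` and the subfamily of their best-identity reference.
#'
#' @param db Candidate protein record table.
#' @param refs Reference set (see [generate_reference_set()]).
#' @param threshold Identity threshold in percent.
#' @param domains Domain-annotation table for candidates: columns `id`,
#'   `name`, `start`, `end`.
#' @return A data.frame with columns `id`, `status`, `family`,
#'   `subfamily`, `identity` and a list-column `rule_trace`.
#' @export
classify <- function(db, refs, threshold = 75, domains = NULL) {
  hits <- screen_candidates(db, refs, threshold)
  if (nrow(hits) == 0)
    return(data.frame(id = character(0), status = character(0),
                      family = character(0), subfamily = character(0),
                      identity = numeric(0)))
  fam_of <- setNames(CONGLUTIN_SUBFAMILIES$family,
                     CONGLUTIN_SUBFAMILIES$subfamily)
  status <- character(nrow(hits)); trace <- vector("list", nrow(hits))
  for (i in seq_len(nrow(hits))) {
    cand_dom <- if (is.null(domains)) NULL
                else domains[domains$id == hits$id[i], , drop = FALSE]
    chk <- check_structure(db$sequence[match(hits$id[i], db$id)],
                           fam_of[[hits$best_ref[i]]], cand_dom,
                           best_ref = hits$best_ref[i])
    status[i] <- if (chk$pass) "classified" else "rejected"
    trace[[i]] <- chk$trace
  }
  out <- data.frame(id = hits$id, status = status,
                    family = unname(fam_of[hits$best_ref]),
                    subfamily = hits$best_ref, identity = hits$identity,
                    stringsAsFactors = FALSE)
  out$rule_trace <- trace
  out
}
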