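test_that("digest handles cleavage sites, proline rule and bounds", {
  d <- digest("AAKGGRCCCCCCCC", max_missed = 0, min_len = 3)
  expect_setequal(d$sequence, c("AAK", "GGR", "CCCCCCCC"))
  expect_true(all(d$missed_cleavages == 0))
  # no cleavage after K when followed by P
  d2 <- digest("AAKPGGRAAAAAAAA", max_missed = 0, min_len = 3,
               max_len = 30)
  expect_setequal(d2$sequence, c("AAKPGGR", "AAAAAAAA"))
  # coordinates match the parent
  expect_equal(substring("AAKPGGRAAAAAAAA", d2$start, d2$end),
               d2$sequence)
  expect_equal(nrow(digest("")), 0)
})

test_that("digest equals the substring-enumeration oracle", {
  set.seed(6)
  for (i in 1:40) {
    p <- random_protein(200)
    got <- digest(p, max_missed = 1, min_len = 8, max_len = 30)
    want <- digest_oracle(p, max_missed = 1, min_len = 8, max_len = 30)
    key <- function(d) sort(paste(d$sequence, d$start, d$missed_cleavages))
    expect_equal(key(got), key(want))
  }
})

test_that("every 0-missed-cleavage digest product is fully tryptic", {
  set.seed(7)
  for (i in 1:20) {
    p <- random_protein(150)
    d <- digest(p, max_missed = 0, min_len = 2, max_len = 150)
    for (s in d$sequence) expect_true(is_fully_tryptic(s, p))
  }
})

test_that("peptide specificity distinguishes unique, group, nonspecific", {
  refs <- generate_reference_set(1)
  targets <- setNames(refs$subfamily, refs$id)
  # a peptide found only in beta4 (overlapping a beta4/beta6 difference)
  b4 <- refs$sequence[refs$subfamily == "beta4"]
  d4 <- digest(b4, max_missed = 0)
  spec4 <- lapply(d4$sequence, peptide_specificity, refs, targets)
  status4 <- vapply(spec4, `[[`, character(1), "status")
  expect_true(any(status4 == "unique"))
  expect_true(any(status4 == "group"))
  grp <- spec4[[which(status4 == "group")[1]]]
  expect_equal(grp$target, "beta4,beta6")
  # contamination: same peptide also planted in a decoy protein
  pep <- d4$sequence[which(status4 == "unique")[1]]
  bg <- rbind(refs[, c("id", "description", "sequence")],
              protein_records("decoy1", paste0("MK", pep, "GGG")))
  expect_equal(peptide_specificity(pep, bg, targets)$status,
               "nonspecific")
  expect_equal(peptide_specificity("WWWWWWWK", refs, targets)$status,
               "absent")
})

test_that("specificity is monotone under background enlargement", {
  refs <- generate_reference_set(1)
  targets <- setNames(refs$subfamily, refs$id)
  pep <- digest(refs$sequence[1], max_missed = 0)$sequence[1]
  small <- peptide_specificity(pep, refs, targets)
  big_bg <- rbind(refs[, c("id", "description", "sequence")],
                  protein_records("extra", paste0("MR", pep, "K")))
  big <- peptide_specificity(pep, big_bg, targets)
  rank <- c(absent = 0, unique = 1, group = 2, nonspecific = 3)
  expect_gte(rank[[big$status]], rank[[small$status]])
})

test_that("marker selection applies the five gates in order", {
  cand <- data.frame(
    peptide = paste0("P", 1:7),
    target = "alpha1",
    specificity = c("unique", "nonspecific", rep("unique", 5)),
    fully_tryptic = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    confidence = c(0.99, 0.99, 0.99, 0.90, 0.99, 0.99, 0.99),
    mods_ok = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    s2n = c(50, 50, 50, 50, 50, 4, 50),
    cv_percent = c(8, 8, 8, 8, 8, 8, 8),
    median_intensity = 1e5,
    stringsAsFactors = FALSE)
  sel <- select_markers(cand)
  expect_setequal(sel$peptide, c("P1", "P7"))
  rej <- attr(sel, "rejections")
  expect_equal(rej$gate[rej$peptide == "P2"], "specificity")
  expect_equal(rej$gate[rej$peptide == "P3"], "fully tryptic")
  expect_equal(rej$gate[rej$peptide == "P4"], "confidence")
  expect_equal(rej$gate[rej$peptide == "P5"], "modifications")
  expect_equal(rej$gate[rej$peptide == "P6"], "signal to noise")
  # s2n exactly at the bound is rejected (strict > 5)
  cand$s2n[6] <- 5
  expect_false("P6" %in% select_markers(cand)$peptide)
})

test_that("survivors are ranked by CV then intensity within target", {
  cand <- data.frame(
    peptide = c("A", "B"), target = "alpha1", specificity = "unique",
    fully_tryptic = TRUE, confidence = 0.99, mods_ok = TRUE, s2n = 50,
    cv_percent = c(9, 5), median_intensity = c(1e5, 1e5),
    stringsAsFactors = FALSE)
  sel <- select_markers(cand, top_k = 1)
  expect_equal(sel$peptide, "B")
  # equal CV: higher intensity wins
  cand$cv_percent <- c(5, 5); cand$median_intensity <- c(2e5, 1e5)
  expect_equal(select_markers(cand, top_k = 1)$peptide, "A")
})

test_that("designed synthetic panel yields 22/37/13/10 markers per family", {
  refs <- generate_reference_set(1)
  mc <- generate_marker_candidates(refs, seed = 3)
  sel <- select_markers(mc$candidates)
  expect_setequal(sel$peptide, mc$truth$selected)
  fam <- vapply(sel$target, function(t)
    sub("[0-9].*$", "", strsplit(t, ",")[[1]][1]), character(1))
  expect_equal(as.integer(table(fam)[c("alpha", "beta", "delta",
                                       "gamma")]),
               c(22L, 37L, 13L, 10L))
  # every selected marker re-passes all five gates
  idx <- match(sel$peptide, mc$candidates$peptide)
  expect_true(all(mc$candidates$specificity[idx] %in%
                    c("unique", "group")))
  expect_true(all(mc$candidates$fully_tryptic[idx]))
  expect_true(all(mc$candidates$confidence[idx] >= 0.95))
  expect_true(all(mc$candidates$mods_ok[idx]))
  expect_true(all(mc$candidates$s2n[idx] > 5))
})

test_that("transition table schedules windows and enforces minimum", {
  markers <- data.frame(peptide = c("AAAK", "CCCK", "GGGK"),
                        target = "alpha1",
                        n_transitions = c(6L, 2L, 3L),
                        rt = c(20, 15, 30),
                        stringsAsFactors = FALSE)
  expect_warning(tt <- build_transition_table(markers), "CCCK")
  expect_equal(sum(tt$peptide == "AAAK"), 6)
  expect_equal(sum(tt$peptide == "GGGK"), 3)
  expect_false("CCCK" %in% tt$peptide)
  w <- tt[tt$peptide == "AAAK", ][1, ]
  expect_equal(c(w$window_start, w$window_end), c(19.5, 20.5))
})
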