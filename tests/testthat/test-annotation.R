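test_that("pairwise identity boundary cases", {
  expect_equal(pairwise_identity("MKVLAW", "MKVLAW"), 100)
  expect_equal(pairwise_identity("AAAA", "TTTT"), 0)
  # symmetry on a handful of random pairs
  set.seed(1)
  for (i in 1:5) {
    a <- random_protein(40); b <- random_protein(35)
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("identity is 100 iff sequences are identical (on mutated copies)", {
  set.seed(2)
  a <- random_protein(60)
  expect_equal(pairwise_identity(a, a), 100)
  b <- a
  substr(b, 30, 30) <- if (substr(a, 30, 30) == "A") "V" else "A"
  expect_lt(pairwise_identity(a, b), 100)
})

test_that("alignment score matches Biostrings overlap alignment", {
  m <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
  diag(m) <- 1
  set.seed(3)
  for (i in 1:10) {
    a <- random_protein(50); b <- random_protein(45)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = m, gapOpening = 10, gapExtension = 0.5,
      type = "overlap")
    expect_equal(pairwise_identity(a, b, details = TRUE)$score,
                 Biostrings::score(pa))
  }
})

test_that("screen_candidates keeps planted variants and drops decoys", {
  refs <- generate_reference_set(1)
  cdb <- generate_candidate_db(refs, n_variants = 3, n_decoys = 2,
                               n_duplicates = 0, identity = 90, seed = 3)
  hits <- screen_candidates(cdb$db, refs, 75)
  expect_setequal(hits$id, cdb$truth$family_assignments$id)
  expect_equal(hits$best_ref,
               cdb$truth$family_assignments$subfamily[
                 match(hits$id, cdb$truth$family_assignments$id)])
  # threshold = 100 retains only exact copies
  exact <- rbind(cdb$db,
                 protein_records("copy", refs$sequence[1]))
  hits100 <- screen_candidates(exact, refs, 100)
  expect_equal(hits100$id, "copy")
})

test_that("cysteine pattern matching: examples and grammar", {
  d <- match_cys_pattern("CACACCACACACACAC", DELTA_CYS_PATTERN)
  expect_true(d$match)
  expect_equal(d$positions, c(1L, 3L, 5L, 6L, 8L, 10L, 12L, 14L, 16L))
  expect_false(match_cys_pattern(strrep("A", 30), "CXnC")$match)
  # exact mode requires the full skeleton
  expect_true(match_cys_pattern("ACAAC", "CXnC", windowed = FALSE)$match)
  expect_false(match_cys_pattern("ACAACAC", "CXnC",
                                 windowed = FALSE)$match)
  expect_error(cys_pattern("CZC"), "unrecognised")
  expect_error(cys_pattern("C"), "at least two")
})

test_that("cysteine matcher agrees with the regex oracle", {
  set.seed(4)
  pats <- c("CXnC", "CXC", "CCXnC", DELTA_CYS_PATTERN)
  alpha <- c(AA20, rep("C", 6))  # cysteine-enriched alphabet
  for (i in 1:250) {
    s <- random_protein(sample(20:60, 1), alpha)
    for (p in pats) {
      expect_equal(match_cys_pattern(s, p, windowed = TRUE)$match,
                   cys_oracle(s, p, windowed = TRUE), info = s)
      expect_equal(match_cys_pattern(s, p, windowed = FALSE)$match,
                   cys_oracle(s, p, windowed = FALSE), info = s)
    }
  }
})

test_that("structural rules: beta zero-cysteine and domain windows", {
  refs <- generate_reference_set(1)
  doms <- ref_domains(refs)
  b <- refs[refs$subfamily == "beta2", ]
  bd <- doms[doms$id == "beta2", ]
  ok <- check_structure(b$sequence, "beta", bd)
  expect_true(ok$pass)
  # introduce one cysteine -> fail with the zero-cysteine rule in trace
  s <- b$sequence
  substr(s, 50, 50) <- "C"
  bad <- check_structure(s, "beta", bd)
  expect_false(bad$pass)
  expect_false(bad$trace$passed[bad$trace$rule == "beta zero-cysteine rule"])
  # gamma with only TAXi_C fails
  g <- refs[refs$subfamily == "gamma1", ]
  gd <- doms[doms$id == "gamma1" & doms$name == "TAXi_C", ]
  expect_false(check_structure(g$sequence, "gamma", gd)$pass)
  expect_true(check_structure(g$sequence, "gamma",
                              doms[doms$id == "gamma1", ])$pass)
  expect_error(check_structure("MKV", "epsilon"), "unknown")
})

test_that("classify recovers synthetic truth and rejects structure breaks", {
  refs <- generate_reference_set(1)
  cdb <- generate_candidate_db(refs, n_variants = 5, n_decoys = 3,
                               n_duplicates = 0, seed = 5)
  cl <- classify(cdb$db, refs, 75, cdb$domains)
  expect_setequal(cl$id, cdb$truth$family_assignments$id)
  expect_true(all(cl$status == "classified"))
  expect_equal(cl$subfamily,
               cdb$truth$family_assignments$subfamily[
                 match(cl$id, cdb$truth$family_assignments$id)])
  # every classified beta has cysteine count 0
  betas <- cl$id[cl$family == "beta" & cl$status == "classified"]
  for (id in betas)
    expect_equal(lengths(regmatches(cdb$db$sequence[cdb$db$id == id],
                                    gregexpr("C", cdb$db$sequence[cdb$db$id == id]))),
                 0L)
  # empty database -> empty result
  expect_equal(nrow(classify(protein_records(character(0), character(0)),
                             refs)), 0)
})

test_that("neighbor joining recovers planted additive topology", {
  # four taxa with additive distances: ((a,b),(c,d))
  base <- strrep("A", 100)
  mut <- function(s, at) {
    for (p in at) substr(s, p, p) <- "V"
    s
  }
  recs <- protein_records(
    c("a", "b", "c", "d"),
    c(mut(base, 1:2), mut(base, 3:4),
      mut(base, c(1:2, 21:30, 41:42)), mut(base, c(1:2, 21:30, 45:48))))
  tr <- nj_tree(recs, as_phylo = TRUE)
  expect_setequal(tr$tip.label, c("a", "b", "c", "d"))
  # the split {a,b} | {c,d} must be present
  parts <- ape::prop.part(tr)
  labs <- attr(parts, "labels")
  splits <- lapply(parts, function(p) sort(labs[p]))
  has_split <- function(x) any(vapply(splits, identical, logical(1), x))
  expect_true(has_split(c("a", "b")) || has_split(c("c", "d")))
  # three identical sequences: star tree with zero branch lengths
  star <- nj_tree(protein_records(c("x", "y", "z"), rep(base, 3)),
                  as_phylo = TRUE)
  expect_equal(sum(star$edge.length), 0)
  expect_error(nj_tree(protein_records("x", base)), "at least 3")
})

test_that("epitope scanning reports every exact occurrence", {
  recs <- protein_records(c("p1", "p2"),
                          c("AAAQQDEQAAA", "GGGGG"))
  hits <- scan_epitopes(recs, c("QQDEQ", "ZZZ"))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 4L)
  # overlapping occurrences are all reported
  ov <- scan_epitopes(protein_records("p", "AAA"), "AA")
  expect_equal(ov$start, c(1L, 2L))
})

test_that("gap-token motifs are annotated, not gated", {
  recs <- protein_records("b", "MMHYAAARMMQQDEQEAAYAALSMM")
  expect_equal(scan_motif(recs, "HYXnR")$start, 3L)
  expect_equal(scan_motif(recs, "QQDEQEXnYXnLS")$start, 11L)
  expect_equal(nrow(scan_motif(recs, "WWW")), 0)
})
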