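toy_markers <- function(n = 6) {
  data.frame(peptide = sprintf("PEP%02d", seq_len(n)),
             target = rep(c("alpha1", "beta2"), length.out = n),
             stringsAsFactors = FALSE)
}

test_that("zero-noise batch offset is removed exactly", {
  ab <- generate_abundance_matrix(toy_markers(), suppressed = NULL,
                                  replicate_cv = 0,
                                  batch_offsets = c(0, 0.3), drift = 0,
                                  genotype_sd = 0, seed = 8)
  corr <- remove_batch_effect(ab$abundance)
  y <- log_areas(corr)
  b <- corr$runs$batch
  for (i in seq_len(nrow(y)))
    expect_equal(mean(y[i, b == "B1"]) - mean(y[i, b == "B2"]), 0,
                 tolerance = 1e-10)
  # a constant peptide is returned unchanged
  expect_equal(max(abs(attr(corr, "batch_effects"))), 0.15,
               tolerance = 1e-10)
})

test_that("batch correction equals the limma oracle", {
  skip_if_not_installed("limma")
  ab <- generate_abundance_matrix(toy_markers(), suppressed = NULL,
                                  replicate_cv = 10, seed = 9)
  x <- ab$abundance
  corr <- remove_batch_effect(x)
  # limma removes the covariate term as well; subtract ours to compare
  ours <- log_areas(corr) -
    attr(corr, "injection_effects") %o% x$runs$injection_order
  theirs <- limma::removeBatchEffect(
    log_areas(x), batch = factor(x$runs$batch),
    covariates = x$runs$injection_order)
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-10)
})

test_that("batch correction leaves within-batch contrasts unchanged", {
  ab <- generate_abundance_matrix(toy_markers(), replicate_cv = 10,
                                  seed = 10)
  x <- ab$abundance
  y0 <- log_areas(x)
  y1 <- log_areas(remove_batch_effect(x))
  b1 <- x$runs$batch == "B1"
  contrast <- y0[, b1][, 1] - y0[, b1][, 2]
  expect_equal(y1[, b1][, 1] - y1[, b1][, 2], contrast,
               tolerance = 1e-10)
})

test_that("constant peptide across runs is unchanged by correction", {
  long <- expand.grid(replicate = 1:2, accession = c("A1", "A2", "A3"),
                      stringsAsFactors = FALSE)
  long$injection_order <- sample(nrow(long))
  long$batch <- rep(c("B1", "B2"), each = 3)
  long$peptide <- "PEP"
  long$area <- 1000
  x <- abundance_set(long)
  expect_equal(unname(remove_batch_effect(x)$areas["PEP", ]),
               rep(1000, 6), tolerance = 1e-10)
})

test_that("replicate CV arithmetic and error cases", {
  long <- data.frame(peptide = "P", accession = rep("A", 3),
                     replicate = 1:3, batch = "B1", injection_order = 1:3,
                     area = c(8, 10, 12))
  cv <- replicate_cv(abundance_set(long))
  expect_equal(cv["P", "A"], 20)
  long$area <- 10
  expect_equal(replicate_cv(abundance_set(long))["P", "A"], 0)
})

test_that("percent of average normalisation", {
  expect_equal(percent_of_average(c(5, 5, 5)), c(100, 100, 100))
  expect_equal(percent_of_average(c(1, 3)), c(50, 150))
  set.seed(11)
  v <- runif(46, 1, 10)
  expect_equal(mean(percent_of_average(v)), 100)
  expect_error(percent_of_average(c(0, 0)), "undefined")
})

test_that("family aggregation: linearity and one-peptide families", {
  mm <- c(P1 = "alpha1", P2 = "beta2", P3 = "beta3")
  long <- expand.grid(replicate = 1:2, accession = c("A1", "A2"),
                      peptide = names(mm), stringsAsFactors = FALSE)
  long$batch <- "B1"
  run_key <- paste(long$accession, long$replicate)
  long$injection_order <- match(run_key, unique(run_key))
  long$area <- 100
  long$area[long$peptide != "P1" & long$accession == "A2"] <- 200
  x <- abundance_set(long)
  prof <- family_abundance(x, mm)
  # one-peptide family equals that peptide's percent-of-average
  expect_equal(unname(prof$family["alpha", ]), c(100, 100))
  expect_equal(unname(prof$family["beta", ]),
               unname(percent_of_average(c(200, 400))))
  # doubling every beta peptide in one accession doubles its beta total
  long2 <- long
  dbl <- long2$peptide != "P1" & long2$accession == "A2"
  long2$area[dbl] <- long2$area[dbl] * 2
  prof2 <- family_abundance(abundance_set(long2), mm)
  expect_equal(prof2$family_total["beta", "A2"],
               2 * prof$family_total["beta", "A2"])
  # unmapped marker errors with the offender named
  expect_error(family_abundance(x, mm[1:2]), "P3")
})

test_that("PCA: variance sums to 100, rank-1 designs, eigen oracle", {
  set.seed(12)
  m <- matrix(rnorm(80), 10, 8)
  p <- pca_profiles(m)
  expect_equal(sum(p$var_percent), 100)
  # duplicated samples in two groups: PC1 captures all the variance
  g <- rbind(matrix(rep(c(1, 2, 3, 4), 5), 5, 4, byrow = TRUE),
             matrix(rep(c(3, 4, 1, 2), 5), 5, 4, byrow = TRUE))
  pr <- pca_profiles(g, scaling = "center")
  expect_equal(pr$var_percent[1], 100)
  # scores match a covariance eigendecomposition up to sign
  pc <- pca_profiles(m, scaling = "center")
  ev <- eigen(cov(scale(m, scale = FALSE)))
  sc <- scale(m, scale = FALSE) %*% ev$vectors
  for (k in 1:3) {
    d <- min(max(abs(pc$scores[, k] - sc[, k])),
             max(abs(pc$scores[, k] + sc[, k])))
    expect_lt(d, 1e-8)
  }
  # sign convention: largest-magnitude loading element is positive
  for (k in seq_len(ncol(pc$loadings)))
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, k])), k], 0)
  expect_error(pca_profiles(m[1, , drop = FALSE]), "at least 2")
})

test_that("HCA: one-minus-Pearson distances and planted clusters", {
  a <- c(1, 2, 3, 4, 5)
  m <- rbind(s1 = a, s2 = a * 2 + 1, s3 = rev(a))
  d <- as.matrix(1 - cor(t(m)))
  expect_equal(d["s1", "s2"], 0)
  expect_equal(d["s1", "s3"], 2)
  set.seed(13)
  base1 <- rnorm(20); base2 <- rnorm(20)
  m2 <- rbind(
    t(replicate(5, base1 + rnorm(20, 0, 0.05))),
    t(replicate(5, base2 + rnorm(20, 0, 0.05))))
  rownames(m2) <- paste0("s", 1:10)
  h <- hca_profiles(m2)
  k2 <- stats::cutree(h$hclust, k = 2)
  expect_equal(length(unique(k2[1:5])), 1)
  expect_equal(length(unique(k2[6:10])), 1)
  expect_true(k2[1] != k2[10])
  expect_match(h$newick, "^\\(")
  m2[1, ] <- 7
  expect_error(hca_profiles(m2), "s1")
})

test_that("Dunnett with one comparison reduces to the two-sample t-test", {
  set.seed(14)
  v <- rnorm(12)
  g <- rep(c("ctl", "trt"), each = 6)
  d <- anova_dunnett(v, g, "ctl", nsim = 2e5, seed = 99)
  tt <- stats::t.test(v[g == "trt"], v[g == "ctl"],
                      var.equal = TRUE)$p.value
  expect_lt(abs(d$p_adj - tt), 0.002)  # Monte-Carlo tolerance
  expect_error(anova_dunnett(v, g, "nope"), "not present")
})

test_that("Dunnett reference validates the design", {
  set.seed(15)
  v <- rnorm(15); g <- rep(c("c", "t1", "t2", "t3", "t4"), each = 3)
  ref <- dunnett_reference(3, rep(3, 4), 10, nsim = 5e4, seed = 1)
  d <- anova_dunnett(v, g, "c", ref = ref)
  expect_equal(nrow(d), 4)
  badref <- dunnett_reference(4, rep(3, 4), 10, nsim = 5e4, seed = 1)
  expect_error(anova_dunnett(v, g, "c", ref = badref), "does not match")
})
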