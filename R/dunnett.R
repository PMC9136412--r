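with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Monte-Carlo reference distribution for Dunnett's test
#'
#' Simulates the null distribution of the maximum absolute Dunnett
#' statistic `max_j |T_j|`, where
#' `T_j = (Ybar_j - Ybar_0) / (s * sqrt(1/n_j + 1/n_0))` and `s^2` is the
#' pooled variance on `df` degrees of freedom. The sample is sorted so
#' adjusted p-values are O(log nsim) lookups; it can be reused across
#' calls to [anova_dunnett()] with the same design.
#'
#' @param n0 Control group size.
#' @param n_treat Integer vector of treatment group sizes (in comparison
#'   order).
#' @param df Error degrees of freedom of the pooled variance.
#' @param nsim Number of Monte-Carlo draws (>= 1e5 recommended).
#' @param seed RNG seed for the draws.
#' @return An object of class `dunnett_ref`.
#' @export
dunnett_reference <- function(n0, n_treat, df, nsim = 1e5, seed = 1) {
  stopifnot(n0 >= 2, all(n_treat >= 2), df >= 1, nsim >= 1000)
  k <- length(n_treat)
  maxT <- with_seed(seed, {
    z0 <- rnorm(nsim) / sqrt(n0)
    s <- sqrt(rchisq(nsim, df) / df)
    m <- matrix(rnorm(nsim * k), nsim, k)
    m <- sweep(m, 2, sqrt(n_treat), "/")
    tt <- abs(m - z0) / (s %o% sqrt(1 / n_treat + 1 / n0))
    apply(tt, 1, max)
  })
  structure(list(maxT = sort(maxT), n0 = n0, n_treat = n_treat, df = df,
                 nsim = nsim, seed = seed), class = "dunnett_ref")
}

#' One-way ANOVA with Dunnett many-to-one comparisons
#'
#' Computes the one-way ANOVA F test and Dunnett-adjusted two-sided
#' p-values for each treatment group against the designated control. The
#' adjustment evaluates `P(max_j |T_j| >= |t_obs|)` under the joint null
#' by Monte-Carlo integration of the multivariate t distribution (at
#' least 1e5 draws by default; the Monte-Carlo standard error of a
#' p-value near 0.05 is then about 0.0007).
#'
#' @param values Numeric response vector.
#' @param groups Group labels (coerced to factor).
#' @param control The control group label.
#' @param alpha Significance threshold for the `significant` flag.
#' @param nsim Monte-Carlo draws when `ref` is not supplied.
#' @param seed Seed for the Monte-Carlo draws.
#' @param ref Optional precomputed [dunnett_reference()] for this design.
#' @return A data.frame with one row per comparison (`group`, `estimate`,
#'   `t`, `p_adj`, `significant`); the ANOVA F statistic, its p-value and
#'   degrees of freedom are attached as attributes `F`, `p_F`, `df`.
#' @export
anova_dunnett <- function(values, groups, control, alpha = 0.05,
                          nsim = 1e5, seed = 1, ref = NULL) {
  groups <- factor(groups)
  if (!control %in% levels(groups))
    stop("control group '", control, "' not present")
  n <- table(groups)
  if (nlevels(groups) < 2 || any(n < 2))
    stop("need >= 2 groups with n >= 2 each")
  treat <- setdiff(levels(groups), control)
  means <- tapply(values, groups, mean)
  N <- length(values); k <- nlevels(groups)
  df <- N - k
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  ssb <- sum(n * (means - mean(values))^2)
  Fstat <- (ssb / (k - 1)) / (ssw / df)
  s2 <- ssw / df
  n0 <- n[[control]]
  nj <- as.numeric(n[treat])
  est <- means[treat] - means[[control]]
  tstat <- est / sqrt(s2 * (1 / nj + 1 / n0))
  if (is.null(ref)) {
    ref <- dunnett_reference(n0, nj, df, nsim = nsim, seed = seed)
  } else {
    stopifnot(inherits(ref, "dunnett_ref"))
    if (ref$n0 != n0 || !identical(as.numeric(ref$n_treat), nj) ||
        ref$df != df)
      stop("supplied dunnett_reference does not match this design")
  }
  p_adj <- (ref$nsim - findInterval(abs(tstat), ref$maxT)) / ref$nsim
  out <- data.frame(group = treat, estimate = as.numeric(est),
                    t = as.numeric(tstat), p_adj = p_adj,
                    significant = p_adj < alpha,
                    stringsAsFactors = FALSE)
  attr(out, "F") <- Fstat
  attr(out, "p_F") <- pf(Fstat, k - 1, df, lower.tail = FALSE)
  attr(out, "df") <- c(k - 1, df)
  rownames(out) <- NULL
  out
}
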