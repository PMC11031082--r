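test_that("with L = 1 the fit equals the exhaustive single-effect Bayes computation", {
  set.seed(31)
  X <- matrix(rnorm(300 * 20), 300, 20)
  y <- drop(scale(X[, 3] * 0.4 + rnorm(300)))
  V_abs <- 0.2 * var(y - mean(y))
  s2 <- var(y - mean(y))
  fit <- susie_fit(X, y, L = 1L, prior_variance = 0.2,
                   estimate_prior_variance = FALSE,
                   residual_variance = s2,
                   estimate_residual_variance = FALSE,
                   standardize = FALSE)
  oracle <- oracle_single_effect(X, y, V_abs, s2)
  expect_equal(unname(fit$alpha[1L, ]), oracle$alpha, tolerance = 1e-10)
  expect_equal(unname(fit$pip), oracle$alpha, tolerance = 1e-10)
  expect_equal(unname(fit$mu[1L, ]), oracle$mu, tolerance = 1e-10)
})

test_that("an overwhelming signal in an orthogonal design gets PIP > 0.99", {
  set.seed(32)
  n <- 2000L
  X <- matrix(rnorm(n * 30), n, 30)
  X <- qr.Q(qr(X)) * sqrt(n)            # orthogonal columns, var ~ 1
  colnames(X) <- paste0("L", 1:30)
  b <- sqrt(400 / n)                    # per-column NCP ~ 400
  y <- drop(X[, 8] * b + rnorm(n))
  fit <- susie_fit(X, y, L = 10L)
  expect_gt(fit$pip[["L8"]], 0.99)
  expect_true(any(vapply(fit$credible_sets, function(cs)
    identical(cs$loci, "L8"), logical(1))))
})

test_that("alpha rows sum to one and credible sets attain their coverage", {
  set.seed(33)
  X <- matrix(rnorm(500 * 40), 500, 40)
  y <- drop(X[, 5] * 0.3 - X[, 22] * 0.25 + rnorm(500))
  fit <- susie_fit(X, y, L = 5L)
  expect_equal(unname(rowSums(fit$alpha)), rep(1, 5L), tolerance = 1e-9)
  for (cs in fit$credible_sets) {
    expect_gte(cs$coverage, 0.95)
    expect_gte(cs$purity, 0.5)
  }
  expect_equal(unname(fit$posterior_effect),
               unname(colSums(fit$alpha * fit$mu)))
})

test_that("pure-noise traits rarely produce a credible set", {
  set.seed(34)
  none <- vapply(1:20, function(i) {
    X <- matrix(rnorm(300 * 25), 300, 25)
    y <- rnorm(300)
    length(susie_fit(X, y, L = 5L)$credible_sets) == 0L
  }, logical(1))
  expect_gte(mean(none), 0.95)
})

test_that("the causal-locus count is stable across L = 2..10", {
  set.seed(35)
  gen <- generate_synthetic_hfs(1500, 200, n_blocks = 2L, seed = 36L)
  keep <- apply(gen$hfs, 2, sd) > 0
  strong <- order(apply(gen$hfs, 2, var), decreasing = TRUE)[1:2]
  y <- drop(scale(8 * gen$hfs[, strong[1]] - 8 * gen$hfs[, strong[2]] +
                    rnorm(1500)))
  counts <- vapply(c(2L, 5L, 10L), function(L) {
    fm <- finemap_blocks(gen$hfs, y, gen$block_of, L = L)
    length(call_causal(setNames(fm$pip, fm$locus_id)))
  }, integer(1))
  expect_equal(counts[1], counts[2])
  expect_equal(counts[2], counts[3])
  expect_gte(counts[1], 1L)
})

test_that("causal calls use a strict PIP threshold and pleiotropy needs two traits", {
  pip <- c(a = 0.96, b = 0.95, c = 0.2)
  expect_equal(call_causal(pip), "a")
  # loci without a PIP (constant columns) are never called
  expect_equal(call_causal(c(a = 0.96, b = NA, c = NA)), "a")
  expect_equal(pleiotropic_loci(list(t1 = c("a", "b"), t2 = c("b", "c"),
                                     t3 = "d")), "b")
})

test_that("control matching prefers near, p-matched loci and is greedy without replacement", {
  assoc <- data.frame(
    locus_id = c("c1", "c2", "n1", "n2", "n3"),
    chrom = "chr1",
    start = c(0, 1e4, 1e4, 1e5, 2e6) + 0,
    end = c(0, 1e4, 1e4, 1e5, 2e6) + 4096,
    p = c(1e-10, 2e-10, 1.5e-10, 1.1e-10, 1e-3))
  m <- match_controls(c("c1", "c2"), assoc)
  # c1 (smaller p) picks first: nearest p-matched is n1 at 10 kb, not n2
  expect_equal(m$control_id[m$causal_id == "c1"], "n1")
  expect_equal(m$control_id[m$causal_id == "c2"], "n2")
  expect_false(any(m$fallback))

  # only candidate has p 10x different on log10 scale: fallback flagged
  assoc2 <- data.frame(locus_id = c("c1", "n1"), chrom = "chr1",
                       start = c(0, 1e4), end = c(4096, 1e4 + 4096),
                       p = c(1e-10, 1e-3))
  m2 <- match_controls("c1", assoc2)
  expect_equal(m2$control_id, "n1")
  expect_true(m2$fallback)
})

test_that("Fisher enrichment reports the cross-product OR and exact two-sided p", {
  r <- fisher_enrichment(matrix(c(10, 10, 5, 15), 2, byrow = TRUE))
  expect_equal(r$or, 3)
  eq <- fisher_enrichment(matrix(c(10, 10, 10, 10), 2, byrow = TRUE))
  expect_equal(eq$or, 1)
  expect_equal(eq$p, 1)
  tab <- matrix(c(8, 2, 2, 8), 2, byrow = TRUE)
  r2 <- fisher_enrichment(tab)
  expect_equal(r2$p, oracle_fisher_p(tab), tolerance = 1e-9)
  expect_equal(round(r2$p, 3), 0.023)
  z <- fisher_enrichment(matrix(c(5, 0, 3, 7), 2, byrow = TRUE))
  expect_true(z$haldane)
  expect_equal(z$or, (5.5 * 7.5) / (0.5 * 3.5))
  expect_error(fisher_enrichment(matrix(c(0, 0, 3, 7), 2, byrow = TRUE)),
               "degenerate")
  # logical-vector interface
  rv <- fisher_enrichment(c(rep(TRUE, 10), rep(FALSE, 10)),
                          c(rep(TRUE, 5), rep(FALSE, 15)))
  expect_equal(rv$or, 3)
})

test_that("tagged variance reports OLS R^2 and p+2-parameter AIC", {
  set.seed(37)
  n <- 200L
  X <- matrix(rnorm(n * 4), n, 4)
  y_exact <- drop(X %*% c(1, -2, 0.5, 3))
  tv <- suppressWarnings(tagged_variance(X, y_exact))  # perfect-fit notice
  expect_equal(tv$r2, 1, tolerance = 1e-12)

  # independent noise: E[R^2] = p / (n - 1) under the null
  r2s <- vapply(1:200, function(i)
    tagged_variance(X, rnorm(n))$r2, numeric(1))
  expect_lt(abs(mean(r2s) - 4 / (n - 1)), 0.005)

  # adding an irrelevant column never decreases R^2
  y <- drop(X[, 1] + rnorm(n))
  r2_small <- tagged_variance(X[, 1:2], y)$r2
  r2_big <- tagged_variance(cbind(X[, 1:2], rnorm(n)), y)$r2
  expect_gte(r2_big, r2_small)

  # AIC equals the Gaussian-likelihood formula with p + 2 parameters
  tvy <- tagged_variance(X, y)
  fit <- lm(y ~ X)
  rss <- sum(residuals(fit)^2)
  expect_equal(tvy$aic, n * log(2 * pi * rss / n) + n + 2 * (4 + 2),
               tolerance = 1e-8)

  dup <- cbind(X, X[, 1])
  expect_warning(tvd <- tagged_variance(dup, y), "rank-deficient")
  expect_true(tvd$rank_deficient)
  expect_error(tagged_variance(matrix(rnorm(10 * 8), 10, 8), rnorm(10)),
               "n_test")
})
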