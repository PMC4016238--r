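test_that("tTREAT at tau = 1 reduces to the classical two-sided t-test", {
  fits <- as_gene_fits(make_fit_table(200, seed = 1), moderate = FALSE)
  res <- ttreat(fits, tau = 1)
  classical <- 2 * pt(abs(fits$t), df = fits$df, lower.tail = FALSE)
  expect_equal(res$p, classical, tolerance = 1e-12)
})

test_that("genes below the threshold are analytically forced to p = 1", {
  fits <- as_gene_fits(make_fit_table(500, seed = 2), moderate = FALSE)
  res <- ttreat(fits, tau = 2)
  below <- abs(fits$M) < log2(2)
  expect_true(all(res$p[below] == 1))
  expect_true(all(res$p >= 0 & res$p <= 1))
})

test_that("the tail bound matches an independent t-CDF computation", {
  # df = 10, t_obs = 3, delta = 1: p = 2*P(T10 > 2)
  # realized with M = 3*se and tau chosen so log2(tau) = 1*se < |M|
  se <- 0.4
  fit <- data.frame(gene = "g1", M = 3 * se, A = 8, s = se / sqrt(1 / 3),
                    z = 1 / 3, df = 10)
  res <- ttreat(fit, tau = 2^se)
  expect_equal(res$p, 2 * (1 - pt(2, df = 10)), tolerance = 1e-12)
  # and the negative branch mirrors it
  fit$M <- -3 * se
  resn <- ttreat(fit, tau = 2^se)
  expect_equal(resn$p, 2 * pt(-2, df = 10), tolerance = 1e-12)
  expect_equal(resn$direction, "down")
})

test_that("TREAT with d0 = 0 collapses to tTREAT; tau = 1 gives moderated t-test", {
  fits <- as_gene_fits(make_fit_table(300, seed = 3))
  t_cl <- ttreat(fits, tau = 1.5)
  t_m0 <- treat(fits, tau = 1.5, prior = list(d0 = 0))
  expect_equal(t_m0$p, t_cl$p, tolerance = 1e-14)
  expect_identical(t_m0$DE, t_cl$DE)
  res1 <- treat(fits, tau = 1)
  t_mod <- fits$M / sqrt(fits$s2_post * fits$z)
  expect_equal(res1$p, 2 * pt(abs(t_mod), df = fits$df_post,
                              lower.tail = FALSE),
               tolerance = 1e-12)
  # moderation: shrinking the variance moves delta and t together
  shrunk <- fits$s2_post < fits$s^2
  expect_true(any(shrunk))
  expect_true(all(abs(t_mod[shrunk]) >= abs(fits$t[shrunk])))
})

test_that("tTREAT p-values are non-decreasing in tau", {
  fits <- as_gene_fits(make_fit_table(100, seed = 4), moderate = FALSE)
  taus <- c(1, 1.2, 1.5, 2, 3)
  ps <- sapply(taus, function(tau) ttreat(fits, tau)$p)
  expect_true(all(diff(t(ps)) >= -1e-14))
})

test_that("negating all M leaves p unchanged and flips directions", {
  fits <- make_fit_table(150, seed = 5)
  neg <- fits
  neg$M <- -neg$M
  a <- ttreat(fits, 1.5)
  b <- ttreat(neg, 1.5)
  expect_equal(a$p, b$p, tolerance = 1e-14)
  flip <- c(up = "down", down = "up", none = "none")
  expect_identical(unname(flip[a$direction]), b$direction)
})

test_that("tTREAT2 stage 1: stop/go follows the confidence interval", {
  # M = 1.2, se = 0.2, df = 10, alpha_stage1 = 0.05, theta = 2:
  # CI = 1.2 +/- qt(0.975, 10)*0.2 ~ [0.754, 1.646], upper > 1 -> go
  fit <- data.frame(gene = "g1", M = 1.2, A = 8, s = 0.2 / sqrt(1 / 3),
                    z = 1 / 3, df = 10)
  res <- ttreat2(fit, theta = 2, tau = 1.5)
  expect_identical(res$stage, "go")
  ci <- 1.2 + c(-1, 1) * qt(0.975, 10) * 0.2
  expect_equal(ci, c(0.7543, 1.6457), tolerance = 1e-3)
  # enormous theta: every finite CI is strictly inside -> all stop, no DE
  fits <- make_fit_table(100, seed = 6)
  res_all <- ttreat2(fits, theta = 1e6, tau = 1.5)
  expect_true(all(res_all$stage == "stop"))
  expect_true(all(res_all$p == 1))
  expect_false(any(res_all$DE))
  expect_error(ttreat2(fits, theta = 1.5, tau = 1.5), "exceed")
})

test_that("tTREAT2 calls are a subset of tTREAT calls at matched tau and alpha", {
  for (seed in 1:20) {
    fits <- as_gene_fits(make_fit_table(50, seed = seed, m_sd = 1.5),
                         moderate = FALSE)
    t1 <- ttreat(fits, tau = 1.5, alpha = 0.05)
    t2 <- ttreat2(fits, theta = 2.5, tau = 1.5, alpha = 0.05)
    expect_true(all(t2$DE <= t1$DE))  # DE set inclusion
    # stage 2 p-values equal tTREAT p-values for the go genes
    go <- t2$stage == "go"
    expect_equal(t2$p[go], t1$p[go], tolerance = 1e-14)
  }
})

test_that("the bound is conservative at the null boundary |M| = log2(tau)", {
  set.seed(8)
  n <- 2e4; tau <- 1.5; sigma <- 0.5; z <- 1 / 3; df <- 10
  truth <- sample(c(-1, 1), n, replace = TRUE) * log2(tau)
  fits <- data.frame(gene = seq_len(n),
                     M = rnorm(n, truth, sigma * sqrt(z)),
                     s = sqrt(sigma^2 * rchisq(n, df) / df),
                     z = z, df = df)
  for (alpha in c(0.05, 0.01)) {
    rate <- mean(ttreat(fits, tau, alpha = alpha)$p < alpha)
    expect_lte(rate, alpha + 3 * sqrt(alpha * (1 - alpha) / n))
  }
})

test_that("combined criterion is the conjunction of t-test and FC flags", {
  fits <- as_gene_fits(make_fit_table(200, seed = 9, m_sd = 0.8),
                       moderate = FALSE)
  res <- combined_criterion(fits, alpha = 0.01, fc = 1.5)
  p_oracle <- 2 * pt(abs(fits$M / (fits$s * sqrt(fits$z))), df = fits$df,
                     lower.tail = FALSE)
  expect_identical(res$DE,
                   p_oracle < 0.01 & abs(fits$M) > log2(1.5))
  zero <- fits[1, ]; zero$M <- 0
  expect_false(combined_criterion(zero, alpha = 0.5, fc = 1)$DE)
})

test_that("p-value adjustment matches brute-force definitions", {
  expect_equal(adjust_pvalues(0.3, "bh"), 0.3)
  expect_equal(adjust_pvalues(rep(0.01, 10), "bonferroni"), rep(0.1, 10))
  set.seed(10)
  p <- runif(57)
  # brute-force BH step-up
  n <- length(p); o <- order(p)
  bh <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, n / i * p[o[i]])
    bh[o[i]] <- prev
  }
  expect_equal(adjust_pvalues(p, "bh"), bh, tolerance = 1e-12)
  expect_equal(adjust_pvalues(p, "bonferroni"), pmin(1, p * n))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "lie in")
})

test_that("zero-variance genes are reported with p = 1 and never called DE", {
  fits <- data.frame(gene = c("a", "b"), M = c(2, 2), s = c(0, 0.3),
                     z = 1 / 3, df = 10)
  res <- ttreat(fits, tau = 1.5, alpha = 0.05)
  expect_equal(res$p[1], 1)
  expect_false(res$DE[1])
  expect_lt(res$p[2], 1)
})
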