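test_that("inverse-gamma ML: scale family, recovery, and grid-search oracle", {
  set.seed(31)
  x <- 1 / rgamma(2000, shape = 3, rate = 2)
  f1 <- fit_invgamma_ml(x)
  f2 <- fit_invgamma_ml(x * 5)
  expect_equal(f2$g1, f1$g1, tolerance = 1e-4)
  expect_equal(f2$g2, 5 * f1$g2, tolerance = 1e-4)
  expect_equal(f1$convergence, 0)
  # small-sample optimum matches a 2-D grid search to grid resolution
  set.seed(32)
  xs <- 1 / rgamma(50, shape = 2.5, rate = 1.5)
  fs <- fit_invgamma_ml(xs)
  ll <- function(g1, g2)
    sum(g1 * log(g2) - lgamma(g1) - (g1 + 1) * log(xs) - g2 / xs)
  grid <- expand.grid(g1 = seq(0.5, 8, by = 0.05),
                      g2 = seq(0.2, 6, by = 0.05))
  best <- grid[which.max(mapply(ll, grid$g1, grid$g2)), ]
  expect_equal(fs$g1, best$g1, tolerance = 0.06)
  expect_equal(fs$g2, best$g2, tolerance = 0.06)
  expect_gte(fs$loglik, ll(best$g1, best$g2) - 1e-6)
  expect_error(fit_invgamma_ml(c(1, 2, -1)), "10 values")
  expect_error(fit_invgamma_ml(c(rep(1, 10), -1)), "positive")
})

test_that("dataset allocation is exact and truth constraints hold by construction", {
  cfg <- sim_config(omega = 1.5, pct_de = 20)
  sim <- simulate_dataset(cfg, seed = 33)
  expect_equal(nrow(sim), 900)
  expect_equal(as.vector(table(sim$group)), c(180L, 540L, 180L))
  m0 <- log2(1.5)
  expect_true(all(abs(sim$beta[sim$group == 1]) >= m0))
  expect_true(all(abs(sim$beta[sim$group == 2]) < m0))
  expect_true(all(sim$beta[sim$group == 3] == 0))
  # each sigma contributes nine genes in one group
  expect_true(all(table(sim$sigma_id) == 9))
  expect_true(all(tapply(sim$group, sim$sigma_id,
                         function(g) length(unique(g))) == 1))
  # group-1 count is pct_de% of 900 for every admissible percentage
  for (pct in c(1, 7, 40)) {
    s <- simulate_dataset(sim_config(pct_de = pct), seed = 34)
    expect_equal(sum(s$group == 1), 9L * pct)
    expect_equal(sum(s$group == 3), 180L)
  }
  expect_error(sim_config(pct_de = 0), "integer between")
  expect_error(sim_config(omega = 1), "exceed 1")
})

test_that("batches are deterministic in the base seed and differ across seeds", {
  cfg <- sim_config(pct_de = 10)
  b1 <- simulate_batch(cfg, n_reps = 3, base_seed = 100)
  b2 <- simulate_batch(cfg, n_reps = 3, base_seed = 100)
  b3 <- simulate_batch(cfg, n_reps = 3, base_seed = 999)
  for (r in 1:3) {
    expect_identical(b1[[r]], b2[[r]])
    expect_false(isTRUE(all.equal(b1[[r]]$beta_hat, b3[[r]]$beta_hat)))
  }
  # replicates within a batch are distinct
  expect_false(isTRUE(all.equal(b1[[1]]$beta_hat, b1[[2]]$beta_hat)))
  # 400-rep-style counting at pct_de = 10: allocation is deterministic
  frac <- vapply(b1, function(s) mean(s$group == 1), numeric(1))
  expect_equal(frac, rep(0.1, 3))
})

test_that("standardized effect estimates are standard normal", {
  cfg <- sim_config(pct_de = 10, n_sigma = 1200)  # 10800 genes
  sim <- simulate_dataset(cfg, seed = 35)
  zstat <- (sim$beta_hat - sim$beta) / sqrt(sim$sigma2 * sim$z)
  ks <- ks.test(zstat, "pnorm")
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(zstat), 0, tolerance = 0.05)
  expect_equal(sd(zstat), 1, tolerance = 0.05)
})

test_that("residual variances follow the scaled chi-square hierarchy", {
  cfg <- sim_config(pct_de = 10, n_sigma = 1200, df = 10)
  sim <- simulate_dataset(cfg, seed = 36)
  q <- cfg$df * sim$s2 / sim$sigma2
  expect_equal(mean(q), cfg$df, tolerance = 0.05 * cfg$df)
  expect_equal(var(q), 2 * cfg$df, tolerance = 0.15 * 2 * cfg$df)
})

test_that("near-degenerate truncation: |beta_hat - beta| is half-normal", {
  cfg <- sim_config(omega = 1.0001, pct_de = 40, n_sigma = 500)
  sim <- simulate_dataset(cfg, seed = 37)
  dev <- abs(sim$beta_hat - sim$beta) / sqrt(sim$sigma2 * sim$z)
  expect_equal(mean(dev), sqrt(2 / pi), tolerance = 0.03)
})

test_that("simulator closes the loop with the inverse-gamma ML fit", {
  cfg <- sim_config(pct_de = 10, g1 = 3, g2 = 0.5, n_sigma = 2000)
  sim <- simulate_dataset(cfg, seed = 38)
  sig <- sim$sigma2[!duplicated(sim$sigma_id)]
  f <- fit_invgamma_ml(sig)
  expect_equal(f$g1, 3, tolerance = 0.15)
  expect_equal(f$g2, 0.5, tolerance = 0.15)
})

test_that("count fixture records recoverable normalization truth", {
  tmp <- tempfile(fileext = ".tsv")
  smp <- tempfile(fileext = ".tsv")
  tru <- tempfile(fileext = ".tsv")
  fx <- generate_count_fixture(n_genes = 25, seed = 39, path = tmp,
                               samples_path = smp, truth_path = tru)
  # round trip
  back <- read_counts(tmp, smp)
  expect_equal(back$counts, fx$counts$counts, tolerance = 1e-10)
  # known-factor recovery after normalization
  nm <- normalize_counts(fx$counts)
  truth <- read.delim(tru)
  expect_equal(unname(nm$pos_factor), truth$pos_factor, tolerance = 1e-10)
  # background recovery: mean + 2*SD of the post-step-2 negatives
  neg <- nm_step2_negatives <- {
    # recompute what the emitted negatives look like after scaling steps
    raw <- fx$counts$counts[fx$counts$probe_class == "Negative", ]
    s1 <- sweep(raw, 2, nm$pos_factor, `*`)
    sweep(s1, 2, nm$ref_factor, `*`)
  }
  expect_equal(unname(nm$background),
               unname(apply(neg, 2, function(v) mean(v) + 2 * sd(v))),
               tolerance = 1e-10)
})
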