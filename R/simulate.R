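# Simulation engine for two-group digital-count experiments.
#
# Hierarchy: 100 gene variances sigma_g^2 drawn from an inverse-gamma prior;
# each sigma gives three true log2 differences beta (Gaussian with SD
# sigma*v_start, truncated by the DE rule), each beta gives three estimates
# beta_hat ~ N(beta, (sigma*sqrt(z))^2) and three residual variances
# s2 ~ sigma^2 * chisq(df)/df -- 900 genes per dataset. Truth groups:
# 1 = DE (|beta| >= log2 omega), 2 = noisy non-DE (0 < |beta| < log2 omega),
# 3 = regular non-DE (beta = 0, fixed at 20% of genes).

#' Simulation configuration
#'
#' @param omega Fold change defining DE truth (> 1): group-1 genes satisfy
#'   |beta| >= log2(omega).
#' @param pct_de Integer percent of DE genes, 1--40 (each percent is one
#'   sigma's nine genes, so the allocation is exact).
#' @param v_start Multiplier of sigma giving the SD of the true differences
#'   (default 8).
#' @param df Residual degrees of freedom per gene (default 10, a 6 vs 6
#'   two-group design).
#' @param z Contrast variance scale (default 1/3 = 1/6 + 1/6).
#' @param g1,g2 Inverse-gamma shape and scale of the variance prior. The
#'   packaged defaults (3, 0.5) describe a plausible digital-count variance
#'   population on the log2 scale (mean sigma^2 = 0.25); they are a package
#'   choice, not fitted to any published dataset. Use
#'   \code{\link{fit_invgamma_ml}} on real residual variances to seed the
#'   simulation from data.
#' @param n_sigma Number of gene variances drawn (default 100; total genes =
#'   9 * n_sigma).
#' @param pct_regular Percent of regular non-DE genes (fixed design point,
#'   default 20).
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(omega = 1.5, pct_de = 10, v_start = 8, df = 10,
                       z = 1 / 3, g1 = 3, g2 = 0.5, n_sigma = 100,
                       pct_regular = 20) {
  if (omega <= 1) stop("omega must exceed 1")
  if (pct_de != round(pct_de) || pct_de < 1 || pct_de > 100 - pct_regular - 1)
    stop("pct_de must be an integer between 1 and ", 100 - pct_regular - 1)
  if (any(c(v_start, df, z, g1, g2) <= 0)) stop("all parameters must be positive")
  if (n_sigma %% 100 != 0 && n_sigma != 100)
    if ((n_sigma * pct_de) %% 100 != 0 || (n_sigma * pct_regular) %% 100 != 0)
      stop("n_sigma must make the percentage allocation whole")
  structure(list(omega = omega, pct_de = pct_de, v_start = v_start, df = df,
                 z = z, g1 = g1, g2 = g2, n_sigma = n_sigma,
                 pct_regular = pct_regular),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulation config: omega = %g, %d%% DE / %d%% regular non-DE, v_start = %g\n",
    x$omega, x$pct_de, x$pct_regular, x$v_start))
  cat(sprintf("  variance prior InvGamma(%g, %g); df = %g, z = %g; %d genes\n",
              x$g1, x$g2, x$df, x$z, 9L * x$n_sigma))
  invisible(x)
}

# draw n values from N(0, sd) subject to keep(|x|); plain rejection sampling
# with a doubling batch size so low acceptance rates stay cheap
rtrunc_norm <- function(n, sd, keep) {
  out <- numeric(0)
  batch <- max(4L * n, 32L)
  repeat {
    cand <- stats::rnorm(batch, 0, sd)
    out <- c(out, cand[keep(abs(cand))])
    if (length(out) >= n) break
    batch <- min(2L * batch, 262144L)
  }
  out[seq_len(n)]
}

#' Simulate one two-group digital-count dataset
#'
#' Draws a full dataset from the hierarchy described above (by default 900
#' genes from 100 gene variances) with exact truth-group allocation: the
#' first \code{pct_de} variances carry the DE genes, the last
#' \code{pct_regular/ (100/n_sigma)} the regular non-DE genes, the rest the
#' noisy non-DE genes.
#'
#' @param config A \code{\link{sim_config}}.
#' @param seed Optional integer seed for reproducibility.
#' @return Object of class \code{sim_dataset}: a data frame with columns
#'   \code{gene}, \code{group} (1 DE / 2 noisy non-DE / 3 regular non-DE),
#'   \code{sigma2}, \code{beta}, \code{beta_hat}, \code{s2}, \code{df},
#'   \code{z}, plus \code{M} and \code{s} aliases so it can be fed directly
#'   to the threshold tests via \code{\link{as_gene_fits}}. The config is
#'   attached as attribute \code{config}.
#' @export
simulate_dataset <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  ns <- config$n_sigma
  per_pct <- ns / 100
  n1 <- as.integer(config$pct_de * per_pct)       # DE sigmas
  n3 <- as.integer(config$pct_regular * per_pct)  # regular non-DE sigmas
  n2 <- ns - n1 - n3
  if (n2 < 0) stop("percentages exceed 100")
  sigma2 <- 1 / stats::rgamma(ns, shape = config$g1, rate = config$g2)
  group_of_sigma <- rep(c(1L, 2L, 3L), times = c(n1, n2, n3))
  m0 <- log2(config$omega)

  rows <- vector("list", ns)
  for (i in seq_len(ns)) {
    sg <- sqrt(sigma2[i])
    beta <- switch(group_of_sigma[i],
                   rtrunc_norm(3L, sg * config$v_start, function(a) a >= m0),
                   rtrunc_norm(3L, sg * config$v_start, function(a) a < m0),
                   rep(0, 3L))
    beta9 <- rep(beta, each = 3L)
    beta_hat <- stats::rnorm(9L, beta9, sg * sqrt(config$z))
    s2 <- sigma2[i] * stats::rchisq(9L, df = config$df) / config$df
    rows[[i]] <- data.frame(
      sigma_id = i, group = group_of_sigma[i], sigma2 = sigma2[i],
      beta = beta9, beta_hat = beta_hat, s2 = s2,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- data.frame(gene = sprintf("sim%04d", seq_len(nrow(out))), out,
                    df = config$df, z = config$z, stringsAsFactors = FALSE)
  out$M <- out$beta_hat
  out$s <- sqrt(out$s2)
  attr(out, "config") <- config
  class(out) <- c("sim_dataset", "data.frame")
  out
}

#' Simulate a batch of independent dataset realizations
#'
#' Replicate r is seeded deterministically as \code{base_seed + r}, so a batch
#' is reproducible end-to-end and replicates are mutually independent.
#'
#' @param config A \code{\link{sim_config}}.
#' @param n_reps Number of realizations (the full study uses 400).
#' @param base_seed Integer base seed.
#' @return List of \code{sim_dataset} objects.
#' @export
simulate_batch <- function(config = sim_config(), n_reps = 400,
                           base_seed = 1L) {
  lapply(seq_len(n_reps),
         function(r) simulate_dataset(config, seed = base_seed + r))
}

#' Maximum-likelihood fit of an inverse-gamma distribution
#'
#' Fits shape \code{g1} and scale \code{g2} of an inverse-gamma distribution
#' to positive values (gene variances) by numerical maximization of the
#' log-likelihood on the log-parameter scale, started from the
#' method-of-moments solution. Used to seed simulations from a real variance
#' population.
#'
#' @param x Positive values (at least 10).
#' @return List of class \code{invgamma_fit} with \code{g1}, \code{g2},
#'   \code{loglik}, \code{convergence} (0 = converged).
#' @export
fit_invgamma_ml <- function(x) {
  if (length(x) < 10L) stop("need at least 10 values")
  if (any(x <= 0)) stop("all values must be positive")
  n <- length(x)
  slx <- sum(log(x))
  six <- sum(1 / x)
  nll <- function(th) {
    g1 <- exp(th[1L]); g2 <- exp(th[2L])
    -(n * g1 * log(g2) - n * lgamma(g1) - (g1 + 1) * slx - g2 * six)
  }
  grad <- function(th) {
    g1 <- exp(th[1L]); g2 <- exp(th[2L])
    dg1 <- -(n * log(g2) - n * digamma(g1) - slx) * g1
    dg2 <- -(n * g1 / g2 - six) * g2
    c(dg1, dg2)
  }
  # method-of-moments start (fall back to a generic start if var is degenerate)
  mx <- mean(x); vx <- stats::var(x)
  g1_0 <- if (is.finite(vx) && vx > 0) max(mx^2 / vx + 2, 0.5) else 2
  g2_0 <- mx * max(g1_0 - 1, 0.5)
  opt <- stats::optim(log(c(g1_0, g2_0)), nll, grad, method = "BFGS",
                      control = list(maxit = 500L, reltol = 1e-12))
  structure(list(g1 = exp(opt$par[1L]), g2 = exp(opt$par[2L]),
                 loglik = -opt$value, convergence = opt$convergence),
            class = "invgamma_fit")
}

#' @export
print.invgamma_fit <- function(x, ...) {
  cat(sprintf("Inverse-gamma ML fit: shape g1 = %.4g, scale g2 = %.4g (loglik %.2f)\n",
              x$g1, x$g2, x$loglik))
  invisible(x)
}

#' Generate a cartridge-like count fixture with known normalization truth
#'
#' Builds a small synthetic \code{\link{count_matrix}} in the tabular export
#' dialect: six positive spikes, eight negatives, five housekeeping genes and
#' \code{n_genes} endogenous probes over \code{n_lanes} lanes split into two
#' groups. Every lane's counts are multiplied by a known lane scale factor,
#' so the positive-control normalization factors the pipeline should recover
#' are known exactly and returned as the \code{truth} component (and written
#' to a sidecar TSV when paths are given).
#'
#' @param n_genes Endogenous probes (default 50).
#' @param n_lanes Lanes (default 6), split evenly into groups.
#' @param groups Two group labels (default \code{c("control", "mutant")}).
#' @param noise_sd Log2-scale SD of multiplicative lane-to-lane noise on the
#'   endogenous probes (default 0.25; set 0 for a noiseless fixture whose
#'   within-group endogenous counts are exactly reproducible). Control
#'   probes are always noiseless so the factor truth stays exact.
#' @param seed Integer seed.
#' @param path,samples_path,truth_path Optional output paths (counts TSV,
#'   samples TSV, sidecar truth TSV).
#' @return List with \code{counts} (a \code{count_matrix}) and \code{truth}
#'   (data frame: lane, lane scale, expected positive-control factor).
#' @export
generate_count_fixture <- function(n_genes = 50, n_lanes = 6,
                                   groups = c("control", "mutant"),
                                   noise_sd = 0.25, seed = 1L, path = NULL,
                                   samples_path = NULL, truth_path = NULL) {
  set.seed(seed)
  lane_ids <- sprintf("lane%02d", seq_len(n_lanes))
  grp <- rep(groups, each = ceiling(n_lanes / 2))[seq_len(n_lanes)]
  lane_scale <- stats::runif(n_lanes, 0.7, 1.4)

  pos_base <- c(128, 320, 800, 2000, 5000, 12500)      # spike ladder
  neg_base <- stats::runif(8, 2, 12)
  hk_base <- stats::runif(5, 400, 4000)
  endo_base <- 2^stats::runif(n_genes, 5, 12)
  effect <- 2^stats::rnorm(n_genes, 0, 0.3)            # group-2 multiplier

  build_lane <- function(l) {
    e <- endo_base * if (grp[l] == groups[2L]) effect else 1
    e <- e * 2^stats::rnorm(n_genes, 0, noise_sd)
    lane_scale[l] * c(pos_base, neg_base, hk_base, e)
  }
  counts <- vapply(seq_len(n_lanes), build_lane,
                   numeric(6 + 8 + 5 + n_genes))
  rownames(counts) <- c(sprintf("POS_%d", 1:6), sprintf("NEG_%d", 1:8),
                        sprintf("HK_%d", 1:5), sprintf("GENE_%03d", seq_len(n_genes)))
  colnames(counts) <- lane_ids
  cls <- rep(c("Positive", "Negative", "Housekeeping", "Endogenous"),
             times = c(6, 8, 5, n_genes))
  cm <- count_matrix(counts, cls, grp, cartridge = rep("SIM1", n_lanes))
  truth <- data.frame(lane_id = lane_ids, lane_scale = lane_scale,
                      pos_factor = mean(lane_scale) / lane_scale,
                      stringsAsFactors = FALSE)
  if (!is.null(path)) {
    if (is.null(samples_path))
      samples_path <- sub("\\.tsv$", "_samples.tsv", path)
    write_counts(cm, path, samples_path)
    if (!is.null(truth_path))
      utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
  }
  list(counts = cm, truth = truth)
}
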