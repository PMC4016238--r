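# Composite-null tests relative to a fold-change threshold.
#
# Null hypothesis: |M_g| <= log2(tau); the p-value is the conservative upper
# bound obtained at the hardest-to-reject point of the null interval,
# M0 = min(log2 tau, |M_obs|), with non-centrality delta = M0/(s*sqrt(z)):
#   t_obs >= 0:  p <= 2 * P(T_df > t_obs - delta)
#   t_obs <  0:  p <= 2 * P(T_df < t_obs + delta)
# clamped to [0, 1].

threshold_pvalue <- function(M, se, t_obs, df, tau) {
  # se = s*sqrt(z) (or moderated); vectorized over genes, tau may be per-gene
  if (any(tau < 1)) stop("fold-change threshold tau must be >= 1")
  M0 <- pmin(log2(rep_len(tau, length(M))), abs(M))
  p <- rep(1, length(M))
  ok <- se > 0 & df >= 1
  delta <- M0[ok] / se[ok]
  tt <- t_obs[ok]
  dfo <- rep_len(df, length(M))[ok]
  pv <- ifelse(tt >= 0,
               2 * stats::pt(tt - delta, df = dfo, lower.tail = FALSE),
               2 * stats::pt(tt + delta, df = dfo, lower.tail = TRUE))
  p[ok] <- pmin(pv, 1)
  p
}

new_fc_test <- function(fits, method, tau, theta = NA_real_, p, stage,
                        de, alpha, adjust = "none") {
  p_adj <- adjust_pvalues(p, adjust)
  out <- data.frame(gene = fits$gene, M = fits$M, A = fits$A,
                    method = method, tau = tau, theta = theta,
                    stage = stage, p = p, p_adjusted = p_adj,
                    DE = de,
                    direction = ifelse(fits$M > 0, "up",
                                       ifelse(fits$M < 0, "down", "none")),
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  class(out) <- c("fc_test", "data.frame")
  out
}

#' @export
print.fc_test <- function(x, ...) {
  cat("Fold-change-threshold test:", x$method[1L], " tau =", x$tau[1L])
  if (!is.na(x$theta[1L])) cat(", theta =", x$theta[1L])
  cat("\n  genes:", nrow(x), "  DE calls:", sum(x$DE),
      "(", sum(x$DE & x$direction == "up"), "up /",
      sum(x$DE & x$direction == "down"), "down ) at alpha =",
      attr(x, "alpha"), "\n")
  invisible(x)
}

#' @export
summary.fc_test <- function(object, ...) {
  print(object)
  if (any(object$stage == "stop"))
    cat("  stage 1 stopped", sum(object$stage == "stop"), "genes;",
        sum(object$stage == "go"), "went to stage 2\n")
  cat("  p-value quartiles:",
      paste(signif(stats::quantile(object$p), 3), collapse = " "), "\n")
  invisible(object)
}

#' tTREAT: threshold test on the classical t-statistic
#'
#' Tests, per gene, the composite null |M| <= log2(tau) against |M| > log2(tau)
#' using the classical (unmoderated) gene-wise t-statistic. The p-value is the
#' conservative bound at the hardest-to-reject boundary point of the null
#' interval. A gene whose observed |M| is below log2(tau) is analytically
#' forced to p = 1. Genes with zero residual SD are reported with p = 1
#' (no evidence scale).
#'
#' @param fits A \code{\link{gene_fits}} object (or compatible data frame).
#' @param tau Fold-change threshold on the natural scale, >= 1.
#' @param alpha Significance cut-off for the DE call.
#' @param adjust Multiple-testing adjustment: \code{"none"} (the default;
#'   the bound is already conservative), \code{"bonferroni"} or \code{"bh"}.
#' @return An \code{fc_test} data frame with per-gene p-values and DE calls.
#' @export
ttreat <- function(fits, tau, alpha = 0.05, adjust = "none") {
  fits <- ensure_fits(fits, moderate = FALSE)
  p <- threshold_pvalue(fits$M, fits$s * sqrt(fits$z), fits$t, fits$df, tau)
  de <- adjust_pvalues(p, adjust) < alpha
  new_fc_test(fits, "ttreat", tau, p = p, stage = "n/a", de = de,
              alpha = alpha, adjust = adjust)
}

#' TREAT: threshold test on the empirical-Bayes moderated t-statistic
#'
#' Same composite-null bound as \code{\link{ttreat}}, applied to the moderated
#' statistic: the residual variance is replaced by the posterior (shrunken)
#' variance and the degrees of freedom are augmented by the prior degrees of
#' freedom d0. With \code{d0 = 0} the test collapses exactly to
#' \code{\link{ttreat}}.
#'
#' @inheritParams ttreat
#' @param prior Optional list with elements \code{d0} and \code{s0_2}
#'   overriding the prior estimated from \code{fits} (use
#'   \code{list(d0 = 0)} to force the classical statistics).
#' @return An \code{fc_test} data frame.
#' @export
treat <- function(fits, tau, alpha = 0.05, adjust = "none", prior = NULL) {
  fits <- ensure_fits(fits, moderate = is.null(prior))
  if (!is.null(prior)) {
    d0 <- prior$d0
    if (d0 == 0) {
      s2_post <- fits$s^2
    } else if (is.infinite(d0)) {
      s2_post <- rep(prior$s0_2, nrow(fits))
    } else {
      s2_post <- (d0 * prior$s0_2 + fits$df * fits$s^2) / (d0 + fits$df)
    }
    df_post <- fits$df + d0
  } else {
    s2_post <- fits$s2_post
    df_post <- fits$df_post
  }
  se <- sqrt(s2_post * fits$z)
  t_mod <- ifelse(se > 0, fits$M / se, 0)
  p <- threshold_pvalue(fits$M, se, t_mod, df_post, tau)
  de <- adjust_pvalues(p, adjust) < alpha
  new_fc_test(fits, "treat", tau, p = p, stage = "n/a", de = de,
              alpha = alpha, adjust = adjust)
}

#' tTREAT2: two-stage stop-or-go threshold test
#'
#' Stage 1 ("stop or go") screens each gene with a 100(1 - alpha_stage1)%
#' confidence interval for M. If that interval falls strictly inside the
#' enlarged interval [-log2(theta), log2(theta)] (theta > tau, the safety
#' margin), the gene is called non-DE and stops. Otherwise the gene goes on to
#' stage 2, a \code{\link{ttreat}} test at threshold tau; it is called DE when
#' the stage-2 p-value is below \code{alpha}. Stopped genes are reported with
#' p = 1.
#'
#' @inheritParams ttreat
#' @param theta Stage-1 fold-change threshold (> tau) defining the safety
#'   margin.
#' @param alpha_stage1 Complement of the stage-1 confidence level
#'   (default 0.05).
#' @param alpha Stage-2 significance cut-off (default 0.01).
#' @return An \code{fc_test} data frame with a \code{stage} column
#'   (\code{"stop"} or \code{"go"}).
#' @export
ttreat2 <- function(fits, theta, tau, alpha_stage1 = 0.05, alpha = 0.01,
                    adjust = "none") {
  if (theta <= tau) stop("theta must exceed tau (safety margin)")
  if (tau < 1) stop("tau must be >= 1")
  fits <- ensure_fits(fits, moderate = FALSE)
  se <- fits$s * sqrt(fits$z)
  tq <- stats::qt(1 - alpha_stage1 / 2, df = fits$df)
  lo <- fits$M - tq * se
  hi <- fits$M + tq * se
  stop1 <- lo > -log2(theta) & hi < log2(theta)
  p <- rep(1, nrow(fits))
  go <- !stop1
  if (any(go)) {
    p[go] <- threshold_pvalue(fits$M[go], se[go], fits$t[go], fits$df[go], tau)
  }
  de <- adjust_pvalues(p, adjust) < alpha & go
  new_fc_test(fits, "ttreat2", tau, theta = theta, p = p,
              stage = ifelse(stop1, "stop", "go"), de = de,
              alpha = alpha, adjust = adjust)
}

#' Combined p-value + fold-change criterion
#'
#' The ad-hoc comparator: a gene is called DE when the ordinary two-sided
#' t-test (point null M = 0) is significant at \code{alpha} and its observed
#' fold change exceeds \code{fc}.
#'
#' @inheritParams ttreat
#' @param fc Fold-change criterion on the natural scale, >= 1.
#' @return An \code{fc_test} data frame (p is the ordinary t-test p-value;
#'   the DE column encodes the conjunction).
#' @export
combined_criterion <- function(fits, alpha = 0.01, fc = 1.5, adjust = "none") {
  if (fc < 1) stop("fc must be >= 1")
  fits <- ensure_fits(fits, moderate = FALSE)
  p <- rep(1, nrow(fits))
  ok <- fits$s > 0
  p[ok] <- 2 * stats::pt(abs(fits$t[ok]), df = fits$df[ok], lower.tail = FALSE)
  de <- adjust_pvalues(p, adjust) < alpha & abs(fits$M) > log2(fc)
  new_fc_test(fits, "combined", fc, p = p, stage = "n/a", de = de,
              alpha = alpha, adjust = adjust)
}

#' Multiple-testing adjustment
#'
#' Thin wrapper with the pipeline's default of no adjustment (the composite
#' null bound is already conservative); Bonferroni and Benjamini-Hochberg are
#' available behind the flag.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param method \code{"none"}, \code{"bonferroni"} or \code{"bh"}.
#' @return Adjusted p-values, clamped at 1.
#' @export
adjust_pvalues <- function(p, method = c("none", "bonferroni", "bh")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  switch(method,
         none = p,
         bonferroni = stats::p.adjust(p, method = "bonferroni"),
         bh = stats::p.adjust(p, method = "BH"))
}

# accept either a gene_fits object or a raw sufficient-statistics table
ensure_fits <- function(fits, moderate) {
  if (!inherits(fits, "gene_fits")) return(as_gene_fits(fits, moderate = moderate))
  if (moderate && is.null(fits$s2_post))
    return(as_gene_fits(as.data.frame(fits), moderate = TRUE))
  fits
}
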