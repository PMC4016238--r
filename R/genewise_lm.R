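#' Two-group design specification
#'
#' Builds the group-means design for a two-group comparison: an intercept-free
#' indicator matrix with one column per group and the contrast
#' test minus control, so the contrast estimate is the log2 fold change M.
#'
#' @param groups Character vector of per-lane group labels (exactly two
#'   distinct values).
#' @param control Label of the control (reference) group. Defaults to the
#'   first label in sorted order.
#' @return A list of class \code{design_spec} with elements \code{X} (lanes x
#'   coefficients), \code{contrast} (coefficient-space contrast vector),
#'   \code{coef_names}, \code{z} (the contrast variance scale
#'   \code{t(C) (X'X)^-1 C}) and \code{df} (residual degrees of freedom).
#' @export
two_group_design <- function(groups, control = NULL) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2L) stop("exactly two distinct group labels required")
  if (is.null(control)) control <- sort(lev)[1L]
  if (!control %in% lev) stop("control label not among the groups")
  test <- setdiff(lev, control)
  lev <- c(control, test)
  X <- cbind(as.numeric(groups == lev[1L]), as.numeric(groups == lev[2L]))
  colnames(X) <- lev
  if (any(colSums(X) == 0)) stop("one group has no lanes")
  design_spec(X, contrast = c(-1, 1), coef_names = lev)
}

#' General design specification
#'
#' @param X Design matrix (lanes x coefficients), full column rank.
#' @param contrast Numeric contrast vector conformable with the columns of X.
#' @param coef_names Optional coefficient names.
#' @return A \code{design_spec} list; see \code{\link{two_group_design}}.
#' @export
design_spec <- function(X, contrast, coef_names = colnames(X)) {
  X <- as.matrix(X)
  if (length(contrast) != ncol(X)) stop("contrast not conformable with design")
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("design matrix is rank deficient")
  V <- chol2inv(qr.R(qx))  # (X'X)^-1
  z <- drop(t(contrast) %*% V %*% contrast)
  structure(list(X = X, contrast = as.numeric(contrast),
                 coef_names = coef_names, qr = qx, V = V, z = z,
                 df = nrow(X) - qx$rank),
            class = "design_spec")
}

#' Fit one gene-wise linear model
#'
#' Least-squares fit of a single gene's log2 expression vector against the
#' design; returns the contrast estimate (the log2 fold change M), residual
#' SD, the contrast scale z, degrees of freedom and the classical t-statistic
#' \code{t = M/(s*sqrt(z))}. Genes with zero residual variance get \code{t = 0}
#' by convention (flagged downstream with p = 1 in the classical tests).
#'
#' @param y Numeric vector of log2 counts, one value per design row.
#' @param design A \code{\link{design_spec}}.
#' @return A list with \code{coef}, \code{M}, \code{s}, \code{z}, \code{df},
#'   \code{t}.
#' @export
fit_gene <- function(y, design) {
  stopifnot(inherits(design, "design_spec"))
  if (length(y) != nrow(design$X)) stop("length(y) must match design rows")
  if (design$df < 1L) stop("at least one residual degree of freedom required")
  psi <- qr.coef(design$qr, y)
  res <- y - drop(design$X %*% psi)
  s2 <- sum(res^2) / design$df
  s <- sqrt(s2)
  M <- drop(sum(design$contrast * psi))
  t <- if (s > 0) M / (s * sqrt(design$z)) else 0
  list(coef = psi, M = M, s = s, z = design$z, df = design$df, t = t)
}

#' Gene-wise linear-model fits for a normalized count matrix
#'
#' The central fitting function. Fits the gene-wise linear model to the log2
#' normalized counts of every (informative) gene, computes contrast estimates
#' (log2 fold changes), residual SDs, classical t-statistics, average
#' expression A, and the empirical-Bayes moderated t via variance shrinkage
#' towards a pooled prior (see \code{\link{estimate_prior}}).
#'
#' @param object A \code{norm_matrix} (from \code{\link{normalize_counts}}),
#'   or a numeric matrix of log2 expression values (genes x lanes).
#' @param design A \code{\link{design_spec}}; if \code{NULL} and \code{object}
#'   is a \code{norm_matrix} with two groups, a two-group design is built with
#'   \code{control} as reference.
#' @param genes Optional gene ids to fit (default: endogenous probes for a
#'   \code{norm_matrix}, all rows for a matrix).
#' @param control For the automatic two-group design: the reference group.
#' @param moderate Logical; estimate the variance-shrinkage prior and attach
#'   moderated statistics (default \code{TRUE}).
#' @return An object of class \code{gene_fits}: a data frame with one row per
#'   gene and columns \code{gene}, \code{M}, \code{A}, \code{s}, \code{z},
#'   \code{df}, \code{t}, and when moderated also \code{s2_post},
#'   \code{df_post}, \code{t_mod}; the prior \code{(d0, s0_2)} is stored in
#'   attributes \code{d0} and \code{s0_2}.
#' @export
gene_fits <- function(object, design = NULL, genes = NULL, control = NULL,
                      moderate = TRUE) {
  if (inherits(object, "norm_matrix")) {
    if (is.null(design)) {
      lev <- unique(object$groups)
      if (length(lev) != 2L)
        stop("norm_matrix has ", length(lev), " groups; supply a design")
      design <- two_group_design(object$groups, control = control)
    }
    if (is.null(genes))
      genes <- rownames(object$normalized)[object$probe_class == "Endogenous"]
    ymat <- log2(object$normalized[genes, , drop = FALSE])
  } else {
    ymat <- as.matrix(object)
    if (is.null(genes)) genes <- rownames(ymat)
    if (is.null(genes)) genes <- paste0("g", seq_len(nrow(ymat)))
    if (is.null(design)) stop("a design is required for a plain matrix")
    ymat <- ymat[, , drop = FALSE]
  }
  stopifnot(inherits(design, "design_spec"))
  if (ncol(ymat) != nrow(design$X)) stop("lanes do not match design rows")

  # vectorized least squares over genes: coefficients via one QR solve
  psi <- t(qr.coef(design$qr, t(ymat)))          # genes x coefficients
  fitted <- psi %*% t(design$X)
  rss <- rowSums((ymat - fitted)^2)
  s2 <- rss / design$df
  s <- sqrt(s2)
  M <- drop(psi %*% design$contrast)
  tstat <- ifelse(s > 0, M / (s * sqrt(design$z)), 0)
  A <- rowMeans(ymat)

  out <- data.frame(gene = genes, M = unname(M), A = unname(A),
                    s = unname(s), z = design$z, df = design$df,
                    t = unname(tstat), stringsAsFactors = FALSE)
  out <- as_gene_fits(out, moderate = moderate)
  attr(out, "design") <- design
  out
}

#' Coerce a per-gene fit table to a gene_fits object
#'
#' Accepts any data frame carrying the sufficient statistics of the gene-wise
#' model -- columns \code{gene}, \code{M}, \code{s}, \code{z}, \code{df}
#' (optionally \code{A}) -- e.g. the output of \code{\link{simulate_dataset}},
#' and attaches classical and (optionally) moderated t-statistics.
#'
#' @param x Data frame with columns \code{gene}, \code{M}, \code{s}, \code{z},
#'   \code{df}.
#' @param moderate Estimate the shrinkage prior and moderated t.
#' @return A \code{gene_fits} object.
#' @export
as_gene_fits <- function(x, moderate = TRUE) {
  need <- c("gene", "M", "s", "z", "df")
  if (!all(need %in% names(x)))
    stop("need columns: ", paste(setdiff(need, names(x)), collapse = ", "))
  x <- as.data.frame(x)
  if (!"A" %in% names(x)) x$A <- NA_real_
  if (!"t" %in% names(x)) x$t <- ifelse(x$s > 0, x$M / (x$s * sqrt(x$z)), 0)
  if (moderate) {
    pr <- estimate_prior(x$s^2, x$df)
    x$s2_post <- pr$s2_post
    x$df_post <- pr$df_post
    x$t_mod <- x$M / sqrt(x$s2_post * x$z)
    attr(x, "d0") <- pr$d0
    attr(x, "s0_2") <- pr$s0_2
  }
  class(x) <- c("gene_fits", "data.frame")
  x
}

#' @export
print.gene_fits <- function(x, ...) {
  cat("Gene-wise linear-model fits:", nrow(x), "genes, df =",
      x$df[1L], ", z =", signif(x$z[1L], 4), "\n")
  if (!is.null(attr(x, "d0")))
    cat("  variance prior: d0 =", signif(attr(x, "d0"), 4),
        ", s0^2 =", signif(attr(x, "s0_2"), 4), "\n")
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6L) cat("  ...", nrow(x) - 6L, "more genes\n")
  invisible(x)
}

#' @export
summary.gene_fits <- function(object, ...) {
  cat("Gene-wise fits:", nrow(object), "genes\n")
  cat("  |M| quartiles:",
      paste(signif(stats::quantile(abs(object$M)), 3), collapse = " "), "\n")
  cat("  residual SD quartiles:",
      paste(signif(stats::quantile(object$s), 3), collapse = " "), "\n")
  if (!is.null(attr(object, "d0")))
    cat("  shrinkage prior: d0 =", signif(attr(object, "d0"), 4),
        ", s0^2 =", signif(attr(object, "s0_2"), 4), "\n")
  invisible(object)
}

#' @export
coef.gene_fits <- function(object, ...) {
  stats::setNames(object$M, object$gene)
}

#' MA plot method for gene-wise fits
#'
#' @param x A \code{gene_fits} object with A values.
#' @param ... Passed to \code{\link{ma_plot}}.
#' @export
plot.gene_fits <- function(x, ...) {
  ma_plot(x, ...)
}

#' Inverse of the trigamma function
#'
#' Newton iteration on \code{trigamma(y) = x}, used by the method-of-moments
#' fit of the variance prior. Monotone decreasing, so the iteration is safe
#' from any positive start; convergence is quadratic.
#'
#' @param x Positive numeric vector.
#' @return y with \code{trigamma(y) = x}, elementwise.
#' @export
trigamma_inverse <- function(x) {
  out <- x
  pos <- is.finite(x) & x > 0
  out[!pos & !is.na(x)] <- NA_real_
  if (!any(pos)) return(out)
  xv <- x[pos]
  # large x (small y): trigamma(y) ~ 1/y^2; small x: trigamma(y) ~ 1/y
  y <- 0.5 + 1 / xv
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / xv) / psigamma(y, 2L)
    y <- y + dif
    if (max(-dif / y) < 1e-10) break
  }
  out[pos] <- y
  out
}

#' Empirical-Bayes variance prior and shrunken variances
#'
#' Fits the hierarchical model in which the true gene variances follow a
#' scaled inverse chi-square prior with d0 degrees of freedom and scale s0^2,
#' and observed sample variances are scaled chi-squares given the truth.
#' The prior is estimated by method of moments on log(s^2) (digamma/trigamma
#' moment matching); each gene's posterior variance is the precision-weighted
#' blend \code{s2_post = (d0*s0^2 + df*s^2)/(d0 + df)} with moderated degrees
#' of freedom \code{df + d0}. With \code{d0 = 0} everything reduces to the
#' classical statistics; identical variances give \code{d0 = Inf} (complete
#' pooling).
#'
#' @param s2 Sample variances (one per gene), non-negative.
#' @param df Residual degrees of freedom (scalar or per gene).
#' @return List with \code{d0}, \code{s0_2}, and per-gene \code{s2_post},
#'   \code{df_post}.
#' @export
estimate_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- s2 > 0 & df >= 1
  if (sum(ok) < 2L) stop("need >= 2 genes with positive variance and df >= 1")
  e <- log(s2[ok]) - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1L)
  evar <- evar - mean(trigamma(df[ok] / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # observed variances are (numerically) exchangeable with no excess spread:
    # complete pooling, and the pooled value is the variances' geometric mean
    # (no log-bias correction, so constant inputs pass through unchanged)
    d0 <- Inf
    s0_2 <- exp(mean(log(s2[ok])))
  }
  s2_post <- if (is.infinite(d0)) rep(s0_2, length(s2))
             else (d0 * s0_2 + df * s2) / (d0 + df)
  list(d0 = d0, s0_2 = s0_2, s2_post = s2_post, df_post = df + d0)
}
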