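# Running fold-change model: expression-level-dependent thresholds from the
# limit-fold-change curve bp = a + b/AR, followed by a threshold test with a
# gene-specific tau. Lowly expressed genes have noisier fold changes, so with
# b > 0 they receive larger thresholds than highly expressed genes.

#' Per-gene fold changes versus the reference group
#'
#' Computes, for each gene, the fold change between the two groups folded to
#' be >= 1 (the reciprocal is taken when FC < 1) and the average expression
#' AR of the reference group (geometric mean of its normalized counts).
#'
#' @param norm A \code{norm_matrix}.
#' @param reference_group,test_group Group labels; AR is computed on the
#'   reference group.
#' @param genes Optional gene ids (default: endogenous probes).
#' @return Data frame with columns \code{gene}, \code{FC} (>= 1), \code{AR},
#'   \code{M} (signed log2 fold change).
#' @export
fold_changes <- function(norm, reference_group, test_group, genes = NULL) {
  gs <- group_summaries(norm, reference_group, test_group, genes = genes)
  data.frame(gene = gs$gene, FC = 2^abs(gs$M), AR = gs$x1, M = gs$M,
             stringsAsFactors = FALSE)
}

#' Equal-count binning
#'
#' Sorts values and splits them into \code{m} contiguous bins whose sizes
#' differ by at most one; when \code{n} is not a multiple of \code{m} the
#' first bins take the extra elements. Ties keep their input order (stable
#' sort), making the split reproducible.
#'
#' @param x Numeric values to bin (e.g. AR).
#' @param m Number of bins, \code{m <= length(x)}.
#' @return Integer vector of bin indices (1 = lowest values), aligned with
#'   \code{x}.
#' @export
bin_equal_count <- function(x, m) {
  n <- length(x)
  if (m > n) stop("more bins than values")
  if (m < 1L) stop("m must be >= 1")
  sizes <- rep(n %/% m, m)
  extra <- n %% m
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ord <- order(x)  # stable in R
  bins <- integer(n)
  bins[ord] <- rep(seq_len(m), times = sizes)
  bins
}

#' Fit the limit-fold-change curve
#'
#' Step 1 and 2 of the running fold-change model: genes are binned into
#' \code{m} equal-count bins along AR; in each bin the \code{b_pct} percentile
#' of the folded fold changes, \code{bp_j}, and the median AR are recorded;
#' then \code{bp = a + b/AR} is fitted to the bin summaries by least squares.
#' Percentiles use linear interpolation between order statistics.
#'
#' @param fc Per-gene fold changes (>= 1).
#' @param ar Per-gene average expression of the reference group.
#' @param m Number of fitting bins (>= 3, default 10).
#' @param b_pct Percentile per bin (default 70; 55--95 is the advisable range:
#'   low when many DE genes are expected, high when few are).
#' @return Object of class \code{lfc_model} with coefficients \code{a},
#'   \code{b} and the bin summary table.
#' @export
lfc_fit <- function(fc, ar, m = 10, b_pct = 70) {
  if (length(fc) != length(ar)) stop("fc and ar must be aligned")
  if (m < 3L) stop("need at least 3 fitting bins")
  if (b_pct < 55 || b_pct > 95)
    warning("b_pct outside the advisable 55-95 range")
  bins <- bin_equal_count(ar, m)
  ar_med <- tapply(ar, bins, stats::median)
  bp <- tapply(fc, bins, function(v) unname(stats::quantile(v, b_pct / 100)))
  if (max(ar_med) - min(ar_med) <= 0)
    stop("all bins have identical median AR; curve slope is unidentifiable")
  fit <- stats::lm(bp ~ I(1 / ar_med))
  cf <- stats::coef(fit)
  structure(list(a = unname(cf[1L]), b = unname(cf[2L]),
                 bins = data.frame(bin = as.integer(names(ar_med)),
                                   ar_median = as.numeric(ar_med),
                                   bp = as.numeric(bp)),
                 m = m, b_pct = b_pct, fit = fit),
            class = "lfc_model")
}

#' @export
print.lfc_model <- function(x, ...) {
  cat(sprintf("Limit-fold-change curve: bp = %.4g + %.4g/AR  (m = %d bins, P%g)\n",
              x$a, x$b, x$m, x$b_pct))
  invisible(x)
}

#' @export
coef.lfc_model <- function(object, ...) c(a = object$a, b = object$b)

#' Predict the fold-change threshold curve at given expression levels
#'
#' @param object An \code{lfc_model}.
#' @param newdata Numeric AR values (defaults to the fitting-bin medians).
#' @param floor Floor predictions at 1 (thresholds below 1 are meaningless
#'   for folded fold changes); default \code{TRUE}.
#' @param ... Unused.
#' @return Numeric vector of predicted bp/threshold values.
#' @export
predict.lfc_model <- function(object, newdata = NULL, floor = TRUE, ...) {
  if (is.null(newdata)) newdata <- object$bins$ar_median
  out <- object$a + object$b / newdata
  if (floor) out <- pmax(1, out)
  out
}

#' Plot the limit-fold-change curve over the bin summaries
#'
#' @param x An \code{lfc_model}.
#' @param ... Passed to \code{plot}.
#' @export
plot.lfc_model <- function(x, ...) {
  graphics::plot(x$bins$ar_median, x$bins$bp, log = "x",
                 xlab = "median AR (bin)", ylab = sprintf("P%g of FC", x$b_pct),
                 pch = 19, ...)
  arseq <- exp(seq(log(min(x$bins$ar_median)), log(max(x$bins$ar_median)),
                   length.out = 200))
  graphics::lines(arseq, predict(x, arseq))
  invisible(x)
}

#' Expression-level-dependent thresholds from a fitted curve
#'
#' Step 3 of the running fold-change model: the observed AR range is divided
#' into \code{k} application bins with edges evenly spaced in log2(AR); in
#' each bin the curve is evaluated at the bin's median AR and floored at 1,
#' giving the threshold tau_i applied to every gene in that bin. Application
#' bins that receive no genes are dropped (merged into their neighbours by
#' construction of the gene assignment).
#'
#' @param model An \code{lfc_model}.
#' @param ar Per-gene AR values to assign.
#' @param k Number of application bins (default 10).
#' @return List with \code{bins} (data frame: \code{bin}, \code{ar_lo},
#'   \code{ar_hi}, \code{ar_median}, \code{n}, \code{tau}) and \code{tau},
#'   the per-gene threshold vector aligned with \code{ar}.
#' @export
lfc_thresholds <- function(model, ar, k = 10) {
  stopifnot(inherits(model, "lfc_model"))
  if (k < 2L) stop("k must be >= 2")
  lar <- log2(ar)
  edges <- seq(min(lar), max(lar), length.out = k + 1L)
  idx <- findInterval(lar, edges, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > k] <- k
  occupied <- sort(unique(idx))
  if (length(occupied) < k)
    message("running FC model: ", k - length(occupied),
            " empty application bin(s) merged with neighbours")
  tab <- do.call(rbind, lapply(occupied, function(b) {
    sel <- idx == b
    med <- stats::median(ar[sel])
    data.frame(bin = b, ar_lo = 2^edges[b], ar_hi = 2^edges[b + 1L],
               ar_median = med, n = sum(sel),
               tau = max(1, model$a + model$b / med))
  }))
  tau <- tab$tau[match(idx, tab$bin)]
  list(bins = tab, tau = tau)
}

#' Running fold-change model: thresholds plus threshold test
#'
#' The full pipeline: per-gene fold changes against the reference group, the
#' limit-fold-change curve fitted on \code{m} equal-count bins, conversion to
#' \code{k} expression-range thresholds, and a threshold test (tTREAT by
#' default) of each gene at its own bin's tau.
#'
#' @param norm A \code{norm_matrix}.
#' @param reference_group,test_group Group labels (reference = control).
#' @param genes Optional gene ids (default: endogenous probes).
#' @param fits Optional precomputed \code{\link{gene_fits}} for these genes;
#'   computed from \code{norm} when missing.
#' @param m,b_pct,k Curve-fitting and application-bin settings; see
#'   \code{\link{lfc_fit}} and \code{\link{lfc_thresholds}}.
#' @param method Stage-2 test: \code{"ttreat"} (classical, default) or
#'   \code{"treat"} (moderated).
#' @param alpha Significance cut-off for the DE calls.
#' @return Object of class \code{running_fc}: list with the \code{lfc_model},
#'   the threshold table, and \code{test}, an \code{fc_test} with per-gene tau.
#' @export
running_fc <- function(norm, reference_group, test_group, genes = NULL,
                       fits = NULL, m = 10, b_pct = 70, k = 10,
                       method = c("ttreat", "treat"), alpha = 0.01) {
  method <- match.arg(method)
  fcs <- fold_changes(norm, reference_group, test_group, genes = genes)
  model <- lfc_fit(fcs$FC, fcs$AR, m = m, b_pct = b_pct)
  thr <- lfc_thresholds(model, fcs$AR, k = k)
  if (is.null(fits)) {
    design <- two_group_design(norm$groups, control = reference_group)
    fits <- gene_fits(norm, design = design, genes = fcs$gene,
                      moderate = method == "treat")
  }
  fits <- ensure_fits(fits, moderate = method == "treat")
  fits <- fits[match(fcs$gene, fits$gene), ]
  if (anyNA(fits$gene)) stop("fits do not cover all genes")
  if (method == "ttreat") {
    se <- fits$s * sqrt(fits$z)
    tt <- fits$t
    df <- fits$df
  } else {
    se <- sqrt(fits$s2_post * fits$z)
    tt <- fits$M / se
    df <- fits$df_post
  }
  p <- threshold_pvalue(fits$M, se, tt, df, thr$tau)
  test <- new_fc_test(fits, paste0("running_fc/", method), tau = thr$tau,
                      p = p, stage = "n/a", de = p < alpha, alpha = alpha)
  structure(list(model = model, thresholds = thr$bins, tau = thr$tau,
                 test = test),
            class = "running_fc")
}

#' @export
print.running_fc <- function(x, ...) {
  print(x$model)
  cat("  thresholds across", nrow(x$thresholds), "expression ranges:",
      paste(sprintf("%.3g", x$thresholds$tau), collapse = " "), "\n")
  print(x$test)
  invisible(x)
}
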