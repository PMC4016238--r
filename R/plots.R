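# Base-graphics MA / MC / FD-MG plots. Each function draws on the active
# device and invisibly returns the plotted coordinate arrays, so callers can
# regression-test plots by hashing data instead of raster bytes.

# pull gene/M/A/DE out of a gene_fits or fc_test (or plain data frame)
plot_frame <- function(x, de = NULL) {
  if (!all(c("gene", "M") %in% names(x)))
    stop("need a per-gene table with columns gene and M")
  d <- data.frame(gene = x$gene, M = x$M,
                  A = if ("A" %in% names(x)) x$A else NA_real_,
                  stringsAsFactors = FALSE)
  if (is.null(de)) de <- if ("DE" %in% names(x)) x$DE else rep(FALSE, nrow(d))
  if (is.character(de)) de <- d$gene %in% de
  if (length(de) != nrow(d)) stop("DE highlight does not match the gene table")
  d$DE <- de
  d
}

#' MA plot
#'
#' Scatter of per-gene M values (log2 fold change) against A values (average
#' log2 expression). DE genes are drawn as filled squares, other genes as
#' open circles. Optional guide lines: the maximum of the negative controls
#' (vertical), the mean M (horizontal), and +/- log2 of a fold change.
#'
#' @param x An \code{fc_test}, \code{gene_fits}, or data frame with columns
#'   \code{gene}, \code{M}, \code{A} (and optionally \code{DE}).
#' @param de Optional DE highlight: logical vector or character vector of
#'   gene ids; defaults to the \code{DE} column when present.
#' @param fc_line Draw horizontal lines at +/- log2 of this fold change
#'   (e.g. 1.3); \code{NULL} for none.
#' @param neg_max A value at which to draw the vertical negative-control
#'   maximum line (on the A axis, i.e. log2 scale); \code{NULL} for none.
#' @param mean_line Draw the horizontal mean-M line (default \code{TRUE}).
#' @param ... Further arguments to \code{plot}.
#' @return Invisibly, a list with the plotted \code{A}, \code{M} and
#'   \code{DE} arrays.
#' @export
ma_plot <- function(x, de = NULL, fc_line = NULL, neg_max = NULL,
                    mean_line = TRUE, ...) {
  d <- plot_frame(x, de)
  if (anyNA(d$A)) stop("A values are required for an MA plot")
  graphics::plot(d$A, d$M, type = "n", xlab = "A (average log2 expression)",
                 ylab = "M (log2 fold change)", ...)
  graphics::points(d$A[!d$DE], d$M[!d$DE], pch = 1, col = "grey40")
  graphics::points(d$A[d$DE], d$M[d$DE], pch = 15, col = "darkgreen")
  if (mean_line) graphics::abline(h = mean(d$M), col = "red", lty = 3)
  if (!is.null(fc_line))
    graphics::abline(h = c(-1, 1) * log2(fc_line), col = "goldenrod", lty = 3)
  if (!is.null(neg_max)) graphics::abline(v = neg_max, lty = 3)
  invisible(list(A = d$A, M = d$M, DE = d$DE))
}

#' MC plot: M values in chromosomal gene order
#'
#' Plots per-gene M values against the relative order of the genes along the
#' chromosomes (concatenated in annotation order), one color per chromosome.
#' Every plotted gene must be annotated.
#'
#' @param x As in \code{\link{ma_plot}} (A values not required).
#' @param annotation Data frame with columns \code{gene_id},
#'   \code{chromosome}, \code{order_index}.
#' @param de Optional DE highlight, as in \code{\link{ma_plot}}.
#' @param ... Further arguments to \code{plot}.
#' @return Invisibly, a list with the plot order, positions, \code{M},
#'   \code{DE} and chromosome of each gene.
#' @export
mc_plot <- function(x, annotation, de = NULL, ...) {
  d <- plot_frame(x, de)
  need <- c("gene_id", "chromosome", "order_index")
  if (!all(need %in% names(annotation)))
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  idx <- match(d$gene, annotation$gene_id)
  if (anyNA(idx))
    stop("unannotated genes: ", paste(d$gene[is.na(idx)], collapse = ", "))
  d$chromosome <- annotation$chromosome[idx]
  d$order_index <- annotation$order_index[idx]
  chrom_levels <- unique(annotation$chromosome)
  ord <- order(match(d$chromosome, chrom_levels), d$order_index)
  d <- d[ord, ]
  d$pos <- seq_len(nrow(d))
  cols <- grDevices::hcl.colors(max(2L, length(chrom_levels)), "Dark 3")
  ccol <- cols[match(d$chromosome, chrom_levels)]
  graphics::plot(d$pos, d$M, type = "n",
                 xlab = "relative gene order along chromosomes",
                 ylab = "M (log2 fold change)", ...)
  graphics::points(d$pos[!d$DE], d$M[!d$DE], pch = 1, col = ccol[!d$DE])
  graphics::points(d$pos[d$DE], d$M[d$DE], pch = 15, col = ccol[d$DE])
  invisible(list(gene = d$gene, pos = d$pos, M = d$M, DE = d$DE,
                 chromosome = d$chromosome))
}

#' Stacked false-discovery / missed-gene bars
#'
#' The study-figure layout: mean false discoveries upward and mean missed
#' genes downward, one bar pair per method, grouped by percent of DE genes.
#'
#' @param report An \code{eval_summary} or \code{study_report}.
#' @param ... Further arguments to \code{barplot}.
#' @return Invisibly, the matrix of bar heights (FD positive, MG negative).
#' @export
fd_mg_bars <- function(report, ...) {
  stopifnot(all(c("method", "fd_mean", "mg_mean") %in% names(report)))
  lab <- if ("pct_de" %in% names(report))
    paste0(report$method, "\n", report$pct_de, "%") else report$method
  h <- rbind(FD = report$fd_mean, MG = -report$mg_mean)
  colnames(h) <- lab
  graphics::barplot(h, beside = TRUE, col = c("grey30", "grey70"),
                    ylab = "mean missed genes   |   mean false discoveries",
                    las = 2, ...)
  graphics::abline(h = 0)
  invisible(h)
}
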