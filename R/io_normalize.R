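#' Geometric mean of positive values
#'
#' The scaling statistic used by digital-count normalization: positive-control
#' and reference-gene lane factors are ratios of geometric means.
#'
#' @param x Numeric vector, all values strictly positive.
#' @return The geometric mean \code{exp(mean(log(x)))}.
#' @examples
#' geometric_mean(c(2, 8, 32))  # 8
#' @export
geometric_mean <- function(x) {
  if (length(x) == 0L) stop("geometric_mean: empty input")
  if (!is.numeric(x) || anyNA(x)) stop("geometric_mean: input must be numeric without NA")
  if (any(x <= 0)) stop("geometric_mean: all values must be > 0")
  exp(mean(log(x)))
}

probe_classes <- c("Endogenous", "Positive", "Negative", "Housekeeping")

#' Construct a digital count matrix
#'
#' Bundles raw barcode counts (genes x lanes) with the probe-class annotation
#' and lane group labels that drive normalization and testing. Probe classes
#' follow the nCounter convention: \code{Endogenous} (the genes under study),
#' \code{Positive}/\code{Negative} (spike-in controls), and
#' \code{Housekeeping} (reference genes).
#'
#' @param counts Numeric matrix, genes in rows (rownames = gene ids), lanes in
#'   columns (colnames = lane ids). All counts must be non-negative.
#' @param probe_class Character vector, one of \code{Endogenous},
#'   \code{Positive}, \code{Negative}, \code{Housekeeping} per gene.
#' @param groups Character vector of group labels, one per lane.
#' @param cartridge Optional character vector of cartridge ids per lane.
#' @param annotation Optional data frame with columns \code{gene_id},
#'   \code{chromosome}, \code{order_index} for chromosome-ordered plots.
#' @return An object of class \code{count_matrix}.
#' @export
count_matrix <- function(counts, probe_class, groups, cartridge = NULL,
                         annotation = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  if (is.null(colnames(counts))) stop("counts must have lane ids as colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids in counts")
  if (!is.numeric(counts) || anyNA(counts)) stop("counts must be numeric without NA")
  if (any(counts < 0)) stop("negative counts are not allowed")
  probe_class <- as.character(probe_class)
  if (length(probe_class) != nrow(counts))
    stop("probe_class must have one entry per gene")
  bad <- setdiff(unique(probe_class), probe_classes)
  if (length(bad))
    stop("unknown probe class(es): ", paste(bad, collapse = ", "))
  groups <- as.character(groups)
  if (length(groups) != ncol(counts))
    stop("groups must have one label per lane")
  if (is.null(cartridge)) cartridge <- rep(NA_character_, ncol(counts))
  if (!is.null(annotation)) {
    need <- c("gene_id", "chromosome", "order_index")
    if (!all(need %in% names(annotation)))
      stop("annotation needs columns: ", paste(need, collapse = ", "))
  }
  structure(list(counts = counts, probe_class = probe_class,
                 groups = groups, cartridge = as.character(cartridge),
                 annotation = annotation),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("Digital count matrix:", nrow(x$counts), "probes x",
      ncol(x$counts), "lanes\n")
  cat("  probe classes:",
      paste(sprintf("%s=%d", names(table(x$probe_class)),
                    table(x$probe_class)), collapse = ", "), "\n")
  cat("  lane groups:",
      paste(sprintf("%s=%d", names(table(x$groups)), table(x$groups)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count table and samples file
#'
#' Reads a tab- or comma-separated export with columns \code{CodeClass},
#' \code{Name}, then one numeric column per lane, plus a samples table mapping
#' \code{lane_id} to \code{group} (and optionally \code{cartridge}).
#'
#' @param path Path to the counts table (TSV or CSV by extension).
#' @param samples Path to the samples table (columns \code{lane_id},
#'   \code{group}, optional \code{cartridge}), or a data frame.
#' @param annotation Optional path to (or data frame of) a gene annotation
#'   table with columns \code{gene_id}, \code{chromosome}, \code{order_index}.
#' @return A \code{\link{count_matrix}}.
#' @export
read_counts <- function(path, samples, annotation = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("CodeClass", "Name") %in% names(tab)))
    stop("counts file must have CodeClass and Name columns")
  lane_ids <- setdiff(names(tab), c("CodeClass", "Name"))
  if (length(lane_ids) == 0L) stop("counts file has no lane columns")
  counts <- as.matrix(tab[, lane_ids, drop = FALSE])
  if (!is.numeric(counts)) stop("lane columns must be numeric")
  rownames(counts) <- tab$Name
  if (is.character(samples) || inherits(samples, "connection"))
    samples <- utils::read.table(samples, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
  if (!all(c("lane_id", "group") %in% names(samples)))
    stop("samples table needs columns lane_id, group")
  idx <- match(lane_ids, samples$lane_id)
  if (anyNA(idx))
    stop("samples table is missing lanes: ",
         paste(lane_ids[is.na(idx)], collapse = ", "))
  cart <- if ("cartridge" %in% names(samples)) samples$cartridge[idx] else NULL
  if (!is.null(annotation) && is.character(annotation))
    annotation <- utils::read.table(annotation, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE)
  count_matrix(counts, tab$CodeClass, samples$group[idx], cart, annotation)
}

#' Write a count matrix back to the tabular export format
#'
#' Inverse of \code{\link{read_counts}}: emits the counts table and the
#' samples table so that generated fixtures round-trip losslessly.
#'
#' @param x A \code{count_matrix}.
#' @param path Output path for the counts TSV.
#' @param samples_path Output path for the samples TSV.
#' @export
write_counts <- function(x, path, samples_path) {
  stopifnot(inherits(x, "count_matrix"))
  tab <- data.frame(CodeClass = x$probe_class, Name = rownames(x$counts),
                    x$counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  smp <- data.frame(lane_id = colnames(x$counts), group = x$groups,
                    cartridge = x$cartridge, stringsAsFactors = FALSE)
  utils::write.table(smp, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Three-step normalization of digital counts
#'
#' Removes lane-level technical variability in three steps: (1) each lane is
#' scaled by the ratio of the across-lane mean of positive-control geometric
#' means to that lane's positive-control geometric mean; (2) the same
#' construction is applied using a set of reference (housekeeping) genes;
#' (3) a per-lane background, the mean plus twice the standard deviation of
#' that lane's negative-control counts after step 2, is subtracted.
#' Values below 1 are fixed to 1, so that log2 of any normalized count is
#' defined and background maps to 0.
#'
#' @param x A \code{\link{count_matrix}}.
#' @param reference_genes Gene ids to use in step 2. Defaults to all probes of
#'   class \code{Housekeeping}.
#' @return An object of class \code{norm_matrix}: the normalized counts plus
#'   per-lane \code{pos_factor}, \code{ref_factor} and \code{background}.
#' @export
normalize_counts <- function(x, reference_genes = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  pos <- x$probe_class == "Positive"
  neg <- x$probe_class == "Negative"
  if (!any(pos)) stop("no positive-control probes present")
  if (sum(neg) < 2L) stop("need at least 2 negative-control probes for background SD")
  if (is.null(reference_genes))
    reference_genes <- rownames(x$counts)[x$probe_class == "Housekeeping"]
  if (length(reference_genes) == 0L) stop("no reference genes specified or present")
  missing_ref <- setdiff(reference_genes, rownames(x$counts))
  if (length(missing_ref))
    stop("reference genes not in matrix: ", paste(missing_ref, collapse = ", "))

  m <- x$counts
  lane_factor <- function(mat) {
    if (any(mat <= 0))
      stop("zero or negative counts among scaling probes indicate a failed lane")
    gm <- apply(mat, 2L, geometric_mean)
    mean(gm) / gm
  }
  pos_factor <- lane_factor(m[pos, , drop = FALSE])
  m <- sweep(m, 2L, pos_factor, `*`)
  ref_factor <- lane_factor(m[reference_genes, , drop = FALSE])
  m <- sweep(m, 2L, ref_factor, `*`)
  negs <- m[neg, , drop = FALSE]
  background <- apply(negs, 2L, function(v) mean(v) + 2 * stats::sd(v))
  m <- sweep(m, 2L, background, `-`)
  m[m < 1] <- 1

  structure(list(normalized = m, probe_class = x$probe_class,
                 groups = x$groups, cartridge = x$cartridge,
                 annotation = x$annotation,
                 pos_factor = pos_factor, ref_factor = ref_factor,
                 background = background),
            class = "norm_matrix")
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat("Normalized count matrix:", nrow(x$normalized), "probes x",
      ncol(x$normalized), "lanes\n")
  cat("  lane scale factors (positive controls):",
      paste(sprintf("%.3f", x$pos_factor), collapse = " "), "\n")
  cat("  lane backgrounds (mean + 2 SD of negatives):",
      paste(sprintf("%.1f", x$background), collapse = " "), "\n")
  invisible(x)
}

#' Informative-gene filter
#'
#' A gene is informative when the median of its normalized counts over the
#' control lanes is at least \code{threshold} (default 100). Only endogenous
#' probes are considered.
#'
#' @param norm A \code{norm_matrix}.
#' @param control_group Group label of the control lanes.
#' @param threshold Median-count cut-off; the boundary is inclusive.
#' @return Character vector of informative gene ids.
#' @export
informative_genes <- function(norm, control_group, threshold = 100) {
  stopifnot(inherits(norm, "norm_matrix"))
  ctrl <- norm$groups == control_group
  if (!any(ctrl)) stop("no lanes in control group '", control_group, "'")
  endo <- norm$probe_class == "Endogenous"
  med <- apply(norm$normalized[endo, ctrl, drop = FALSE], 1L, stats::median)
  names(med)[med >= threshold]
}

#' Per-gene group summaries: fold change, M and A values
#'
#' For each gene, the geometric means of normalized counts within the two
#' groups, \code{x1} and \code{x2}, give the fold change \code{FC = x2/x1},
#' its log2 \code{M = log2(x2/x1)}, and the average expression
#' \code{A = log2(sqrt(x1*x2))}. Group 1 is the reference (control) group.
#'
#' @param norm A \code{norm_matrix}.
#' @param group1,group2 Group labels: reference group first, test group second.
#' @param genes Optional gene ids to restrict to (default: endogenous probes).
#' @return A data frame with columns \code{gene}, \code{x1}, \code{x2},
#'   \code{M}, \code{A}.
#' @export
group_summaries <- function(norm, group1, group2, genes = NULL) {
  stopifnot(inherits(norm, "norm_matrix"))
  l1 <- norm$groups == group1
  l2 <- norm$groups == group2
  if (!any(l1) || !any(l2)) stop("both groups must contain lanes")
  if (identical(group1, group2)) l2 <- l1  # degenerate self-comparison allowed
  if (is.null(genes)) genes <- rownames(norm$normalized)[norm$probe_class == "Endogenous"]
  m <- norm$normalized[genes, , drop = FALSE]
  x1 <- apply(m[, l1, drop = FALSE], 1L, geometric_mean)
  x2 <- apply(m[, l2, drop = FALSE], 1L, geometric_mean)
  data.frame(gene = genes, x1 = unname(x1), x2 = unname(x2),
             M = unname(log2(x2 / x1)),
             A = unname(log2(sqrt(x1 * x2))),
             stringsAsFactors = FALSE)
}
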