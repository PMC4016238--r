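# Scoring DE calls against simulation truth: false discoveries, missed
# genes, rank-based AUC, and batch summaries with prediction intervals.

#' False discoveries and missed genes
#'
#' Truth positives are group-1 genes; groups 2 and 3 are truth negatives.
#' FD counts truth-negative genes called DE; MG counts truth-positive genes
#' not called.
#'
#' @param de Logical vector of DE calls.
#' @param group Integer truth groups (1 = DE, 2 = noisy non-DE, 3 = regular
#'   non-DE), aligned with \code{de}.
#' @return Named numeric vector \code{c(FD = ..., MG = ...)}.
#' @export
confusion <- function(de, group) {
  if (length(de) != length(group)) stop("de and group must be aligned")
  pos <- group == 1L
  c(FD = sum(de & !pos), MG = sum(pos & !de))
}

#' Rank-based AUC on the percent scale
#'
#' Mann-Whitney AUC with midrank tie handling: the probability that a random
#' truth-positive gene outranks a random truth-negative gene (ties count
#' half), times 100. Scores must be oriented so that larger means more DE;
#' the convention throughout the package is \code{score = 1 - p}.
#'
#' @param scores Per-gene scores (larger = more evidence of DE).
#' @param positive Logical vector of truth positives.
#' @return AUC in [0, 100].
#' @export
auc_score <- function(scores, positive) {
  if (length(scores) != length(positive)) stop("scores and truth must be aligned")
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) stop("need both positive and negative genes")
  r <- rank(scores)  # midranks
  100 * (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Summarize per-replicate performance across a batch
#'
#' Means and empirical 95\% prediction intervals (2.5 and 97.5 percentiles
#' across replicates) of FD, MG and AUC per method, plus signed percent
#' change in FD and MG versus a reference method
#' (\code{100 * (method - reference) / reference}; negative = fewer than the
#' reference).
#'
#' @param per_rep Data frame with columns \code{method}, \code{rep},
#'   \code{FD}, \code{MG}, \code{AUC}.
#' @param reference Name of the reference method (default: first method).
#' @return Data frame of class \code{eval_summary}, one row per method.
#' @export
summarize_batch <- function(per_rep, reference = NULL) {
  need <- c("method", "rep", "FD", "MG", "AUC")
  if (!all(need %in% names(per_rep)))
    stop("per_rep needs columns: ", paste(need, collapse = ", "))
  methods <- unique(per_rep$method)
  if (is.null(reference)) reference <- methods[1L]
  if (!reference %in% methods) stop("reference method not present")
  pi95 <- function(v) stats::quantile(v, c(0.025, 0.975), names = FALSE)
  one <- function(m) {
    d <- per_rep[per_rep$method == m, ]
    if (nrow(d) < 2L) stop("need >= 2 replicates per method")
    fd_pi <- pi95(d$FD); mg_pi <- pi95(d$MG); auc_pi <- pi95(d$AUC)
    data.frame(method = m, n_reps = nrow(d),
               fd_mean = mean(d$FD), fd_lo = fd_pi[1L], fd_hi = fd_pi[2L],
               mg_mean = mean(d$MG), mg_lo = mg_pi[1L], mg_hi = mg_pi[2L],
               auc_mean = mean(d$AUC), auc_lo = auc_pi[1L], auc_hi = auc_pi[2L],
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(methods, one))
  ref <- out[out$method == reference, ]
  pct <- function(v, r) if (r == 0) NA_real_ else 100 * (v - r) / r
  out$pct_change_fd <- vapply(out$fd_mean, pct, numeric(1L), r = ref$fd_mean)
  out$pct_change_mg <- vapply(out$mg_mean, pct, numeric(1L), r = ref$mg_mean)
  attr(out, "reference") <- reference
  class(out) <- c("eval_summary", "data.frame")
  out
}

#' @export
print.eval_summary <- function(x, ...) {
  cat("Batch evaluation over", x$n_reps[1L], "replicates (reference:",
      attr(x, "reference"), ")\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(v) signif(v, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

# apply one method spec to a fits object; spec: list(method=, tau=, theta=,
# alpha=, alpha_stage1=, fc=, label=)
apply_method <- function(fits, spec, alpha) {
  a <- if (!is.null(spec$alpha)) spec$alpha else alpha
  switch(spec$method,
         treat = treat(fits, tau = spec$tau, alpha = a),
         ttreat = ttreat(fits, tau = spec$tau, alpha = a),
         ttreat2 = ttreat2(fits, theta = spec$theta, tau = spec$tau,
                           alpha_stage1 = if (!is.null(spec$alpha_stage1))
                             spec$alpha_stage1 else 0.05,
                           alpha = a),
         combined = combined_criterion(fits, alpha = a, fc = spec$fc),
         stop("unknown method: ", spec$method))
}

method_label <- function(spec) {
  if (!is.null(spec$label)) return(spec$label)
  switch(spec$method,
         ttreat2 = sprintf("ttreat2(%g/%g)", spec$theta, spec$tau),
         combined = sprintf("combined(fc=%g)", spec$fc),
         sprintf("%s(%g)", spec$method, spec$tau))
}

#' Run a simulation study over a grid of scenarios and methods
#'
#' Orchestrates the full evaluation: for each percent of DE genes, a batch of
#' simulated datasets is generated, each method is applied to every
#' realization, per-replicate FD/MG/AUC are recorded (AUC scores are 1 minus
#' the method's p-values), and the batch is summarized against the reference
#' method (the first in \code{methods}).
#'
#' @param methods List of method specifications, each a list with
#'   \code{method} (\code{"treat"}, \code{"ttreat"}, \code{"ttreat2"} or
#'   \code{"combined"}) and its thresholds (\code{tau}, \code{theta},
#'   \code{fc}) and optionally \code{alpha}, \code{alpha_stage1},
#'   \code{label}.
#' @param omega Fold change the data are simulated with respect to.
#' @param pct_de Vector of DE percentages to scan (default \code{c(1, 10, 20)},
#'   the grid reported in the study figures).
#' @param n_reps Replicates per scenario (the full study uses 400).
#' @param alpha Default significance cut-off for methods that do not set
#'   their own.
#' @param base_seed Integer seed; scenario i uses
#'   \code{base_seed + 1000 * (i - 1)} as its batch seed.
#' @param config_args Extra arguments passed to \code{\link{sim_config}}
#'   (e.g. \code{g1}, \code{g2}, \code{df}, \code{z}, \code{v_start}).
#' @return Data frame of class \code{study_report}: one row per
#'   (pct_de, method) with the \code{\link{summarize_batch}} columns.
#' @export
run_study <- function(methods, omega = 1.5, pct_de = c(1, 10, 20),
                      n_reps = 400, alpha = 0.05, base_seed = 1L,
                      config_args = list()) {
  needs_mod <- any(vapply(methods, function(m) m$method == "treat", logical(1L)))
  res <- vector("list", length(pct_de))
  for (i in seq_along(pct_de)) {
    cfg <- do.call(sim_config,
                   c(list(omega = omega, pct_de = pct_de[i]), config_args))
    batch <- simulate_batch(cfg, n_reps = n_reps,
                            base_seed = base_seed + 1000L * (i - 1L))
    per_rep <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
      sim <- batch[[r]]
      fits <- as_gene_fits(as.data.frame(sim), moderate = needs_mod)
      rows <- lapply(methods, function(spec) {
        tst <- apply_method(fits, spec, alpha)
        cm <- confusion(tst$DE, sim$group)
        data.frame(method = method_label(spec), rep = r,
                   FD = cm[["FD"]], MG = cm[["MG"]],
                   AUC = auc_score(1 - tst$p, sim$group == 1L),
                   stringsAsFactors = FALSE)
      })
      per_rep[[r]] <- do.call(rbind, rows)
    }
    summ <- summarize_batch(do.call(rbind, per_rep))
    summ <- data.frame(omega = omega, pct_de = pct_de[i],
                       as.data.frame(summ), stringsAsFactors = FALSE)
    res[[i]] <- summ
  }
  out <- do.call(rbind, res)
  attr(out, "reference") <- method_label(methods[[1L]])
  class(out) <- c("study_report", "eval_summary", "data.frame")
  out
}
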