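# Fixture builders shared across the test files. Everything is generated in
# code at test time; no data files.

# random per-gene sufficient-statistics table (the gene-wise model summary)
make_fit_table <- function(n, seed = 1L, df = 10L, z = 1 / 3,
                           m_sd = 1, sigma = 0.5) {
  set.seed(seed)
  s2 <- sigma^2 * rchisq(n, df) / df
  data.frame(gene = sprintf("g%04d", seq_len(n)),
             M = rnorm(n, 0, m_sd),
             A = runif(n, 5, 12),
             s = sqrt(s2), z = z, df = df,
             stringsAsFactors = FALSE)
}

# minimal hand-built count matrix: 2 positives, 3 negatives, 2 housekeeping,
# a few endogenous genes, with every lane identical unless tweaked by the
# caller. Lanes: 2 control + 2 mutant.
make_hand_counts <- function(endo = rbind(GENE_A = c(200, 200, 400, 400),
                                          GENE_B = c(50, 50, 50, 50),
                                          GENE_C = c(1000, 1000, 250, 250)),
                             negatives = c(10, 20, 30)) {
  n_lanes <- ncol(endo)
  pos <- matrix(rep(c(500, 2000), n_lanes), nrow = 2,
                dimnames = list(c("POS_1", "POS_2"), NULL))
  neg <- matrix(rep(negatives, n_lanes), nrow = length(negatives),
                dimnames = list(paste0("NEG_", seq_along(negatives)), NULL))
  hk <- matrix(rep(c(800, 1200), n_lanes), nrow = 2,
               dimnames = list(c("HK_1", "HK_2"), NULL))
  counts <- rbind(pos, neg, hk, endo)
  colnames(counts) <- paste0("lane", seq_len(n_lanes))
  count_matrix(counts,
               probe_class = rep(c("Positive", "Negative", "Housekeeping",
                                   "Endogenous"),
                                 times = c(2, length(negatives), 2, nrow(endo))),
               groups = rep(c("control", "mutant"), each = n_lanes / 2))
}
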