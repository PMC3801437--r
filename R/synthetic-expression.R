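#' Configuration for the synthetic expression simulator
#'
#' The simulator emulates the duplicate bead-array design of the emulated
#' study: four conditions (`control`, `ifnb`, `yf`, `ifng`) measured in
#' `replicate_count` replicates each, with planted induced gene sets mirroring
#' the IFN-beta / U-ISGF3 / IFN-gamma membership structure:
#' `ifnb_only` genes respond to IFN-beta alone, `u_isgf3` genes to IFN-beta
#' and to Y701F-STAT1 upregulation, `ifng_overlap` genes to IFN-beta and
#' IFN-gamma. Intensities are log-normal: a per-gene baseline drawn on the
#' log2 scale, multiplied by the planted fold where applicable, with additive
#' Gaussian noise on log2 (multiplicative on the linear scale) per sample.
#'
#' @param n_genes total genes.
#' @param set_sizes named counts for the planted memberships
#'   (`ifnb_only`, `u_isgf3`, `ifng_overlap`); their sum must not exceed
#'   `n_genes`.
#' @param baseline_log2_mean,baseline_log2_sd log2-scale baseline intensity
#'   distribution.
#' @param induced_fold_range fold-change interval (lower bound > 1); each
#'   planted gene-condition fold is drawn log2-uniformly from it.
#' @param replicate_count replicates per condition (>= 2).
#' @param noise_sd_log2 per-sample log2 noise standard deviation.
#' @param seed integer RNG seed.
#' @return a `expression_sim_config` list.
#' @export
expression_sim_config <- function(n_genes = 1000,
                                  set_sizes = c(ifnb_only = 100, u_isgf3 = 20,
                                                ifng_overlap = 40),
                                  baseline_log2_mean = 7, baseline_log2_sd = 1.5,
                                  induced_fold_range = c(4, 16),
                                  replicate_count = 2, noise_sd_log2 = 0.2,
                                  seed = 1) {
  need <- c("ifnb_only", "u_isgf3", "ifng_overlap")
  if (!all(need %in% names(set_sizes))) stop("set_sizes needs: ", paste(need, collapse = ", "))
  if (sum(set_sizes[need]) > n_genes) stop("planted set sizes exceed n_genes")
  if (length(induced_fold_range) != 2L || induced_fold_range[1] <= 1 ||
      diff(induced_fold_range) < 0) stop("induced_fold_range must be an interval with lower bound > 1")
  if (replicate_count < 2L) stop("replicate_count must be >= 2")
  if (noise_sd_log2 < 0) stop("noise_sd_log2 must be >= 0")
  structure(list(n_genes = as.integer(n_genes), set_sizes = set_sizes[need],
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 induced_fold_range = induced_fold_range,
                 replicate_count = as.integer(replicate_count),
                 noise_sd_log2 = noise_sd_log2, seed = as.integer(seed)),
            class = "expression_sim_config")
}

#' Simulate an expression matrix with planted induced gene sets
#'
#' @param config an [expression_sim_config()].
#' @return list with `matrix` (an [expr_matrix()]) and `truth`, where `truth`
#'   carries `sets` (character vectors `ifnb_induced`, `u_isgf3`,
#'   `ifng_induced` — the unions implied by the planted memberships) and
#'   `genes`, a per-gene table of planted folds per condition. Identical
#'   seeds give identical output.
#' @export
simulate_expression <- function(config = expression_sim_config()) {
  stopifnot(inherits(config, "expression_sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  gene_ids <- sprintf("gene%04d", seq_len(n))
  sz <- config$set_sizes
  idx <- seq_len(sum(sz))
  ifnb_only <- gene_ids[idx[seq_len(sz[1])]]
  u_isgf3 <- gene_ids[idx[sz[1] + seq_len(sz[2])]]
  ifng_ov <- gene_ids[idx[sz[1] + sz[2] + seq_len(sz[3])]]

  conds <- c("control", "ifnb", "yf", "ifng")
  reps <- config$replicate_count
  samples <- data.frame(
    sample = paste0(rep(conds, each = reps), "_r", rep(seq_len(reps), length(conds))),
    condition = rep(conds, each = reps),
    replicate = rep(seq_len(reps), length(conds)))

  baseline <- 2^stats::rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)
  lfr <- log2(config$induced_fold_range)
  draw_fold <- function(members) {
    f <- rep(1, n)
    i <- match(members, gene_ids)
    f[i] <- 2^stats::runif(length(i), lfr[1], lfr[2])
    f
  }
  fold <- cbind(control = rep(1, n),
                ifnb = draw_fold(c(ifnb_only, u_isgf3, ifng_ov)),
                yf = draw_fold(u_isgf3),
                ifng = draw_fold(ifng_ov))

  values <- matrix(0, n, nrow(samples), dimnames = list(gene_ids, samples$sample))
  for (j in seq_len(nrow(samples))) {
    mu <- baseline * fold[, samples$condition[j]]
    eps <- if (config$noise_sd_log2 > 0) {
      2^stats::rnorm(n, 0, config$noise_sd_log2)
    } else rep(1, n)
    values[, j] <- mu * eps
  }

  truth <- list(
    sets = list(ifnb_induced = c(ifnb_only, u_isgf3, ifng_ov),
                u_isgf3 = u_isgf3, ifng_induced = ifng_ov),
    genes = data.frame(gene_id = gene_ids, baseline = baseline,
                       fold_ifnb = fold[, "ifnb"], fold_yf = fold[, "yf"],
                       fold_ifng = fold[, "ifng"], row.names = NULL))
  list(matrix = expr_matrix(values, samples), truth = truth)
}
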