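# sites: character vector of equal-length ACGT sequences -> n x 4L one-hot matrix
.site_onehot <- function(sites) {
  L <- unique(nchar(sites))
  if (length(L) != 1L) stop("aligned sites must all have equal length")
  n <- length(sites)
  X <- matrix(0L, n, 4L * L)
  for (i in seq_len(n)) {
    v <- seq_to_int(sites[i])
    if (anyNA(v)) stop("aligned sites must be over {A,C,G,T}")
    X[i, 4L * (seq_len(L) - 1L) + v] <- 1L
  }
  X
}

# one-hot rows -> 4 x L count matrix
.onehot_counts <- function(X, rows) {
  matrix(colSums(X[rows, , drop = FALSE]), nrow = 4L)
}

.counts_to_prob <- function(counts, n, pseudocount) {
  (counts + pseudocount) / (n + 4 * pseudocount)
}

#' Build a position frequency matrix from aligned binding sites
#'
#' `p_i(b) = (count_i(b) + pseudocount) / (n + 4 * pseudocount)`; every
#' column sums to 1. The default half-count pseudocount keeps all
#' probabilities strictly positive, guaranteeing finite Kullback-Leibler
#' divergences downstream.
#'
#' @param sites character vector of equal-length sequences over \{A,C,G,T\},
#'   or a `motif_sites` data.frame (its unclipped `site_seq` column is used).
#' @param pseudocount non-negative, default 0.5.
#' @return a probability-form [position_matrix()] with attribute `n_sites`.
#' @export
build_pfm <- function(sites, pseudocount = 0.5) {
  if (inherits(sites, "motif_sites")) sites <- sites$site_seq[!sites$clipped]
  if (!length(sites)) stop("empty site alignment")
  X <- .site_onehot(sites)
  counts <- .onehot_counts(X, seq_len(nrow(X)))
  pm <- position_matrix(.counts_to_prob(counts, length(sites), pseudocount),
                        kind = "probability")
  attr(pm, "n_sites") <- length(sites)
  pm
}

#' Per-position information content (sequence-logo column heights)
#'
#' `IC_i = 2 + sum_b p_i(b) log2 p_i(b) - e(n)`, in bits under a uniform
#' background, with the small-sample correction `e(n) = 3 / (2 ln(2) n)`
#' (the standard logo correction; on by default) and clipping below at 0.
#'
#' @param pfm probability-form [position_matrix()].
#' @param n_sites number of sequences the PFM was estimated from; defaults to
#'   the matrix's `n_sites` attribute. Required (> 0) when the correction is
#'   on.
#' @param small_sample_correction logical, default `TRUE`.
#' @return numeric vector of per-position bits in \[0, 2\].
#' @export
information_content <- function(pfm, n_sites = attr(pfm, "n_sites"),
                                small_sample_correction = TRUE) {
  stopifnot(inherits(pfm, "position_matrix"), pfm$kind == "probability")
  e_n <- 0
  if (small_sample_correction) {
    if (is.null(n_sites) || n_sites <= 0) stop("n_sites must be positive when the correction is on")
    e_n <- 3 / (2 * log(2) * n_sites)
  }
  p <- pfm$mat
  plogp <- ifelse(p > 0, p * log2(p), 0)
  pmax(2 + colSums(plogp) - e_n, 0)
}

#' Symmetrized position-averaged Kullback-Leibler divergence profile
#'
#' Per position, the arithmetic mean of the two directed divergences
#' (Jeffreys-type symmetrization):
#' `D_i = 1/2 [ sum_b p log2(p/q) + sum_b q log2(q/p) ]`, in bits; `mean_d`
#' averages `D_i` over positions. Zero if and only if the matrices are equal;
#' symmetric in its arguments.
#'
#' @param pfm_a,pfm_b probability-form [position_matrix()] objects of equal
#'   length with strictly positive entries (enforce via pseudocount upstream).
#' @return list of class `divergence_result`: `per_position_d` (bits) and
#'   `mean_d`.
#' @export
kl_divergence_profile <- function(pfm_a, pfm_b) {
  stopifnot(inherits(pfm_a, "position_matrix"), inherits(pfm_b, "position_matrix"))
  if (ncol(pfm_a$mat) != ncol(pfm_b$mat)) stop("position matrices differ in length")
  .kl_profile_mat(pfm_a$mat, pfm_b$mat)
}

.kl_profile_mat <- function(p, q) {
  if (any(p <= 0) || any(q <= 0)) {
    stop("zero probabilities make KL infinite; raise the pseudocount")
  }
  lr <- log2(p / q)
  d <- 0.5 * (colSums(p * lr) + colSums(-q * lr))
  d <- pmax(d, 0)  # guard tiny negative rounding
  structure(list(per_position_d = d, mean_d = mean(d)), class = "divergence_result")
}

#' Label-permutation test for motif divergence between two site groups
#'
#' The observed statistic is the symmetrized position-averaged KL divergence
#' between the two groups' PFMs (each built with `pseudocount`). Under the
#' null the group labels are exchangeable: for each permutation the pooled
#' sites are relabelled preserving group sizes, PFMs are rebuilt and the mean
#' divergence recomputed. `p = (1 + #\{perm >= observed\}) / (n_perm + 1)`.
#'
#' @param sites_a,sites_b character vectors of aligned sites (>= 2 each,
#'   one common length), or `motif_sites` data.frames.
#' @param n_perm number of permutations (default 999; must be >= 19).
#' @param pseudocount PFM pseudocount (default 0.5).
#' @param seed integer seed; fixed seed gives a deterministic result.
#' @return list of class `divergence_result`: `per_position_d`, `mean_d`,
#'   `n_perm`, `perm_null` (mean, sd, quantiles), `p_value`, `seed`.
#' @export
divergence_permutation_test <- function(sites_a, sites_b, n_perm = 999,
                                        pseudocount = 0.5, seed = 1) {
  if (inherits(sites_a, "motif_sites")) sites_a <- sites_a$site_seq[!sites_a$clipped]
  if (inherits(sites_b, "motif_sites")) sites_b <- sites_b$site_seq[!sites_b$clipped]
  if (length(sites_a) < 2L || length(sites_b) < 2L) {
    stop("each group needs at least 2 sites")
  }
  if (n_perm < 19) stop("n_perm must be >= 19 for any useful p-value resolution")
  na <- length(sites_a); nb <- length(sites_b)
  X <- .site_onehot(c(sites_a, sites_b))
  obs <- .perm_stat(X, seq_len(na), na, nb, pseudocount)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(b) {
    ia <- sample.int(na + nb, na)
    .perm_stat(X, ia, na, nb, pseudocount)$mean_d
  }, numeric(1))
  p <- (1 + sum(perm >= obs$mean_d)) / (n_perm + 1)
  structure(list(per_position_d = obs$per_position_d, mean_d = obs$mean_d,
                 n_perm = n_perm,
                 perm_null = c(mean = mean(perm), sd = stats::sd(perm),
                               stats::quantile(perm, c(0.5, 0.95, 0.99))),
                 p_value = p, seed = seed),
            class = "divergence_result")
}

.perm_stat <- function(X, rows_a, na, nb, pseudocount) {
  ca <- .onehot_counts(X, rows_a)
  cb <- matrix(colSums(X), nrow = 4L) - ca
  .kl_profile_mat(.counts_to_prob(ca, na, pseudocount),
                  .counts_to_prob(cb, nb, pseudocount))
}

#' @export
print.divergence_result <- function(x, ...) {
  cat(sprintf("symmetrized position-averaged KL: mean_d = %.4f bits over %d positions\n",
              x$mean_d, length(x$per_position_d)))
  if (!is.null(x$p_value)) {
    cat(sprintf("  permutation p = %.4g (%d label permutations, null mean %.4f)\n",
                x$p_value, x$n_perm, x$perm_null[["mean"]]))
  }
  invisible(x)
}

#' K-means clustering of one-hot-encoded binding sites
#'
#' Sites are encoded as 4L-dimensional one-hot vectors and clustered with
#' Lloyd's algorithm (best of `n_restarts` random starts by within-cluster
#' sum of squares) for each requested `k`. Average silhouette width (squared
#' Euclidean distance space) and, when group labels are supplied, cluster
#' purity against those labels are reported; the recommended `k` is the
#' silhouette argmax.
#'
#' @param sites character vector of aligned sites or a `motif_sites`
#'   data.frame.
#' @param groups optional character/factor of group labels, one per site.
#' @param k_values cluster counts to fit (default `2:6`; values above the
#'   site count are dropped).
#' @param n_restarts random restarts per `k` (default 20).
#' @param seed integer seed; fixed seed and restarts give deterministic
#'   assignments.
#' @return list of class `cluster_result_set`: per-`k` results (each with
#'   `k`, `assignments`, `centroids` as a 4-row base-frequency matrix list,
#'   `within_ss`, `silhouette`, `purity`), plus `recommended_k`.
#' @export
kmeans_site_clustering <- function(sites, groups = NULL, k_values = 2:6,
                                   n_restarts = 20, seed = 1) {
  if (inherits(sites, "motif_sites")) {
    if (is.null(groups) && !is.null(sites$group)) groups <- sites$group[!sites$clipped]
    sites <- sites$site_seq[!sites$clipped]
  }
  X <- .site_onehot(sites)
  n <- nrow(X)
  k_values <- k_values[k_values <= n & k_values >= 1]
  if (!length(k_values)) stop("no feasible k: more clusters than sites")
  D <- stats::dist(X)
  set.seed(seed)
  # duplicate one-hot rows would make random initial centers coincide; a tiny
  # deterministic jitter keeps Lloyd's starts distinct without moving any
  # reported quantity beyond ~1e-9
  if (anyDuplicated(X)) X <- X + matrix(stats::runif(length(X)), nrow(X)) * 1e-6
  fits <- lapply(k_values, function(k) {
    km <- stats::kmeans(X, centers = k, iter.max = 300, nstart = n_restarts,
                        algorithm = "Lloyd")
    sil <- if (k >= 2 && k < n) {
      mean(cluster::silhouette(km$cluster, D)[, "sil_width"])
    } else NA_real_
    purity <- if (!is.null(groups)) {
      sum(apply(table(km$cluster, groups), 1, max)) / n
    } else NA_real_
    list(k = k, assignments = km$cluster, centroids = km$centers,
         within_ss = km$tot.withinss, silhouette = sil, purity = purity)
  })
  names(fits) <- paste0("k", k_values)
  sils <- vapply(fits, `[[`, numeric(1), "silhouette")
  rec <- if (all(is.na(sils))) k_values[1] else k_values[which.max(sils)]
  structure(list(fits = fits, recommended_k = rec, seed = seed),
            class = "cluster_result_set")
}

#' Export a sequence-logo table
#'
#' Per position: information content and per-base letter heights
#' `height(b, i) = p_i(b) * IC_i`, so each column's heights sum to its IC.
#'
#' @param pfm probability-form [position_matrix()].
#' @param ic per-position information content; computed via
#'   [information_content()] when omitted.
#' @param ... passed to [information_content()] when `ic` is omitted.
#' @return data.frame: `position`, `ic`, and height columns `A`, `C`, `G`,
#'   `T`.
#' @export
logo_matrix_export <- function(pfm, ic = NULL, ...) {
  stopifnot(inherits(pfm, "position_matrix"), pfm$kind == "probability")
  if (is.null(ic)) ic <- information_content(pfm, ...)
  if (length(ic) != ncol(pfm$mat)) stop("ic length must match matrix length")
  h <- sweep(pfm$mat, 2, ic, "*")
  data.frame(position = seq_len(ncol(h)), ic = ic, A = h["A", ], C = h["C", ],
             G = h["G", ], T = h["T", ], row.names = NULL)
}
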