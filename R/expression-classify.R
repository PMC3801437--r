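#' Expression matrix container
#'
#' Thin container pairing a genes-by-samples intensity matrix (linear scale)
#' with its sample sheet. Bead-array style data: a small number of conditions,
#' each measured in replicate (duplicates in the emulated design).
#'
#' @param values numeric matrix, genes in rows (row names are gene ids),
#'   samples in columns; non-negative, linear scale.
#' @param samples data.frame with columns `sample`, `condition`, `replicate`;
#'   one row per matrix column, in column order.
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, samples) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must carry gene ids as row names")
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (any(!is.finite(values))) stop("non-finite intensities")
  if (any(values < 0)) stop("negative intensities")
  samples <- as.data.frame(samples)
  need <- c("sample", "condition", "replicate")
  if (!all(need %in% names(samples))) stop("samples needs columns: sample, condition, replicate")
  if (nrow(samples) != ncol(values)) stop("sample sheet rows must match matrix columns")
  colnames(values) <- samples$sample
  structure(list(values = values, samples = samples), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$samples$condition), collapse = ", ")))
  invisible(x)
}

#' Read / write an expression matrix as TSV plus sample sheet
#'
#' The matrix TSV has gene ids in the first column and one column per sample;
#' the sample sheet TSV has columns `sample`, `condition`, `replicate`.
#'
#' @param matrix_path,samples_path file paths.
#' @return [read_expr_matrix()]: an `expr_matrix`.
#' @export
read_expr_matrix <- function(matrix_path, samples_path) {
  tab <- utils::read.delim(matrix_path, check.names = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- as.character(tab[[1]])
  samples <- utils::read.delim(samples_path)
  expr_matrix(values[, samples$sample, drop = FALSE], samples)
}

#' @rdname read_expr_matrix
#' @param em an `expr_matrix`.
#' @export
write_expr_matrix <- function(em, matrix_path, samples_path) {
  stopifnot(inherits(em, "expr_matrix"))
  out <- data.frame(gene_id = rownames(em$values), em$values, check.names = FALSE)
  utils::write.table(out, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(em$samples, samples_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(matrix_path)
}

#' Quantile normalization
#'
#' Forces every column to share one empirical distribution: each column's
#' rank-r value is replaced by the mean of all columns' rank-r values. After
#' normalization the sorted value vector is identical across columns; within
#' a column, ties in the input are broken by original order, so each column
#' is an exact permutation of the common vector.
#'
#' @param x an `expr_matrix` or bare numeric matrix.
#' @return same type as the input, normalized; row and column labels kept.
#' @export
quantile_normalize <- function(x) {
  m <- if (inherits(x, "expr_matrix")) x$values else as.matrix(x)
  if (ncol(m) < 1L) stop("need at least one column")
  if (any(!is.finite(m))) stop("non-finite values")
  ord <- apply(m, 2, order)                       # ties broken by row order
  sorted <- vapply(seq_len(ncol(m)), function(j) m[ord[, j], j], numeric(nrow(m)))
  means <- rowMeans(sorted)
  out <- m
  for (j in seq_len(ncol(m))) out[ord[, j], j] <- means
  if (inherits(x, "expr_matrix")) { x$values <- out; x } else out
}

# vectorized two-sample t-tests on the rows of two matrices (log2 scale)
.row_ttest <- function(a, b, pooled = TRUE) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  if (pooled) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(ma))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (ma - mb) / se
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  # zero-variance, zero-difference rows give 0/0: no evidence of change
  p[is.nan(p) & abs(ma - mb) < 1e-12] <- 1
  p
}

#' Score per-gene induction under the bead-array filter criteria
#'
#' A gene is called induced when all three gates pass: differential p-value
#' `<= p_max` (inclusive), treated average signal `> signal_min` (strict), and
#' fold change `> fold_min` (strict). Replicates are reduced by their mean on
#' the linear scale ("the mean of the duplicates"); fold change is the ratio
#' of linear-scale means; the differential test runs on `log2(value + 1)`.
#'
#' @param em a (normalized) `expr_matrix`.
#' @param treated,control condition labels present in the sample sheet.
#' @param fold_min,p_max,signal_min filter thresholds (defaults 2, 0.05, 25).
#' @param test `"pooled_t"` (two-sample pooled-variance t, the default),
#'   `"welch"`, or `"moderated"` (limma empirical-Bayes moderated t).
#' @return data.frame of class `induction_calls`: `gene_id`, `treated_mean`,
#'   `control_mean`, `fold_change`, `diff_p`, `induced`. Genes whose control
#'   mean is zero have `fold_change = NA` and `induced = NA` (excluded with a
#'   warning).
#' @export
score_induction <- function(em, treated, control, fold_min = 2, p_max = 0.05,
                            signal_min = 25,
                            test = c("pooled_t", "welch", "moderated")) {
  stopifnot(inherits(em, "expr_matrix"))
  test <- match.arg(test)
  cond <- em$samples$condition
  for (cc in c(treated, control)) {
    if (sum(cond == cc) < 2L) stop("condition '", cc, "' absent or has < 2 replicates")
  }
  A <- em$values[, cond == treated, drop = FALSE]
  B <- em$values[, cond == control, drop = FALSE]
  la <- log2(A + 1); lb <- log2(B + 1)
  p <- switch(test,
    pooled_t = .row_ttest(la, lb, pooled = TRUE),
    welch    = .row_ttest(la, lb, pooled = FALSE),
    moderated = {
      y <- cbind(la, lb)
      design <- cbind(1, c(rep(1, ncol(la)), rep(0, ncol(lb))))
      fit <- limma::eBayes(limma::lmFit(y, design))
      fit$p.value[, 2]
    })
  tm <- rowMeans(A); cm <- rowMeans(B)
  fc <- ifelse(cm > 0, tm / cm, NA_real_)
  if (anyNA(fc)) {
    warning(sum(is.na(fc)), " gene(s) with zero control mean: fold undefined, excluded")
  }
  induced <- (p <= p_max) & (tm > signal_min) & (fc > fold_min)
  out <- data.frame(gene_id = rownames(em$values), treated_mean = tm,
                    control_mean = cm, fold_change = fc, diff_p = p,
                    induced = induced, row.names = NULL)
  class(out) <- c("induction_calls", "data.frame")
  out
}

#' Gene-set algebra defining the U-ISGF3 and ISGF3-only groups
#'
#' Given the IFN-beta-induced set, the set induced by unphosphorylated
#' Y701F-STAT1 upregulation, and the IFN-gamma-induced set, computes
#' `u_isgf3 = ifnb` \eqn{\cap} `yf` and
#' `isgf3_only = ifnb - u_isgf3 - ifng` (the genes induced only by classical
#' ISGF3), together with a count summary including the intermediate
#' "remaining after U-ISGF3 removal" set and its IFN-gamma overlap.
#'
#' @param ifnb,yf,ifng character vectors of gene ids over a common id space.
#' @return object of class `gene_set_partition` with elements `ifnb_induced`,
#'   `u_isgf3`, `ifng_induced`, `isgf3_only` and a named integer `counts`
#'   (`ifnb_induced`, `u_isgf3`, `remaining`, `ifng_overlap`, `isgf3_only`).
#' @export
partition_isgs <- function(ifnb, yf, ifng) {
  ifnb <- unique(as.character(ifnb))
  yf <- unique(as.character(yf))
  ifng <- unique(as.character(ifng))
  u_isgf3 <- intersect(ifnb, yf)
  remaining <- setdiff(ifnb, u_isgf3)
  ifng_overlap <- intersect(remaining, ifng)
  isgf3_only <- setdiff(remaining, ifng)
  structure(list(
    ifnb_induced = ifnb, u_isgf3 = u_isgf3, ifng_induced = ifng,
    isgf3_only = isgf3_only,
    counts = c(ifnb_induced = length(ifnb), u_isgf3 = length(u_isgf3),
               remaining = length(remaining), ifng_overlap = length(ifng_overlap),
               isgf3_only = length(isgf3_only))),
    class = "gene_set_partition")
}

#' @export
print.gene_set_partition <- function(x, ...) {
  cat("gene_set_partition:\n")
  print(x$counts)
  invisible(x)
}
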