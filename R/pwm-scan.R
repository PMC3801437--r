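# log2 likelihood-ratio score matrix (4 x L, bits) for a PWM against a background
.llr_matrix <- function(pwm, background, pseudocount = 0.01) {
  if (pwm$kind != "probability") pwm <- pm_probability(pwm, pseudocount)
  # zero probabilities are legal here: impossible bases score -Inf
  log2(pwm$mat / background)
}

# forward-strand placement scores for one integer-encoded sequence;
# placements overlapping N (NA) come back NA
.scan_one <- function(x, S) {
  W <- length(x); L <- ncol(S); n <- W - L + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  for (j in seq_len(L)) s <- s + S[x[j:(j + n - 1L)] + 4L * (j - 1L)]
  s
}

.resolve_background <- function(background, windows, pwm) {
  if (is.null(background)) return(pwm$background)
  if (is.character(background)) {
    return(switch(match.arg(background, c("windows", "uniform")),
                  windows = sequence_composition(windows),
                  uniform = stats::setNames(rep(0.25, 4), .BASES)))
  }
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  stats::setNames(as.numeric(background), .BASES)
}

#' Scan sequences for motif occurrences with log-likelihood-ratio scores
#'
#' Every placement of the PWM on every sequence (both strands by default) is
#' scored as \eqn{\sum_i \log_2 (p_i(b_i) / q(b_i))} in bits, where
#' \eqn{p_i} are the motif probabilities and \eqn{q} the background.
#' Placements overlapping `N` are skipped. Hits at or above `threshold` are
#' returned sorted by score (descending), then offset (ascending), then
#' strand (`+` first), within each sequence.
#'
#' @param windows sequences to scan: a character vector, `DNAStringSet`, or
#'   [extract_promoter_windows()] result.
#' @param pwm a [position_matrix()]; count matrices are converted with
#'   `pseudocount`.
#' @param threshold minimum score in bits (default `-Inf`: all placements).
#' @param both_strands scan the reverse strand too (default `TRUE`). Minus-
#'   strand offsets refer to the hit's leftmost base on the forward sequence.
#' @param background `NULL` (use the PWM's stored background), `"windows"`
#'   (composition of the scanned set), `"uniform"`, or a numeric 4-vector.
#' @param pseudocount used when converting a count PWM (default 0.01).
#' @return data.frame: `gene_id`, `offset` (0-based), `strand`, `score`
#'   (bits), `core_seq` (match read in motif orientation). Sequences shorter
#'   than the motif yield no rows, with a warning.
#' @export
scan_pwm <- function(windows, pwm, threshold = -Inf, both_strands = TRUE,
                     background = NULL, pseudocount = 0.01) {
  seqs <- .as_seq_chr(windows)
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%03d", seq_along(seqs))
  bg <- .resolve_background(background, windows, pwm)
  S <- .llr_matrix(pwm, bg, pseudocount)
  L <- ncol(S)
  Srev <- S[4:1, L:1, drop = FALSE]
  out <- vector("list", length(seqs))
  for (k in seq_along(seqs)) {
    x <- seq_to_int(seqs[[k]])
    if (length(x) < L) {
      warning("sequence '", names(seqs)[k], "' shorter than the motif; skipped")
      next
    }
    fwd <- .scan_one(x, S)
    io <- which(!is.na(fwd) & fwd >= threshold)
    hits <- data.frame(offset = io - 1L, strand = rep("+", length(io)),
                       score = fwd[io])
    if (both_strands) {
      rev_ <- .scan_one(x, Srev)
      ir <- which(!is.na(rev_) & rev_ >= threshold)
      hits <- rbind(hits, data.frame(offset = ir - 1L,
                                     strand = rep("-", length(ir)),
                                     score = rev_[ir]))
    }
    if (!nrow(hits)) next
    hits <- hits[order(-hits$score, hits$offset, hits$strand), , drop = FALSE]
    core <- substr(rep(seqs[[k]], nrow(hits)), hits$offset + 1L, hits$offset + L)
    core[hits$strand == "-"] <- revcomp_chr(core[hits$strand == "-"])
    out[[k]] <- data.frame(gene_id = names(seqs)[k], offset = hits$offset,
                           strand = hits$strand, score = hits$score,
                           core_seq = core, row.names = NULL)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(gene_id = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0),
                      core_seq = character(0))
  }
  res
}

#' CLOVER-style motif over-representation score for a sequence set
#'
#' Per sequence, the arithmetic mean over all valid placements (both strands
#' by default) of the likelihood ratio \eqn{\prod_i p_i(b_i)/q(b_i)}; the set
#' score is the mean over sequences of the natural log of the per-sequence
#' mean. A PWM identical to the background gives a set score of 0. Placements
#' overlapping `N` are excluded from the average.
#'
#' @inheritParams scan_pwm
#' @param background default `"windows"`: composition of the analyzed set.
#' @return the set score (dimensionless).
#' @export
clover_set_score <- function(windows, pwm, both_strands = TRUE,
                             background = "windows", pseudocount = 0.01) {
  seqs <- .as_seq_chr(windows)
  if (!length(seqs)) stop("empty window set")
  bg <- .resolve_background(background, windows, pwm)
  S <- .llr_matrix(pwm, bg, pseudocount)
  L <- ncol(S)
  Srev <- S[4:1, L:1, drop = FALSE]
  per_seq <- vapply(seqs, function(s) {
    x <- seq_to_int(s)
    if (length(x) < L) stop("window shorter than the motif")
    sc <- .scan_one(x, S)
    if (both_strands) sc <- c(sc, .scan_one(x, Srev))
    sc <- sc[!is.na(sc)]
    if (!length(sc)) stop("no valid placements (all overlap N)")
    mean(2^sc)
  }, numeric(1))
  mean(log(per_seq))
}

#' Motif enrichment p-value against a shuffled-sequence null
#'
#' The observed [clover_set_score()] is compared with scores of `n_null`
#' null sets, each built by independently permuting the bases of every
#' window (composition-preserving shuffle). The p-value is
#' `(1 + #\{null >= observed\}) / (n_null + 1)`.
#'
#' @inheritParams clover_set_score
#' @param n_null number of null sets (>= 19).
#' @param seed integer seed; fixed seed gives a deterministic result.
#' @return list of class `enrichment_result`: `set_raw_score`, `p_value`,
#'   `n_null`, `null_mean`, `null_sd`, `seed`.
#' @export
enrichment_pvalue <- function(windows, pwm, n_null = 999, seed = 1,
                              both_strands = TRUE, background = "windows",
                              pseudocount = 0.01) {
  if (n_null < 19) stop("n_null must be >= 19 for any useful p-value resolution")
  seqs <- .as_seq_chr(windows)
  bg <- .resolve_background(background, windows, pwm)
  observed <- clover_set_score(seqs, pwm, both_strands, bg, pseudocount)
  set.seed(seed)
  ints <- lapply(seqs, seq_to_int)
  null_scores <- vapply(seq_len(n_null), function(b) {
    shuf <- vapply(ints, function(x) int_to_seq(sample(x)), character(1))
    clover_set_score(shuf, pwm, both_strands, bg, pseudocount)
  }, numeric(1))
  p <- (1 + sum(null_scores >= observed)) / (n_null + 1)
  structure(list(set_raw_score = observed, p_value = p, n_null = n_null,
                 null_mean = mean(null_scores), null_sd = stats::sd(null_scores),
                 seed = seed),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("CLOVER-style enrichment: score %.4f, p = %.4g (%d shuffles, null %.4f +/- %.4f)\n",
              x$set_raw_score, x$p_value, x$n_null, x$null_mean, x$null_sd))
  invisible(x)
}

#' Collect the best flank-extended motif site per sequence
#'
#' For each sequence the maximum-score placement at or above `threshold`
#' (ties: smallest offset, then plus strand) is extended by `flank_width`
#' bases on each side, read in motif orientation (minus-strand sites are
#' reverse-complemented including their flanks). Extensions running off the
#' sequence are flagged `clipped`; unclipped sites all share one length,
#' ready for position-frequency-matrix construction. Sequences with no site
#' above threshold are omitted with a message.
#'
#' @inheritParams scan_pwm
#' @param flank_width bases added on each side of the core (default 5).
#' @param per_gene `"best"` (default) or `"all"` sites above threshold.
#' @param threshold minimum core score in bits; `NULL` (default) uses 60% of
#'   the PWM's maximum attainable score against the chosen background.
#' @param background default `"windows"`.
#' @return data.frame of class `motif_sites`: `gene_id`, `offset` (0-based
#'   core start), `strand`, `score`, `core_seq`, `site_seq` (flank-extended),
#'   `clipped`.
#' @export
collect_group_sites <- function(windows, pwm, flank_width = 5,
                                per_gene = c("best", "all"), threshold = NULL,
                                both_strands = TRUE, background = "windows",
                                pseudocount = 0.01) {
  per_gene <- match.arg(per_gene)
  seqs <- .as_seq_chr(windows)
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%03d", seq_along(seqs))
  bg <- .resolve_background(background, windows, pwm)
  if (is.null(threshold)) {
    S <- .llr_matrix(pwm, bg, pseudocount)
    threshold <- 0.6 * sum(apply(S, 2, max))
  }
  hits <- scan_pwm(seqs, pwm, threshold = threshold, both_strands = both_strands,
                   background = bg, pseudocount = pseudocount)
  L <- ncol(pwm$mat)
  missing_ <- setdiff(names(seqs), unique(hits$gene_id))
  if (length(missing_)) {
    message(length(missing_), " sequence(s) with no site above threshold omitted: ",
            paste(utils::head(missing_, 5), collapse = ", "),
            if (length(missing_) > 5) ", ..." else "")
  }
  if (!nrow(hits)) {
    return(structure(data.frame(gene_id = character(0), offset = integer(0),
                                strand = character(0), score = numeric(0),
                                core_seq = character(0), site_seq = character(0),
                                clipped = logical(0)),
                     class = c("motif_sites", "data.frame")))
  }
  if (per_gene == "best") {
    hits <- do.call(rbind, lapply(split(hits, hits$gene_id), function(h) h[1, ]))
  }
  lens <- nchar(seqs)[hits$gene_id]
  lo <- hits$offset - flank_width               # 0-based
  hi <- hits$offset + L + flank_width           # 0-based exclusive
  clipped <- lo < 0 | hi > lens
  site <- substr(seqs[hits$gene_id], pmax(lo, 0) + 1L, pmin(hi, lens))
  site[hits$strand == "-"] <- revcomp_chr(site[hits$strand == "-"])
  res <- data.frame(gene_id = hits$gene_id, offset = hits$offset,
                    strand = hits$strand, score = hits$score,
                    core_seq = hits$core_seq, site_seq = unname(site),
                    clipped = clipped, row.names = NULL)
  res <- res[order(match(res$gene_id, names(seqs)), -res$score, res$offset), ]
  rownames(res) <- NULL
  class(res) <- c("motif_sites", "data.frame")
  res
}

#' Write motif sites as BED6+score
#'
#' 0-based half-open records over the core match, score in the 5th column
#' (rounded to 2 decimals), strand in the 6th.
#'
#' @param sites a `motif_sites` data.frame.
#' @param path output path.
#' @param core_length motif width used to set record ends.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path, core_length = nchar(sites$core_seq)) {
  bed <- data.frame(sites$gene_id, sites$offset, sites$offset + core_length,
                    sites$core_seq, round(sites$score, 2), sites$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
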