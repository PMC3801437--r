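#' Position matrix (PFM/PWM) constructor
#'
#' A position matrix holds per-position values over the DNA alphabet
#' \{A,C,G,T\}: either raw observation counts (`kind = "counts"`) or column
#' probabilities (`kind = "probability"`). The same object serves as a
#' scanning PWM (after conversion to probabilities against a background) and
#' as a group position frequency matrix estimated from aligned binding sites.
#'
#' @param mat numeric matrix with 4 rows (A, C, G, T order; row names are set)
#'   and one column per motif position.
#' @param kind `"counts"` or `"probability"`.
#' @param background numeric length-4 base probabilities (must sum to 1);
#'   used when the matrix is scored against sequence.
#' @param name optional motif identifier.
#' @return an object of class `position_matrix`.
#' @export
position_matrix <- function(mat, kind = c("probability", "counts"),
                            background = rep(0.25, 4), name = NULL) {
  kind <- match.arg(kind)
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) stop("position matrix must have 4 rows (A, C, G, T)")
  if (any(!is.finite(mat)) || any(mat < 0)) stop("position matrix values must be finite and >= 0")
  if (abs(sum(background) - 1) > 1e-9 || any(background <= 0)) {
    stop("background must be strictly positive probabilities summing to 1")
  }
  if (kind == "probability") {
    cs <- colSums(mat)
    if (any(abs(cs - 1) > 1e-9)) stop("probability columns must each sum to 1")
  }
  rownames(mat) <- .BASES
  background <- stats::setNames(as.numeric(background), .BASES)
  structure(list(mat = mat, kind = kind, background = background, name = name),
            class = "position_matrix")
}

#' @export
print.position_matrix <- function(x, ...) {
  cat(sprintf("position_matrix (%s), %d positions%s\n", x$kind, ncol(x$mat),
              if (is.null(x$name)) "" else paste0(", '", x$name, "'")))
  print(round(x$mat, 3))
  invisible(x)
}

#' @export
length.position_matrix <- function(x) ncol(x$mat)

#' Convert a position matrix to probability form
#'
#' Count columns become probabilities with an additive pseudocount:
#' `p = (count + pseudocount) / (total + 4 * pseudocount)`. A probability-form
#' matrix is regularized the same way, treating its columns as unit-total
#' counts, so that a zero probability can be lifted before likelihood-ratio
#' scoring or Kullback-Leibler computation.
#'
#' @param pm a [position_matrix()].
#' @param pseudocount non-negative value added to every cell (default 0.01,
#'   a light regularizer for scanning; motif-divergence estimation uses 0.5).
#' @param background optional replacement background probabilities.
#' @return a probability-form `position_matrix`.
#' @export
pm_probability <- function(pm, pseudocount = 0.01, background = NULL) {
  stopifnot(inherits(pm, "position_matrix"), pseudocount >= 0)
  m <- pm$mat
  totals <- colSums(m)
  if (any(totals + 4 * pseudocount == 0)) {
    stop("column with zero total and zero pseudocount cannot be normalized")
  }
  p <- sweep(m + pseudocount, 2, totals + 4 * pseudocount, "/")
  position_matrix(p, kind = "probability",
                  background = if (is.null(background)) pm$background else background,
                  name = pm$name)
}

#' Maximum attainable log-likelihood-ratio score of a PWM
#'
#' Sum over positions of the best per-position log2 probability ratio against
#' the matrix background, in bits. Useful for setting relative scan thresholds.
#'
#' @param pm a `position_matrix`; converted to probabilities if in count form.
#' @param pseudocount passed to [pm_probability()] when conversion is needed.
#' @return maximum score in bits.
#' @export
pwm_max_score <- function(pm, pseudocount = 0.01) {
  if (pm$kind != "probability") pm <- pm_probability(pm, pseudocount)
  sum(apply(log2(pm$mat / pm$background), 2, max))
}

# ---- file formats -----------------------------------------------------------

#' Read a position matrix from a motif file
#'
#' Supports the three common text dialects: JASPAR (`>id name` header then
#' `A [ n n ... ]` rows), TRANSFAC (`P0` column header, numbered position
#' rows), and MEME minimal (`letter-probability matrix:` block). JASPAR and
#' TRANSFAC carry counts; MEME carries probabilities.
#'
#' @param path file path.
#' @param format `"jaspar"`, `"transfac"` or `"meme"`.
#' @param background base probabilities attached to the returned matrix
#'   (default uniform).
#' @return a `position_matrix` (`kind = "counts"` for JASPAR/TRANSFAC,
#'   `"probability"` for MEME).
#' @export
read_position_matrix <- function(path, format = c("jaspar", "transfac", "meme"),
                                 background = rep(0.25, 4)) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  switch(format,
    jaspar   = .parse_jaspar(lines, background),
    transfac = .parse_transfac(lines, background),
    meme     = .parse_meme(lines, background))
}

.parse_jaspar <- function(lines, background) {
  name <- NULL
  hdr <- grep("^>", lines)
  if (length(hdr)) name <- trimws(sub("^>\\s*", "", lines[hdr[1]]))
  rows <- grep("^\\s*[ACGTacgt]\\s*[\\[|]", lines, value = TRUE)
  if (length(rows) != 4L) stop("malformed JASPAR matrix: expected 4 base rows")
  base <- toupper(sub("^\\s*([ACGTacgt]).*$", "\\1", rows))
  nums <- lapply(rows, function(l) {
    l <- gsub("^\\s*[ACGTacgt]\\s*\\[?|\\]\\s*$", "", l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  if (length(unique(lengths(nums))) != 1L) stop("malformed JASPAR matrix: ragged rows")
  m <- do.call(rbind, nums)[match(.BASES, base), , drop = FALSE]
  if (any(is.na(m))) stop("malformed JASPAR matrix: non-numeric or missing base row")
  position_matrix(m, kind = "counts", background = background, name = name)
}

.parse_transfac <- function(lines, background) {
  p0 <- grep("^P0|^PO", lines)
  if (!length(p0)) stop("malformed TRANSFAC matrix: no P0 header")
  order_ <- toupper(strsplit(trimws(sub("^P[0O]\\s*", "", lines[p0[1]])), "\\s+")[[1]])[1:4]
  if (!setequal(order_, .BASES)) stop("malformed TRANSFAC matrix: P0 must list A C G T")
  name <- NULL
  id <- grep("^ID\\s+", lines, value = TRUE)
  if (length(id)) name <- trimws(sub("^ID\\s+", "", id[1]))
  rows <- list()
  for (l in lines[seq(p0[1] + 1L, length(lines))]) {
    if (grepl("^(XX|//)", l)) break
    if (!grepl("^\\s*\\d+\\s", l)) next
    f <- strsplit(trimws(l), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(f[2:5]))
    if (any(is.na(vals))) stop("malformed TRANSFAC matrix: non-numeric counts")
    rows[[length(rows) + 1L]] <- vals
  }
  if (!length(rows)) stop("malformed TRANSFAC matrix: no position rows")
  m <- t(do.call(rbind, rows))
  m <- m[match(.BASES, order_), , drop = FALSE]
  position_matrix(m, kind = "counts", background = background, name = name)
}

.parse_meme <- function(lines, background) {
  hdr <- grep("letter-probability matrix", lines)
  if (!length(hdr)) stop("malformed MEME file: no letter-probability matrix block")
  name <- NULL
  mot <- grep("^MOTIF\\s+", lines, value = TRUE)
  if (length(mot)) name <- trimws(sub("^MOTIF\\s+", "", mot[1]))
  w <- suppressWarnings(as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr[1]])))
  rows <- list()
  for (l in lines[seq(hdr[1] + 1L, length(lines))]) {
    if (!grepl("^\\s*[0-9.eE+-]+\\s+[0-9.eE+-]+", l)) break
    vals <- as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    if (length(vals) != 4L) stop("malformed MEME matrix row (expected 4 columns)")
    rows[[length(rows) + 1L]] <- vals
  }
  if (!length(rows)) stop("malformed MEME file: empty matrix")
  if (!is.na(w) && length(rows) != w) stop("malformed MEME file: row count disagrees with w=")
  m <- t(do.call(rbind, rows))
  # guard against printed rounding: renormalize columns that are off by <1e-3
  cs <- colSums(m)
  if (any(abs(cs - 1) > 1e-3)) stop("malformed MEME matrix: columns do not sum to 1")
  m <- sweep(m, 2, cs, "/")
  position_matrix(m, kind = "probability", background = background, name = name)
}

#' Write a position matrix in JASPAR text format
#'
#' @param pm a `position_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_position_matrix <- function(pm, path) {
  stopifnot(inherits(pm, "position_matrix"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0(">", if (is.null(pm$name)) "motif" else pm$name), con)
  for (b in .BASES) {
    writeLines(sprintf("%s [ %s ]", b,
                       paste(format(pm$mat[b, ], trim = TRUE, scientific = FALSE),
                             collapse = " ")), con)
  }
  invisible(path)
}

#' Bundled synthetic ISRE-like matrix
#'
#' Returns the count matrix shipped with the package
#' (`inst/extdata/isre_synthetic.jaspar`). This is a synthetic stand-in with
#' the canonical ISRE architecture (consensus `AGTTTCANTTTC`, the reverse
#' orientation of the tandem `GAAAC` repeat), constructed for this package
#' because the commercially licensed reference matrices cannot be
#' redistributed. Substitute any JASPAR/TRANSFAC/MEME file for real analyses.
#'
#' @param background base probabilities attached to the matrix.
#' @return a count-form `position_matrix` of width 12.
#' @export
isre_matrix <- function(background = rep(0.25, 4)) {
  path <- system.file("extdata", "isre_synthetic.jaspar", package = "isremotif",
                      mustWork = TRUE)
  read_position_matrix(path, "jaspar", background = background)
}
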