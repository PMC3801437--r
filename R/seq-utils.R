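# Internal integer encoding of DNA: A=1, C=2, G=3, T=4, anything else (N) = NA.
# Scanning and simulation work on integer vectors; Biostrings is used only at
# FASTA boundaries.

.BASES <- c("A", "C", "G", "T")

.decode_lookup <- local({
  lut <- rep(NA_integer_, 128L)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("a")] <- 1L
  lut[utf8ToInt("C")] <- 2L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("g")] <- 3L
  lut[utf8ToInt("T")] <- 4L; lut[utf8ToInt("t")] <- 4L
  lut
})

seq_to_int <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  .decode_lookup[utf8ToInt(s)]
}

int_to_seq <- function(x) {
  chars <- c(65L, 67L, 71L, 84L)[x]  # ACGT code points
  chars[is.na(chars)] <- 78L         # N
  intToUtf8(chars)
}

# reverse complement on the integer encoding (NA stays NA)
revcomp_int <- function(x) rev(5L - x)

revcomp_chr <- function(s) {
  vapply(s, function(si) int_to_seq(revcomp_int(seq_to_int(si))), character(1),
         USE.NAMES = FALSE)
}

# Coerce promoter windows / DNAStringSet / plain character to a named character
# vector of sequences.
.as_seq_chr <- function(x) {
  if (inherits(x, "promoter_windows")) {
    out <- x$sequence
    names(out) <- x$gene_id
    return(out)
  }
  if (inherits(x, "DNAStringSet")) {
    out <- as.character(x)
    return(out)
  }
  if (is.character(x)) return(x)
  stop("cannot interpret 'windows': expected character, DNAStringSet or promoter_windows")
}

# ACGT composition of a set of sequences (N ignored); used as the default
# scanning background.
sequence_composition <- function(x) {
  seqs <- .as_seq_chr(x)
  counts <- integer(4)
  for (s in seqs) {
    v <- seq_to_int(s)
    counts <- counts + tabulate(v, nbins = 4L)
  }
  if (sum(counts) == 0) stop("no A/C/G/T bases found in sequences")
  p <- counts / sum(counts)
  names(p) <- .BASES
  p
}
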