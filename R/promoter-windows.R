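#' Extract promoter windows around transcription start sites
#'
#' For a plus-strand gene the window covers `[TSS - upstream, TSS + downstream]`
#' in 1-based inclusive coordinates — 3001 bp at the defaults, the TSS base
#' included in the downstream span. Minus-strand windows are mirrored
#' (`[TSS - downstream, TSS + upstream]`) and reverse-complemented, so every
#' returned sequence reads 5' to 3' relative to its gene. Windows running off
#' a chromosome end are clipped and flagged `truncated`.
#'
#' @param tss data.frame with columns `gene_id`, `chrom`, `tss` (1-based
#'   position) and `strand` (`"+"`/`"-"`).
#' @param genome a named `DNAStringSet`, a named character vector, or the
#'   path of a FASTA file.
#' @param upstream,downstream window extents in bp (defaults 2500 and 500).
#' @return data.frame of class `promoter_windows`: `gene_id`, `chrom`,
#'   `strand`, `start`, `end` (0-based half-open genomic span), `truncated`,
#'   `sequence`.
#' @export
extract_promoter_windows <- function(tss, genome, upstream = 2500, downstream = 500) {
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(tss))) stop("tss needs columns: ", paste(need, collapse = ", "))
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  seqs <- if (inherits(genome, "DNAStringSet")) {
    stats::setNames(as.character(genome), names(genome))
  } else genome
  out <- vector("list", nrow(tss))
  for (i in seq_len(nrow(tss))) {
    r <- tss[i, ]
    if (!r$chrom %in% names(seqs)) stop("unknown chromosome: ", r$chrom)
    chrlen <- nchar(seqs[[r$chrom]])
    if (r$tss < 1L || r$tss > chrlen) {
      stop("TSS outside chromosome for gene ", r$gene_id)
    }
    span <- if (r$strand == "+") c(r$tss - upstream, r$tss + downstream)
            else c(r$tss - downstream, r$tss + upstream)
    clipped <- c(max(span[1], 1L), min(span[2], chrlen))
    s <- substr(seqs[[r$chrom]], clipped[1], clipped[2])
    if (r$strand == "-") s <- revcomp_chr(s)
    out[[i]] <- data.frame(gene_id = r$gene_id, chrom = r$chrom, strand = r$strand,
                           start = clipped[1] - 1L, end = clipped[2],
                           truncated = any(span != clipped), sequence = s)
  }
  res <- do.call(rbind, out)
  class(res) <- c("promoter_windows", "data.frame")
  res
}
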