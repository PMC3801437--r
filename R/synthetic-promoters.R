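#' Configuration for the synthetic promoter simulator
#'
#' Generates two groups of promoter-length sequences from an i.i.d. background
#' composition, each carrying one embedded ISRE core sampled from `core_pwm`.
#' Group A cores are flanked by plain background; group B cores additionally
#' carry group-specific conserved 5'/3' flanks: each flank base matches a
#' fixed group consensus with probability `flank_conservation`, otherwise it
#' is a background draw. `flank_conservation = 0` makes the two groups
#' statistically exchangeable (the null configuration). The whole
#' flank+core+flank block is inserted on the minus strand (reverse
#' complemented) with probability `strand_prob`.
#'
#' @param n_per_group sequences per group.
#' @param length promoter length in bp (default 3000, matching a
#'   2.5 kb-upstream / 0.5 kb-downstream window).
#' @param background i.i.d. base composition, A/C/G/T (default
#'   0.3/0.2/0.2/0.3, human promoter-like).
#' @param core_pwm `position_matrix` the core is sampled from (count matrices
#'   are converted with pseudocount 0.01).
#' @param flank_width conserved flank width on each side, bp.
#' @param flank_conservation probability in \[0,1\] that a group-B flank base
#'   matches the group consensus.
#' @param insert_position_range 0-based interval of allowed block start
#'   offsets; `NULL` means anywhere the block fits.
#' @param strand_prob probability of minus-strand insertion.
#' @param sites_per_promoter planted sites per sequence (default 1; blocks
#'   are placed without overlap when > 1).
#' @param seed integer RNG seed.
#' @return a `promoter_sim_config` list.
#' @export
promoter_sim_config <- function(n_per_group = 30, length = 3000,
                                background = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                                core_pwm = isre_matrix(), flank_width = 5,
                                flank_conservation = 0.9,
                                insert_position_range = NULL, strand_prob = 0.5,
                                sites_per_promoter = 1, seed = 1) {
  if (flank_conservation < 0 || flank_conservation > 1) {
    stop("flank_conservation must lie in [0, 1]")
  }
  if (strand_prob < 0 || strand_prob > 1) stop("strand_prob must lie in [0, 1]")
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  if (core_pwm$kind != "probability") core_pwm <- pm_probability(core_pwm, 0.01)
  block_len <- ncol(core_pwm$mat) + 2L * flank_width
  if (block_len > length) stop("core plus flanks does not fit in the sequence length")
  if (is.null(insert_position_range)) {
    insert_position_range <- c(0L, length - block_len)
  }
  if (insert_position_range[2] + block_len > length || insert_position_range[1] < 0) {
    stop("insert window plus core plus flanks must fit within the sequence length")
  }
  structure(list(n_per_group = as.integer(n_per_group), length = as.integer(length),
                 background = background, core_pwm = core_pwm,
                 flank_width = as.integer(flank_width),
                 flank_conservation = flank_conservation,
                 insert_position_range = as.integer(insert_position_range),
                 strand_prob = strand_prob,
                 sites_per_promoter = as.integer(sites_per_promoter),
                 seed = as.integer(seed)),
            class = "promoter_sim_config")
}

# one background sequence as integer vector
.bg_draw <- function(n, background) {
  sample.int(4L, n, replace = TRUE, prob = background)
}

# sample a core realization (integer vector) from a probability-form PWM
.sample_core <- function(pwm_mat) {
  L <- ncol(pwm_mat)
  vapply(seq_len(L), function(j) sample.int(4L, 1L, prob = pwm_mat[, j]), integer(1))
}

.make_flank <- function(consensus, conservation, background) {
  f <- length(consensus)
  if (f == 0L) return(integer(0))
  keep <- stats::runif(f) < conservation
  out <- .bg_draw(f, background)
  out[keep] <- consensus[keep]
  out
}

#' Simulate two promoter groups with planted ISRE sites
#'
#' @param config a [promoter_sim_config()].
#' @return list with `groupA`, `groupB` (named character vectors of
#'   sequences; use [promoters_to_fasta()] to write them) and `truth`, a
#'   data.frame with one row per planted site: `seq_id`, `group`,
#'   `block_start` (0-based start of flank+core+flank in the emitted
#'   sequence), `offset` (0-based start of the core), `strand`, `core_seq`
#'   and `site_seq` (flank-extended site, read in motif orientation).
#'   Identical seeds give identical output.
#' @export
simulate_promoters <- function(config = promoter_sim_config()) {
  stopifnot(inherits(config, "promoter_sim_config"))
  set.seed(config$seed)
  pwm <- config$core_pwm$mat
  Lc <- ncol(pwm); f <- config$flank_width
  block_len <- Lc + 2L * f
  # fixed group-specific flank consensus (only group B enforces it)
  consensus <- list(A = list(l = .bg_draw(f, config$background),
                             r = .bg_draw(f, config$background)),
                    B = list(l = .bg_draw(f, config$background),
                             r = .bg_draw(f, config$background)))
  truth <- list(); seqs <- list(A = character(0), B = character(0))
  for (grp in c("A", "B")) {
    cons <- consensus[[grp]]
    conservation <- if (grp == "B") config$flank_conservation else 0
    for (i in seq_len(config$n_per_group)) {
      x <- .bg_draw(config$length, config$background)
      sid <- sprintf("%s_%03d", grp, i)
      # non-overlapping block starts within the allowed window
      lo <- config$insert_position_range[1]; hi <- config$insert_position_range[2]
      starts <- integer(0); tries <- 0L
      while (length(starts) < config$sites_per_promoter && tries < 1000L) {
        cand <- if (hi > lo) lo + sample.int(hi - lo + 1L, 1L) - 1L else lo
        if (!any(abs(cand - starts) < block_len)) starts <- c(starts, cand)
        tries <- tries + 1L
      }
      if (length(starts) < config$sites_per_promoter) {
        stop("could not place ", config$sites_per_promoter, " non-overlapping sites")
      }
      for (s0 in starts) {
        core <- .sample_core(pwm)
        block <- c(.make_flank(cons$l, conservation, config$background), core,
                   .make_flank(cons$r, conservation, config$background))
        minus <- stats::runif(1) < config$strand_prob
        x[(s0 + 1L):(s0 + block_len)] <- if (minus) revcomp_int(block) else block
        truth[[length(truth) + 1L]] <- data.frame(
          seq_id = sid, group = grp, block_start = s0, offset = s0 + f,
          strand = if (minus) "-" else "+",
          core_seq = int_to_seq(core), site_seq = int_to_seq(block))
      }
      seqs[[grp]][sid] <- int_to_seq(x)
    }
  }
  list(groupA = seqs$A, groupB = seqs$B, truth = do.call(rbind, truth))
}

#' Write simulated promoters to FASTA and planted sites to BED
#'
#' @param sim result of [simulate_promoters()].
#' @param fasta_a,fasta_b,bed_path output paths (`bed_path` optional). BED
#'   records are 0-based half-open over the flank-extended block, with the
#'   core offset in the name field.
#' @return invisibly, the FASTA paths.
#' @export
promoters_to_fasta <- function(sim, fasta_a, fasta_b, bed_path = NULL) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$groupA), fasta_a)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$groupB), fasta_b)
  if (!is.null(bed_path)) {
    tr <- sim$truth
    bed <- data.frame(tr$seq_id, tr$block_start,
                      tr$block_start + nchar(tr$site_seq),
                      paste0("core_at_", tr$offset), 0L, tr$strand)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(c(fasta_a, fasta_b))
}
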