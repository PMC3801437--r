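# Independent brute-force oracles for PWM scanning and the CLOVER-style set
# score. Deliberately naive: character-level enumeration of every placement on
# both strands, kept free of the package's integer-encoding scan path.

.ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracle_placements <- function(s, prob, bg) {
  # prob: 4 x L probability matrix with rownames ACGT; bg named A/C/G/T
  L <- ncol(prob)
  W <- nchar(s)
  out <- list()
  for (o in 0:(W - L)) {
    ch <- strsplit(substring(s, o + 1, o + L), "")[[1]]
    if (any(!ch %in% c("A", "C", "G", "T"))) next
    fwd <- sum(vapply(seq_len(L),
                      function(j) log2(prob[ch[j], j] / bg[[ch[j]]]), numeric(1)))
    rc <- rev(unname(.ORACLE_COMP[ch]))
    rev_ <- sum(vapply(seq_len(L),
                       function(j) log2(prob[rc[j], j] / bg[[rc[j]]]), numeric(1)))
    out[[length(out) + 1L]] <- data.frame(offset = o,
                                          score_fwd = fwd, score_rev = rev_)
  }
  do.call(rbind, out)
}

oracle_clover <- function(seqs, prob, bg, both_strands = TRUE) {
  per_seq <- vapply(seqs, function(s) {
    pl <- oracle_placements(s, prob, bg)
    lr <- 2^pl$score_fwd
    if (both_strands) lr <- c(lr, 2^pl$score_rev)
    mean(lr)
  }, numeric(1))
  mean(log(per_seq))
}

# random probability-form position_matrix and random ACGT sequence
random_pfm <- function(L, concentration = 1) {
  m <- matrix(stats::rgamma(4 * L, shape = concentration), nrow = 4)
  m <- sweep(m, 2, colSums(m), "/")
  position_matrix(m, kind = "probability")
}

random_seq <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob), collapse = "")
}

# near-degenerate ISRE-consensus core matrix: planted cores are almost always
# the consensus, so the top-scoring scan hit is the planted site
sharp_isre_pwm <- function(p = 0.997) {
  cons <- strsplit("AGTTTCATTTTC", "")[[1]]
  m <- matrix((1 - p) / 3, nrow = 4, ncol = length(cons),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(cons)) m[cons[j], j] <- p
  position_matrix(m, kind = "probability")
}
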