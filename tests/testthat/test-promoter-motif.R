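test_that("promoter windows follow the 2500-up / 500-down inclusive convention", {
  set.seed(1)
  chrom <- random_seq(10000)
  genome <- c(chr1 = chrom)
  tss <- data.frame(gene_id = c("plus", "minus", "edge"),
                    chrom = "chr1", tss = c(3000, 3000, 100),
                    strand = c("+", "-", "+"))
  w <- extract_promoter_windows(tss, genome)
  plus <- w[w$gene_id == "plus", ]
  expect_identical(plus$start, 499)          # 1-based 500..3500
  expect_identical(plus$end, 3500)
  expect_identical(nchar(plus$sequence), 3001L)
  expect_false(plus$truncated)
  expect_identical(plus$sequence, substr(chrom, 500, 3500))

  minus <- w[w$gene_id == "minus", ]
  expect_identical(minus$start, 2499)        # 1-based 2500..5500, then revcomp
  expect_identical(minus$end, 5500)
  expect_identical(minus$sequence,
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(substr(chrom, 2500, 5500)))))

  edge <- w[w$gene_id == "edge", ]
  expect_true(edge$truncated)
  expect_identical(edge$start, 0)            # clipped to 1-based 1..600
  expect_identical(edge$end, 600)
  expect_identical(nchar(edge$sequence), 600L)

  expect_error(extract_promoter_windows(
    data.frame(gene_id = "x", chrom = "chr9", tss = 10, strand = "+"), genome),
    "unknown chromosome")
  expect_error(extract_promoter_windows(
    data.frame(gene_id = "x", chrom = "chr1", tss = 20000, strand = "+"), genome),
    "outside chromosome")
})

test_that("a degenerate PWM scores its consensus at the closed-form maximum", {
  m <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  m["A", 1] <- 1; m["C", 2] <- 1; m["A", 3] <- 1; m["G", 4] <- 1
  pwm <- position_matrix(m, kind = "probability")
  hits <- scan_pwm(c(w1 = "ACAG"), pwm, threshold = 0, background = "uniform")
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$strand, "+")
  expect_equal(hits$score, 4 * log2(4))
  expect_identical(hits$core_seq, "ACAG")
})

test_that("reverse-complementing a window mirrors offsets and flips strands", {
  set.seed(3)
  pwm <- random_pfm(6)
  s <- random_seq(60)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  a <- scan_pwm(c(x = s), pwm, background = "uniform")
  b <- scan_pwm(c(x = rc), pwm, background = "uniform")
  expect_equal(sort(a$score), sort(b$score), tolerance = 1e-12)
  key_a <- paste(a$offset, a$strand)
  key_b <- paste(60 - 6 - b$offset, ifelse(b$strand == "+", "-", "+"))
  expect_setequal(key_a, key_b)
})

test_that("scan scores equal brute-force enumeration over all placements and strands", {
  set.seed(11)
  for (rep in 1:20) {
    L <- sample(4:10, 1)
    pwm <- random_pfm(L)
    s <- random_seq(sample(L:80, 1))
    bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
    hits <- scan_pwm(stats::setNames(s, "w"), pwm, background = bg)
    orc <- oracle_placements(s, pwm$mat, bg)
    for (i in seq_len(nrow(orc))) {
      expect_equal(hits$score[hits$offset == orc$offset[i] & hits$strand == "+"],
                   orc$score_fwd[i], tolerance = 1e-9)
      expect_equal(hits$score[hits$offset == orc$offset[i] & hits$strand == "-"],
                   orc$score_rev[i], tolerance = 1e-9)
    }
  }
})

test_that("placements overlapping N are skipped", {
  set.seed(5)
  pwm <- random_pfm(4)
  hits <- scan_pwm(c(w = "AAANAAAA"), pwm, background = "uniform")
  # offsets 0..3 touch the N at index 3 (0-based); only 4 placements per strand remain
  expect_true(all(hits$offset == 4))
  expect_identical(nrow(hits), 2L)
})

test_that("CLOVER-style set score has its closed forms and matches the oracle", {
  set.seed(19)
  pwm <- random_pfm(5)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  # single motif-length window, single strand: ln of that one likelihood ratio
  s <- random_seq(5)
  lr <- 2^oracle_placements(s, pwm$mat, bg)$score_fwd
  expect_equal(clover_set_score(s, pwm, both_strands = FALSE, background = bg),
               log(lr), tolerance = 1e-12)
  # PWM identical to background: every likelihood ratio is 1
  flat <- position_matrix(matrix(0.25, 4, 6), kind = "probability")
  expect_equal(clover_set_score(random_seq(50), flat, background = "uniform"), 0,
               tolerance = 1e-12)
  # 10 random windows against the brute-force oracle
  seqs <- vapply(1:10, function(i) random_seq(40), character(1))
  expect_equal(clover_set_score(seqs, pwm, background = bg),
               oracle_clover(seqs, pwm$mat, bg), tolerance = 1e-9)
  expect_error(clover_set_score(character(0), pwm), "empty")
})

test_that("enrichment p-value hits its bounds and detects planted cores", {
  set.seed(2)
  # PWM equal to the background ties every null: p must be 1
  flat <- position_matrix(matrix(0.25, 4, 5), kind = "probability")
  seqs <- vapply(1:5, function(i) random_seq(40), character(1))
  r <- enrichment_pvalue(seqs, flat, n_null = 49, seed = 1, background = "uniform")
  expect_equal(r$p_value, 1)
  expect_error(enrichment_pvalue(seqs, flat, n_null = 5), ">= 19")

  # every window carries a near-consensus core: shuffles destroy it
  sim <- simulate_promoters(promoter_sim_config(n_per_group = 15, length = 300,
                                                core_pwm = sharp_isre_pwm(),
                                                flank_conservation = 0, seed = 5))
  r2 <- enrichment_pvalue(sim$groupA, sharp_isre_pwm(), n_null = 999, seed = 5)
  expect_equal(r2$p_value, 1 / 1000)
  expect_true(r2$set_raw_score > r2$null_mean + 6 * r2$null_sd)
})

test_that("enrichment test is calibrated on motif-free sequences", {
  set.seed(77)
  pwm <- random_pfm(6, concentration = 0.5)
  rejections <- 0L
  n_runs <- 500
  for (i in seq_len(n_runs)) {
    seqs <- vapply(1:8, function(j) random_seq(50), character(1))
    r <- enrichment_pvalue(seqs, pwm, n_null = 99, seed = i, background = "uniform")
    if (r$p_value <= 0.05) rejections <- rejections + 1L
  }
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / n_runs)
  expect_gte(rejections / n_runs, ci[1])
  expect_lte(rejections / n_runs, ci[2])
})

test_that("site collection applies the tie rule and flags clipped extensions", {
  m <- matrix(0.01 / 3, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  m["A", 1] <- 0.99; m["C", 2] <- 0.99; m["G", 3] <- 0.99; m["T", 4] <- 0.99
  pwm <- position_matrix(m, kind = "probability")
  # identical occurrences at offsets 10 and 40 in a T-padded window
  pad <- strrep("T", 10)
  w <- paste0(pad, "ACGT", strrep("T", 26), "ACGT", strrep("T", 10))
  sites <- collect_group_sites(c(g1 = w), pwm, flank_width = 3, threshold = 1,
                               background = "uniform")
  expect_identical(sites$offset, 10L)
  expect_identical(nchar(sites$site_seq), 4L + 6L)
  expect_false(sites$clipped)
  # a hit at the window edge cannot be fully extended
  w2 <- paste0("ACGT", strrep("T", 20))
  s2 <- collect_group_sites(c(g2 = w2), pwm, flank_width = 3, threshold = 1,
                            background = "uniform")
  expect_identical(s2$offset, 0L)
  expect_true(s2$clipped)
})

test_that("collected sites recover planted offsets and strands on a sharp-core fixture", {
  sim <- simulate_promoters(promoter_sim_config(n_per_group = 20, length = 1000,
                                                core_pwm = sharp_isre_pwm(),
                                                flank_conservation = 0.9, seed = 17))
  for (grp in c("A", "B")) {
    seqs <- if (grp == "A") sim$groupA else sim$groupB
    sites <- collect_group_sites(seqs, sharp_isre_pwm(), flank_width = 5,
                                 threshold = 0)
    tr <- sim$truth[sim$truth$group == grp, ]
    m <- merge(sites, tr, by.x = "gene_id", by.y = "seq_id")
    expect_identical(nrow(m), 20L)
    expect_identical(m$offset.x, m$offset.y)
    expect_identical(m$strand.x, m$strand.y)
    expect_identical(m$site_seq.x, m$site_seq.y)
  }
})

test_that("sites serialize to BED6 with half-open core coordinates", {
  sim <- simulate_promoters(promoter_sim_config(n_per_group = 4, length = 300, seed = 2))
  sites <- collect_group_sites(sim$groupA, isre_matrix(), threshold = 0)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_sites_bed(sites, bed)
  tab <- utils::read.delim(bed, header = FALSE)
  expect_identical(tab$V2, sites$offset)
  expect_true(all(tab$V3 - tab$V2 == nchar(sites$core_seq)))
  expect_identical(tab$V6, sites$strand)
})
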