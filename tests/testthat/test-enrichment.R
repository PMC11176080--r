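test_that("the enrichment formula reproduces hand-computed values", {
  # n_i=92, N_i=1e6, n_j=10, N_j=1e6, medN=1e6, c=8 -> log2(100/18)
  expect_equal(chip_enrichment(92, 1e6, 10, 1e6, 1e6), log2(100 / 18))
  # equal rates cancel regardless of depths
  expect_equal(chip_enrichment(50, 1e6, 100, 2e6, 1.5e6), 0)
  # zero counts hit the pseudocount floor exactly
  expect_equal(chip_enrichment(0, 1e6, 0, 1e6, 1e6), 0)
  expect_error(chip_enrichment(5, 0, 5, 1e6, 1e6), "library")
  expect_error(chip_enrichment(-1, 1e6, 5, 1e6, 1e6), "counts")
})

test_that("enrichment is monotone and converges to log2 of the rate ratio", {
  e <- chip_enrichment(c(10, 20, 40), 1e6, 10, 1e6, 1e6)
  expect_true(all(diff(e) > 0))
  e2 <- chip_enrichment(10, 1e6, c(10, 20, 40), 1e6, 1e6)
  expect_true(all(diff(e2) < 0))
  # pseudocount limit: counts -> Inf at fixed ratio r = 4
  ratio4 <- vapply(10^(2:6), function(n)
    chip_enrichment(4 * n, 1e7, n, 1e7, 1e7), 0)
  expect_true(all(diff(abs(ratio4 - 2)) < 0))
  expect_lt(abs(ratio4[5] - 2), 1e-3)
  # doubling depths with proportional counts leaves enrichment unchanged
  # when median(N) is held fixed
  expect_equal(chip_enrichment(30, 1e6, 12, 1e6, 1e6),
               chip_enrichment(60, 2e6, 24, 2e6, 1e6))
})

test_that("bound calling applies the inclusive twofold threshold", {
  # construct counts that give exactly 1.0: (n1 + 8)/(n2 + 8) = 2
  # with equal library sizes and medN = N: n1 = 40, n2 = 16
  e <- chip_enrichment(40, 1e6, 16, 1e6, 1e6)
  expect_equal(e, 1.0)
  model <- enrichment_model()
  sites <- data.frame(chrom = "chr1", start = 481L, end = 500L,
                      center = 490L)
  mk <- function(n_in, n_total) {
    pos <- c(as.integer(seq(390, 590, length.out = n_in)),
             as.integer(seq(3000, 4000, length.out = n_total - n_in)))
    fragment_table("chr1", pos - 10L, pos + 10L)
  }
  # equal library sizes of 100: normalized window counts are the raw
  # counts, so 40 vs 16 gives (40+8)/(16+8) = 2, i.e. exactly 1.0
  ip <- mk(40, 100); input <- mk(16, 100)
  called <- call_bound(sites, ip, input, model)
  expect_equal(called$enrichment, 1.0)
  expect_true(called$bound)       # exactly at threshold counts as bound
  # identical tables are never bound
  same <- call_bound(sites, ip, ip, model)
  expect_equal(same$enrichment, 0)
  expect_false(same$bound)
})

test_that("response scores vanish for identical conditions and are antisymmetric", {
  set.seed(21)
  fr1 <- rand_fragments(400, genome_len = 5000, seed = 31)
  fr2 <- rand_fragments(400, genome_len = 5000, seed = 32)
  sites <- data.frame(chrom = "chr1", start = c(1000L, 2500L),
                      end = c(1019L, 2519L))
  r0 <- response_scores(sites, fr1, fr1, fr2, fr2)
  expect_equal(r0$delta_chip, c(0, 0))
  expect_equal(r0$delta_atac, c(0, 0))
  ab <- response_scores(sites, fr1, fr2, fr1, fr2)
  ba <- response_scores(sites, fr2, fr1, fr2, fr1)
  expect_equal(ab$delta_chip, -ba$delta_chip)
  expect_error(response_scores(sites, fr1, NULL, fr2, fr2), "ip_wt")
})

test_that("PWM scanning finds consensus hits on both strands with equal score", {
  pwm <- ctcfkit:::placeholder_pwm("GATTACAGG")
  cons <- "GATTACAGG"
  bg <- "TTTTTTTTTTTTTTTTTTTT"
  hits <- scan_pwm(list(chr1 = paste0(bg, cons, bg)), pwm)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 20L)
  expect_equal(hits$strand, "+")
  lo <- pwm_log_odds(pwm)
  expect_equal(hits$pwm_score, sum(apply(lo, 2, max)))
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(cons, "")[[1]]),
                                     collapse = ""))
  hits_rc <- scan_pwm(list(chr1 = paste0(bg, rc, bg)), pwm)
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$start, 20L)
  expect_equal(hits_rc$pwm_score, hits$pwm_score)
})

test_that("PWM scan equals the exhaustive per-position scan", {
  pwm <- ctcfkit:::placeholder_pwm("GATTACA")
  for (seed in 1:8) {
    set.seed(seed)
    g <- list(chr1 = paste(sample(c("A", "C", "G", "T"), 2000,
                                  replace = TRUE), collapse = ""))
    got <- scan_pwm(g, pwm, score_threshold = 0.5)
    want <- brute_pwm_scan(g, pwm, 0.5)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
      next
    }
    # same hit set up to the package's same-strand overlap resolution:
    # every reported hit must be in the exhaustive set with equal score,
    # and every exhaustive hit must overlap a reported same-strand hit
    # of score >= its own
    key <- function(d) paste(d$chrom, d$start, d$strand)
    expect_true(all(key(got) %in% key(want)), info = seed)
    m <- match(key(got), key(want))
    expect_equal(got$pwm_score, want$score[m], info = seed)
    for (i in seq_len(nrow(want))) {
      same <- got$strand == want$strand[i] &
        got$start < want$start[i] + 7L & got$start + 7L > want$start[i]
      expect_true(any(same & got$pwm_score >= want$score[i] - 1e-9),
                  info = seed)
    }
  }
})

test_that("a PWM wider than the sequence yields an empty set with warning", {
  pwm <- ctcfkit:::placeholder_pwm("ACGTACGTACGT")
  expect_warning(hits <- scan_pwm(list(chr1 = "ACGT"), pwm), "wider")
  expect_equal(nrow(hits), 0L)
})

test_that("JASPAR PFM I/O round-trips", {
  pwm <- ctcfkit:::placeholder_pwm("TACGCA") * 100
  path <- withr::local_tempfile(fileext = ".jaspar")
  write_jaspar_pfm(pwm, path, id = "toy")
  back <- read_jaspar_pfm(path)
  expect_equal(unclass(back), unclass(pwm), ignore_attr = TRUE)
  expect_equal(attr(back, "motif_id"), "toy")
  # the shipped placeholder motifs load
  m1 <- read_jaspar_pfm(system.file("extdata",
                                    "m1_placeholder_synthetic.jaspar",
                                    package = "ctcfkit"))
  expect_equal(ncol(m1), 19L)
})
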