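toy_matrix <- function(n = 60L, seed = 1L, exponent = -1) {
  set.seed(seed)
  d <- abs(row(diag(n)) - col(diag(n)))
  base <- 1000 * pmax(d, 1)^exponent
  m <- matrix(rpois(n * n, base), n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  contact_matrix(m, resolution = 10000L)
}

test_that("contact matrices validate symmetry and round-trip via triplets", {
  expect_error(contact_matrix(matrix(1:9, 3)), "symmetric")
  cm <- toy_matrix(30)
  tp <- withr::local_tempfile(fileext = ".tsv")
  bp <- withr::local_tempfile(fileext = ".tsv")
  write_contact_matrix(cm, tp, bp)
  back <- read_contact_matrix(tp, bp)
  expect_equal(back$counts, cm$counts)
  expect_equal(back$resolution, 10000L)
})

test_that("observed/expected is unity on its own diagonal means and idempotent", {
  cm <- toy_matrix(50, seed = 3)
  oe <- observed_over_expected(cm)
  # every diagonal of the O/E matrix has mean 1
  d <- abs(row(oe$counts) - col(oe$counts))
  for (k in c(0, 1, 5, 20))
    expect_equal(mean(oe$counts[d == k], na.rm = TRUE), 1)
  oe2 <- observed_over_expected(oe)
  expect_equal(oe2$counts, oe$counts, tolerance = 1e-12)
})

test_that("balancing weights multiply into the O/E values", {
  cm <- toy_matrix(30, seed = 4)
  w <- runif(30, 0.5, 2)
  cmw <- contact_matrix(cm$counts, resolution = 10000L, weights = w)
  oe <- observed_over_expected(cmw)
  manual <- cm$counts * outer(w, w)
  d <- abs(row(manual) - col(manual))
  exp_d <- vapply(0:29, function(k) mean(manual[d == k]), 0)
  expect_equal(oe$counts, manual / exp_d[d + 1], tolerance = 1e-12)
})

test_that("a single-anchor pileup returns that submatrix and flips are involutive", {
  cm <- toy_matrix(60, seed = 5)
  oe <- observed_over_expected(cm)
  pu <- hic_pileup(oe, data.frame(bin = 30L), pad = 100000L)
  expect_equal(pu$values, oe$counts[21:41, 21:41], ignore_attr = TRUE)
  expect_equal(pu$n_anchors, 1L)
  # minus-strand anchor flips both axes
  pm <- hic_pileup(oe, data.frame(bin = 30L, strand = "-"),
                   pad = 100000L)
  expect_equal(pm$values, pu$values[21:1, 21:1], ignore_attr = TRUE)
  # strand-balanced anchors with both orientations: flipping all strands
  # twice returns the original pileup
  an <- data.frame(bin = c(20L, 30L, 40L), strand = c("+", "-", "+"))
  p0 <- hic_pileup(oe, an, pad = 50000L)
  an2 <- an; an2$strand <- c("-", "+", "-")
  p1 <- hic_pileup(oe, an2, pad = 50000L)
  an3 <- an2; an3$strand <- an$strand
  p2 <- hic_pileup(oe, an3, pad = 50000L)
  expect_equal(p2$values, p0$values)
  expect_false(isTRUE(all.equal(p1$values, p0$values)))
  # edge anchors are skipped and counted
  pe <- hic_pileup(oe, data.frame(bin = c(1L, 30L)), pad = 100000L)
  expect_equal(pe$skipped, 1L)
  expect_equal(pe$n_anchors, 1L)
})

test_that("insulation strength is 1 on uniform windows and scale invariant", {
  u <- matrix(1, 21, 21)
  expect_equal(insulation_strength(u), 1)
  cm <- toy_matrix(60, seed = 6)
  pu <- hic_pileup(observed_over_expected(cm), data.frame(bin = 30L),
                   pad = 100000L)
  s1 <- insulation_strength(pu)
  expect_equal(insulation_strength(pu$values * 7), s1)
  expect_error(insulation_strength(matrix(1, 20, 20)), "odd")
  expect_error(insulation_strength(matrix(1, 3, 3), ignore_diags = 5L),
               "empty quadrant")
})

test_that("noiseless planted boundaries calibrate the quadrant statistic exactly", {
  for (s in c(1, 1.5, 2, 4)) {
    cfg <- synthetic_config(seed = 1, hic_n_bins = 200,
                            boundary_strength = s,
                            tad_boundaries = c(49L, 99L, 149L))
    cm <- simulate_contact_matrix(cfg, noiseless = TRUE)
    oe <- observed_over_expected(cm,
                                 expected = attr(cm, "expected_decay"))
    pu <- hic_pileup(oe, data.frame(bin = c(49L, 99L, 149L)),
                     pad = 200000L)
    expect_equal(insulation_strength(pu), s, tolerance = 1e-12)
  }
})

test_that("diamond insulation matches brute force and finds planted minima", {
  cfg <- synthetic_config(seed = 9, hic_n_bins = 120, hic_depth = 5e5,
                          boundary_strength = 3,
                          tad_boundaries = c(39L, 79L))
  cm <- simulate_contact_matrix(cfg)
  di <- diamond_insulation(cm, window = 100000L)
  expect_equal(di$insulation, brute_diamond(cm$counts, 10L))
  # planted boundaries are local minima of the track
  # the diamond fully crosses the boundary at both flanking bins, so
  # the minimum sits on one of them
  for (b in c(39L, 79L)) {
    region <- di$log2_insulation[di$bin %in% (b - 5L):(b + 6L)]
    expect_true(which.min(region) %in% 6:7, info = b)
  }
  expect_true(any(di$boundary[di$bin %in% c(39L, 40L, 79L, 80L)]))
  # a Toeplitz (translation invariant) matrix gives a flat track
  n <- 80L
  d <- abs(row(diag(n)) - col(diag(n)))
  flat <- contact_matrix(1000 * pmax(d, 1)^-1, resolution = 10000L)
  df <- diamond_insulation(flat, window = 100000L)
  mid <- df$insulation[!is.na(df$insulation)]
  expect_lt(diff(range(mid)) / mean(mid), 1e-12)
  expect_true(all(is.na(df$insulation[1:10])))
})

test_that("diamond insulation equals brute force on random matrices", {
  for (seed in 11:14) {
    cm <- toy_matrix(70, seed = seed)
    di <- diamond_insulation(cm, window = 50000L)
    expect_equal(di$insulation, brute_diamond(cm$counts, 5L),
                 info = seed)
  }
})

test_that("TAD construction pairs boundaries and drops over-long candidates", {
  tads <- build_tads(c(0, 1e6, 3e6))
  expect_equal(nrow(tads), 1L)
  expect_equal(tads$end - tads$start, 1e6)
  expect_equal(nrow(build_tads(5e5)), 0L)
  b <- sort(runif(10, 0, 1e7))
  cands <- build_tads(b, max_length = Inf)
  expect_equal(nrow(cands), 9L)
  # exactly max_length is kept ("longer than" is dropped)
  keep <- build_tads(c(0, 1.5e6), max_length = 1.5e6)
  expect_equal(nrow(keep), 1L)
})

test_that("pileup ratios propagate scaling and identity", {
  cm <- toy_matrix(60, seed = 15)
  oe <- observed_over_expected(cm)
  pu <- hic_pileup(oe, data.frame(bin = c(25L, 35L)), pad = 80000L)
  same <- pileup_ratio(pu, pu)
  expect_true(all(abs(same$values - 1) < 1e-12, na.rm = TRUE))
  expect_equal(same$insulation_ratio, 1)
  doubled <- pu; doubled$values <- pu$values * 2
  expect_true(all(abs(pileup_ratio(doubled, pu)$values - 2) < 1e-12,
                  na.rm = TRUE))
  bad <- hic_pileup(oe, data.frame(bin = 30L), pad = 50000L)
  expect_error(pileup_ratio(pu, bad), "mismatch")
})
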