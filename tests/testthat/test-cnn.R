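test_that("one-hot encoding is exact and round-trips", {
  m <- one_hot(strrep("A", 150))
  expect_equal(unname(m["A", ]), rep(1, 150))
  expect_equal(sum(m), 150)
  s <- paste0(strrep("C", 10), "N", strrep("G", 139))
  mn <- one_hot(s)
  expect_equal(unname(colSums(mn)[11]), 0)       # N column all-zero
  set.seed(7)
  for (i in 1:5) {
    sq <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                collapse = "")
    expect_equal(one_hot_decode(one_hot(sq)), sq)
  }
  expect_equal(one_hot_decode(mn), s)
  expect_error(one_hot("ACGT"), "length")
})

test_that("parameter tensors match the declared architecture exactly", {
  spec <- cnn_spec()
  expect_equal(spec$flat_size, 9L * 64L)         # 150 -> 75 -> 37 -> 18 -> 9
  set.seed(1)
  ps <- ctcfkit:::init_params(spec)
  shapes <- ctcfkit:::cnn_param_shapes(spec)
  expect_setequal(names(ps), names(shapes))
  for (nm in names(shapes)) {
    got <- if (is.matrix(ps[[nm]])) dim(ps[[nm]]) else length(ps[[nm]])
    expect_equal(got, shapes[[nm]], info = nm, ignore_attr = TRUE)
  }
  expect_equal(dim(ps$convW1), c(5L * 4L, 128L))
  expect_equal(dim(ps$convW4), c(3L * 128L, 64L))
  expect_equal(dim(ps$denseW1), c(576L, 128L))
  expect_equal(dim(ps$denseW3), c(64L, 1L))
})

test_that("analytic gradients match finite differences through the network", {
  spec <- cnn_spec()
  set.seed(2)
  ps <- ctcfkit:::init_params(spec)
  X <- ctcfkit:::one_hot_batch(vapply(1:3, function(i)
    paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
          collapse = ""), ""), 150L)
  y <- rnorm(3)
  fw <- ctcfkit:::cnn_batch(ps, X, spec, y = y, want_grads = TRUE,
                            input_grad = TRUE)
  num_grad <- function(nm, idx) {
    eps <- 1e-2
    p2 <- ps; p2[[nm]][idx] <- p2[[nm]][idx] + eps
    l1 <- ctcfkit:::cnn_batch(p2, X, spec, y = y)$loss
    p2[[nm]][idx] <- p2[[nm]][idx] - 2 * eps
    l2 <- ctcfkit:::cnn_batch(p2, X, spec, y = y)$loss
    (l1 - l2) / (2 * eps)
  }
  set.seed(3)
  for (nm in c("convW1", "convW3", "convb2", "denseW1", "denseW3",
               "denseb3")) {
    for (idx in sample.int(length(ps[[nm]]),
                           min(3L, length(ps[[nm]])))) {
      a <- fw$grads[[nm]][idx]
      n <- num_grad(nm, idx)
      expect_lt(abs(a - n), 1e-2 + 0.1 * abs(n),
                label = paste(nm, idx))
    }
  }
  # input gradient against a finite difference of the prediction
  fo <- ctcfkit:::cnn_batch(ps, X, spec, dout = rep(1, 3),
                            want_grads = TRUE, input_grad = TRUE)
  eps <- 1e-2
  X2 <- X; X2[30, 2, 1] <- X2[30, 2, 1] + eps
  p1 <- ctcfkit:::cnn_batch(ps, X2, spec)$pred[1]
  X2[30, 2, 1] <- X2[30, 2, 1] - 2 * eps
  p2 <- ctcfkit:::cnn_batch(ps, X2, spec)$pred[1]
  expect_lt(abs(fo$dX[30, 2, 1] - (p1 - p2) / (2 * eps)), 5e-3)
})

test_that("constant labels train to near-constant predictions", {
  set.seed(5)
  seqs <- vapply(1:120, function(i)
    paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
          collapse = ""), "")
  sites <- data.frame(chrom = rep(c("chr1", "chr2"), each = 60),
                      sequence = seqs, delta = 0)
  spec <- cnn_spec(max_epochs = 3L, patience = 3L)
  m <- train_cnn(sites, spec = spec, holdout_chroms = "chr2", seed = 1)
  expect_true(m$report$zero_label_variance)
  expect_lt(mean((m$test$predicted - 0)^2), 0.05)
})

test_that("training splits never leak holdout chromosomes", {
  set.seed(6)
  seqs <- vapply(1:80, function(i)
    paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
          collapse = ""), "")
  sites <- data.frame(chrom = sample(paste0("chr", 1:4), 80,
                                     replace = TRUE),
                      sequence = seqs, delta = rnorm(80))
  spec <- cnn_spec(max_epochs = 1L, patience = 1L)
  m <- train_cnn(sites, spec = spec, holdout_chroms = c("chr3", "chr4"),
                 seed = 2)
  expect_equal(m$report$n_test, sum(sites$chrom %in% c("chr3", "chr4")))
  expect_equal(m$report$n_train + m$report$n_val + m$report$n_test, 80L)
  expect_true(all(m$test$chrom %in% c("chr3", "chr4")))
  expect_error(train_cnn(sites, spec = spec, holdout_chroms = "chr9",
                         seed = 2), "holdout")
})

test_that("dinucleotide shuffles preserve the dinucleotide multiset", {
  set.seed(11)
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
    sh <- dinucleotide_shuffle(s, n_shuffles = 10L, seed = i)
    for (x in sh) {
      expect_equal(dinuc_counts(x), dinuc_counts(s))
      expect_equal(sort(strsplit(x, "")[[1]]), sort(strsplit(s, "")[[1]]))
    }
  }
  # "ACACAC" admits only itself
  expect_true(all(dinucleotide_shuffle("ACACAC", 5L, seed = 1) ==
                    "ACACAC"))
  # N segments shuffled independently, N skeleton preserved
  sn <- dinucleotide_shuffle("ACGTACGNNTGCATGCA", 8L, seed = 2)
  expect_true(all(substr(sn, 8, 9) == "NN"))
  for (x in sn) expect_equal(dinuc_counts(substr(x, 1, 7)),
                             dinuc_counts("ACGTACG"))
})

test_that("shuffles are uniform over the valid Euler paths of a 10-mer", {
  s <- "ACGTCAGTCA"
  valid <- enumerate_dinuc_shuffles(s)
  expect_gt(length(valid), 3)
  draws <- dinucleotide_shuffle(s, n_shuffles = 10000L, seed = 42)
  expect_true(all(draws %in% valid))
  tab <- table(factor(draws, levels = valid))
  p <- suppressWarnings(stats::chisq.test(tab)$p.value)
  expect_gt(p, 0.001)
})

test_that("attribution refuses untrained models and honors analytic cases", {
  fake <- structure(list(params = NULL), class = "list")
  expect_error(attribute(fake, "ACGT"), "trained")
})

test_that("persistent sites are enriched for the M2 motif when it drives persistence", {
  cfg <- synthetic_config(genome_length = 1e6, n_sites = 2000,
                          m2_fraction = 0.3, seed = 33)
  g <- simulate_genome(cfg, min_gap = 400L)
  r <- simulate_binding_response(g$sites, a = 0.2, b = 0.8,
                                 noise_sd = 0.3, seed = 33)
  # binding change centered on loss; M2 pushes sites back toward
  # persistence (no change)
  r$delta_chip <- r$delta - 1
  r$delta_atac <- 0
  grp <- persistent_groups(r, n_groups = 2L)
  scan <- m2_site_scan(site_sequences(g$genome, g$sites))
  tab <- table(persistent = grp$persistent, m2 = scan$has_m2)
  ft <- fisher.test(tab, alternative = "greater")
  expect_lt(ft$p.value, 0.01)
  frac_p <- mean(scan$has_m2[grp$persistent])
  frac_l <- mean(scan$has_m2[!grp$persistent])
  expect_gt(frac_p, frac_l)
})
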