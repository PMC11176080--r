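test_that("cytosine contexts follow the GCH/HCG rule with ambiguous overlaps", {
  expect_equal(classify_contexts("ACGT", 1L)$context, "CpG")
  expect_equal(classify_contexts("GCGT", 1L)$context, "GCG")
  expect_true(classify_contexts("GCGT", 1L)$ambiguous)
  expect_equal(classify_contexts("GCAT", 1L)$context, "GpC")
  expect_equal(classify_contexts("CCGT", 1L)$context, "CCG")
  expect_equal(classify_contexts("ACAT", 1L)$context, "other")
  # not a C: error record, not an exception
  res <- classify_contexts("AAAA", 1L)
  expect_equal(res$context, "other")
  expect_match(res$error, "not a C")
})

test_that("all 64 trinucleotide contexts match a hand-written truth table", {
  bases <- c("A", "C", "G", "T")
  truth <- function(prev, nxt) {
    if (prev == "G" && nxt == "G") "GCG"
    else if (prev == "C" && nxt == "G") "CCG"
    else if (nxt == "G") "CpG"
    else if (prev == "G") "GpC"
    else "other"
  }
  for (p in bases) for (n in bases) {
    s <- paste0(p, "C", n)
    expect_equal(classify_contexts(s, 1L)$context, truth(p, n),
                 info = s)
  }
})

test_that("minus-strand positions classify on the reverse complement", {
  # plus strand "AGCA": G at index 2 is a C on the minus strand read
  # 5'-TGCT-3'; its context there is GpC
  expect_equal(classify_contexts("AGCA", 1L, strand = "-")$context, "GpC")
  # "ACGT": G at index 2 on minus is C followed by G (CpG on minus)
  expect_equal(classify_contexts("ACGT", 2L, strand = "-")$context, "CpG")
})

test_that("context filtering removes exactly the ambiguous columns", {
  for (seed in 1:5) {
    set.seed(seed)
    s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
               collapse = "")
    cpos <- which(strsplit(s, "")[[1]] == "C") - 1L
    ctx <- classify_contexts(s, cpos)
    chars <- strsplit(s, "")[[1]]
    tri <- function(p) paste0(chars[p], chars[p + 1L], chars[p + 2L])
    amb <- vapply(cpos, function(p)
      p >= 1L && p + 2L <= length(chars) && tri(p) %in% c("GCG", "CCG"),
      TRUE)
    expect_equal(ctx$ambiguous, amb, info = seed)
  }
})

test_that("footprint limits: all methylated gives 0, none gives 1", {
  s <- paste(rep("GCAT", 25), collapse = "")    # GpC every 4 bp
  calls <- expand.grid(molecule_id = 1:20,
                       position = seq(1L, 97L, 4L))
  calls$is_methylated <- 1L
  m <- smf_matrix(calls, s)
  fp <- footprint_profile(m, min_coverage = 5L)
  expect_true(all(fp$footprint == 0))
  calls$is_methylated <- 0L
  fp1 <- footprint_profile(smf_matrix(calls, s), min_coverage = 5L)
  expect_true(all(fp1$footprint == 1))
  # complement identity per position
  set.seed(4)
  calls$is_methylated <- rbinom(nrow(calls), 1L, 0.35)
  m2 <- smf_matrix(calls, s)
  fp2 <- footprint_profile(m2, min_coverage = 1L)
  expect_equal(fp2$footprint, 1 - colMeans(m2$calls, na.rm = TRUE),
               ignore_attr = TRUE)
  expect_true(all(fp2$footprint >= 0 & fp2$footprint <= 1))
})

test_that("low-coverage positions are missing, not zero", {
  s <- paste(rep("GCAT", 10), collapse = "")
  calls <- data.frame(molecule_id = c(1L, 1L, 2L),
                      position = c(1L, 5L, 5L),
                      is_methylated = c(1L, 0L, 1L))
  m <- smf_matrix(calls, s)
  fp <- footprint_profile(m, min_coverage = 2L)
  expect_true(is.na(fp$footprint[fp$position == 1]))
  expect_equal(fp$footprint[fp$position == 5], 0.5)
})

test_that("replicate averaging equals the pooled mean at equal molecule counts", {
  s <- paste(rep("GCAT", 25), collapse = "")
  mk <- function(seed) {
    set.seed(seed)
    calls <- expand.grid(molecule_id = 1:30, position = seq(1L, 97L, 4L))
    calls$is_methylated <- rbinom(nrow(calls), 1L, 0.4)
    smf_matrix(calls, s)
  }
  reps <- list(mk(1), mk(2), mk(3))
  fp <- footprint_profile(reps, min_coverage = 1L)
  pooled <- 1 - colMeans(do.call(rbind, lapply(reps, `[[`, "calls")),
                         na.rm = TRUE)
  expect_equal(fp$footprint, unname(pooled))
  expect_true(all(is.finite(fp$sd)))
})

test_that("molecule sorting partitions by window methylation deterministically", {
  s <- paste(rep("GCAT", 25), collapse = "")
  pos <- seq(1L, 97L, 4L)
  calls <- expand.grid(molecule_id = 1:40, position = pos)
  # molecules 1..20 protected (unmethylated), 21..40 accessible
  calls$is_methylated <- as.integer(calls$molecule_id > 20L)
  m <- smf_matrix(calls, s)
  srt <- molecule_sort(m, c(0L, 100L))
  expect_equal(sum(srt$label == "bound_like"), 20L)
  expect_equal(sum(srt$label == "accessible_like"), 20L)
  expect_true(all(srt$label[1:20] == "bound_like"))
  srt2 <- molecule_sort(m, c(0L, 100L))
  expect_identical(srt, srt2)
  # homogeneous molecules form a single partition
  calls$is_methylated <- 1L
  one <- molecule_sort(smf_matrix(calls, s), c(0L, 100L))
  expect_true(all(one$label == "accessible_like"))
  expect_error(molecule_sort(m, c(200L, 300L)), "no GpC")
})
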