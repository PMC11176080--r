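# Brute-force oracles and small fixture builders shared across tests.

# random fragment table on a small genome
rand_fragments <- function(n, genome_len = 2000L, chroms = "chr1",
                           max_len = 200L, seed = 1L) {
  set.seed(seed)
  start <- sample.int(genome_len - max_len, n, replace = TRUE) - 1L
  len <- sample(20:max_len, n, replace = TRUE)
  fragment_table(sample(chroms, n, replace = TRUE), start, start + len,
                 sample(c("+", "-"), n, replace = TRUE))
}

# per-site brute-force anchored profile counter (midpoint / five_prime)
brute_profile <- function(fragments, anchors, window, mode) {
  anchors <- as_anchors(anchors)
  h <- window %/% 2L
  out <- matrix(0, nrow(anchors), window)
  pt <- switch(mode,
               midpoint = fragments$start +
                 (fragments$end - fragments$start) %/% 2L,
               five_prime = ifelse(fragments$strand == "-",
                                   fragments$end - 1L, fragments$start))
  for (i in seq_len(nrow(anchors))) {
    for (f in seq_len(nrow(fragments))) {
      if (fragments$chrom[f] != anchors$chrom[i]) next
      rel <- if (anchors$strand[i] == "-")
        anchors$center[i] - pt[f] else pt[f] - anchors$center[i]
      if (rel >= -h && rel <= h - 1L)
        out[i, rel + h + 1L] <- out[i, rel + h + 1L] + 1
    }
  }
  out
}

# all-pairs brute-force phasogram
brute_phasogram <- function(fragments, max_distance) {
  counts <- numeric(max_distance)
  pt <- ifelse(fragments$strand == "-", fragments$end - 1L,
               fragments$start)
  key <- paste(fragments$chrom, fragments$strand)
  for (g in split(pt, key)) {
    if (length(g) < 2L) next
    d <- as.vector(abs(outer(g, g, `-`)))
    d <- d[d >= 1 & d <= max_distance]
    counts <- counts + tabulate(d, nbins = max_distance) / 2
  }
  counts
}

# exhaustive per-position log-odds PWM scan (both strands, no overlap
# resolution)
brute_pwm_scan <- function(seqs, pwm, thr_frac = 0.8) {
  lo <- pwm_log_odds(pwm)
  w <- ncol(lo)
  thr <- thr_frac * sum(apply(lo, 2L, max))
  score1 <- function(s) {
    b <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    n <- length(b)
    if (n < w) return(numeric(0))
    vapply(seq_len(n - w + 1L), function(p) {
      idx <- b[p:(p + w - 1L)]
      if (anyNA(idx)) -Inf else sum(lo[cbind(idx, seq_len(w))])
    }, 0)
  }
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  out <- list()
  for (ch in names(seqs)) {
    s <- seqs[[ch]]
    fw <- score1(s); rv <- score1(rc(s))
    n <- nchar(s)
    hf <- which(fw >= thr); hr <- which(rv >= thr)
    out[[ch]] <- rbind(
      if (length(hf)) data.frame(chrom = ch, start = hf - 1L,
                                 strand = "+", score = fw[hf]),
      if (length(hr)) data.frame(chrom = ch, start = n - w + 1L - hr,
                                 strand = "-", score = rv[hr]))
  }
  do.call(rbind, out)
}

# O(n w^2) brute-force diamond insulation
brute_diamond <- function(m, w) {
  n <- nrow(m)
  ins <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - w < 1L || i + w > n) next
    vals <- c()
    for (a in (i - w):(i - 1L)) for (b in (i + 1L):(i + w))
      vals <- c(vals, m[a, b])
    ins[i] <- mean(vals, na.rm = TRUE)
  }
  ins
}

# enumerate all distinct dinucleotide-preserving shuffles of a short
# sequence (same start and end base), by depth-first search over the
# edge multiset
enumerate_dinuc_shuffles <- function(s) {
  b <- strsplit(s, "")[[1]]
  n <- length(b)
  edges <- table(paste0(b[-n], b[-1]))
  res <- character(0)
  recurse <- function(cur, remaining, acc) {
    if (sum(remaining) == 0L) {
      res[[length(res) + 1L]] <<- paste(acc, collapse = "")
      return(invisible())
    }
    outs <- names(remaining)[remaining > 0 &
                               substr(names(remaining), 1, 1) == cur]
    for (e in outs) {
      remaining[e] <- remaining[e] - 1L
      recurse(substr(e, 2, 2), remaining, c(acc, substr(e, 2, 2)))
      remaining[e] <- remaining[e] + 1L
    }
  }
  rem <- c(edges)
  recurse(b[1], rem, b[1])
  unique(res)
}

dinuc_counts <- function(s) {
  b <- strsplit(s, "")[[1]]
  table(paste0(b[-length(b)], b[-1]))
}

# toy response table of k well-separated Gaussian blobs
blob_table <- function(k = 5L, n_per = 60L, sep = 6, sd = 0.4, seed = 1L) {
  set.seed(seed)
  centers <- cbind(delta_atac = sep * seq_len(k),
                   delta_chip = sep * ((seq_len(k) %% 2) * 2 - 1) *
                     seq_len(k) / 2)
  df <- do.call(rbind, lapply(seq_len(k), function(i)
    data.frame(delta_atac = rnorm(n_per, centers[i, 1], sd),
               delta_chip = rnorm(n_per, centers[i, 2], sd),
               truth = i)))
  df[sample.int(nrow(df)), ]
}
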