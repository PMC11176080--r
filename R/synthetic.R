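#' Configuration of the synthetic-data generators
#'
#' Collects every knob of the ground-truth simulators.  The seed fully
#' determines all generator outputs.  Defaults describe a desk-scale
#' mouse-like setting: ~42 percent GC background, a 19-bp core motif
#' (M1) with an optional 9-bp accessory motif (M2) whose start sits
#' 21 bp downstream of the M1 center in motif orientation, 182-bp
#' nucleosome repeat length, and Hi-C at 10-kb resolution with a
#' distance-decay exponent of -1.
#'
#' @param genome_length total genome length in bp, split evenly over
#'   `chrom_names`.
#' @param chrom_names chromosome labels.
#' @param gc_content background GC fraction in [0, 1].
#' @param seed integer seed.
#' @param n_sites number of planted motif sites.
#' @param m2_fraction fraction of sites carrying the M2 motif.
#' @param m2_offset bp from the M1 center to the M2 start, 3' in motif
#'   orientation (> 0; default 21).
#' @param nrl nucleosome repeat length in bp (> 146).
#' @param dyad_jitter_sd s.d. of dyad placement jitter in bp (>= 0).
#' @param n_arrays_per_boundary phased nucleosomes per side of an anchor.
#' @param n_cells simulated cells (array realizations per anchor).
#' @param read_depth fragments per sample.
#' @param enrichment_factor fold IP-over-input density at bound sites
#'   (>= 1).
#' @param footprint_halfwidth protected half-width around an occupied
#'   site center, bp (> 0).
#' @param p_meth_accessible,p_meth_protected GpC methylation
#'   probabilities outside/inside a footprint, in [0, 1].
#' @param occupancy per-molecule probability that the site is occupied.
#' @param amplicon_length SMF amplicon length in bp.
#' @param n_molecules SMF molecules per amplicon.
#' @param hic_resolution Hi-C bin size in bp.
#' @param hic_n_bins number of Hi-C bins.
#' @param hic_depth expected total contact count.
#' @param ps_exponent distance-decay exponent (< 0).
#' @param tad_boundaries 0-based bin indices of TAD boundaries, sorted.
#' @param boundary_strength fold contact depletion across a boundary
#'   (> 0).
#' @param background_rate background fragments per planted nucleosomal
#'   fragment in the MNase simulator (0 disables background).
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(genome_length = 1e6, chrom_names = "chr1",
                             gc_content = 0.42, seed = 1L,
                             n_sites = 300L, m2_fraction = 0.25,
                             m2_offset = 21L, nrl = 182L,
                             dyad_jitter_sd = 10, n_arrays_per_boundary = 10L,
                             n_cells = 50L, read_depth = 1e6,
                             enrichment_factor = 8,
                             footprint_halfwidth = 15L,
                             p_meth_accessible = 0.8,
                             p_meth_protected = 0.1, occupancy = 0.5,
                             amplicon_length = 300L, n_molecules = 500L,
                             hic_resolution = 10000L, hic_n_bins = 400L,
                             hic_depth = 1e6, ps_exponent = -1,
                             tad_boundaries = NULL, boundary_strength = 2,
                             background_rate = 0.1) {
  cfg <- as.list(environment())
  probs <- c(gc_content, m2_fraction, p_meth_accessible, p_meth_protected,
             occupancy)
  if (any(probs < 0 | probs > 1)) stop_("probabilities must be in [0, 1]")
  if (m2_offset <= 0) stop_("m2_offset must be > 0")
  if (nrl <= 146) stop_("nrl must exceed the nucleosome core (146 bp)")
  if (dyad_jitter_sd < 0) stop_("dyad_jitter_sd must be >= 0")
  if (enrichment_factor < 1) stop_("enrichment_factor must be >= 1")
  if (footprint_halfwidth <= 0) stop_("footprint_halfwidth must be > 0")
  if (ps_exponent >= 0) stop_("ps_exponent must be < 0")
  if (boundary_strength <= 0) stop_("boundary_strength must be positive")
  if (!is.null(tad_boundaries) && is.unsorted(tad_boundaries))
    stop_("tad_boundaries must be sorted")
  structure(cfg, class = "synthetic_config")
}

# default planted PWMs: synthetic placeholder motifs (NOT the canonical
# CTCF MA0139.1 / M2 matrices -- deliberately non-canonical consensi with
# 0.85 weight on the consensus base); real matrices may be supplied.
default_m1_pwm <- function() placeholder_pwm("GTACCAGTTGGCAACTGGA")
default_m2_pwm <- function() placeholder_pwm("TAGCGCCTA")

placeholder_pwm <- function(consensus) {
  b <- strsplit(consensus, "")[[1]]
  m <- matrix(0.05, 4L, length(b), dimnames = list(DNA_BASES, NULL))
  m[cbind(match(b, DNA_BASES), seq_along(b))] <- 0.85
  m
}

rand_seq <- function(n, gc) {
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm, 2L, which.max)], collapse = "")
}

sample_from_pwm <- function(pwm) {
  p <- sweep(pwm, 2L, colSums(pwm), "/")
  idx <- apply(p, 2L, function(col) sample.int(4L, 1L, prob = col))
  paste(DNA_BASES[idx], collapse = "")
}

pwm_score_seq <- function(s, lo) {
  iv <- seq_to_int(s)
  sum(lo[cbind(iv, seq_along(iv))])
}

splice_seq <- function(s, at, insert) {
  # replace nchar(insert) bases of s starting at 0-based position `at`
  paste0(substr(s, 1L, at), insert,
         substr(s, at + nchar(insert) + 1L, nchar(s)))
}

#' Simulate a genome with planted motif sites
#'
#' Generates i.i.d. background sequence at the configured GC content and
#' plants `n_sites` non-overlapping motif instances with random
#' orientation.  Each M1 instance is sampled per-column from the M1 PWM
#' (giving graded motif scores); a fraction of sites additionally carry
#' an M2 instance whose start lies `m2_offset` bp 3' of the M1 center in
#' motif orientation.  Sites are spaced by at least `min_gap`.
#'
#' @param config a [synthetic_config()].
#' @param m1_pwm,m2_pwm 4 x width PFMs; defaults are the package's
#'   synthetic placeholder motifs (19 and 9 columns).
#' @param min_gap minimum distance between site centers (default 400 bp).
#' @return list with `genome` (named list of sequences) and `sites`, a
#'   data.frame `site_id, chrom, start, end, strand, center, m1_score,
#'   has_m2, m2_start` (coordinates of the M1 match, 0-based half-open;
#'   `m1_score` is the log2-odds PWM score of the planted instance).
#' @export
simulate_genome <- function(config, m1_pwm = default_m1_pwm(),
                            m2_pwm = default_m2_pwm(), min_gap = 400L) {
  stopifnot(inherits(config, "synthetic_config"))
  w1 <- ncol(m1_pwm); w2 <- ncol(m2_pwm)
  n_chr <- length(config$chrom_names)
  chr_len <- rep(config$genome_length %/% n_chr, n_chr)
  names(chr_len) <- config$chrom_names
  lo1 <- pwm_log_odds(m1_pwm)
  with_seed(config$seed, {
    genome <- lapply(chr_len, rand_seq, gc = config$gc_content)
    if (config$n_sites == 0L)
      return(list(genome = genome,
                  sites = cbind(empty_sites(w1),
                                data.frame(m1_score = numeric(),
                                           has_m2 = logical(),
                                           m2_start = integer())[0, ])))
    # capacity check: greedy placement on a per-chromosome grid
    margin <- w1 + config$m2_offset + w2 + 50L
    per_chr <- table(factor(sample(config$chrom_names, config$n_sites,
                                   replace = TRUE,
                                   prob = chr_len / sum(chr_len)),
                            levels = config$chrom_names))
    sites <- list()
    for (ch in config$chrom_names) {
      k <- per_chr[[ch]]
      if (k == 0L) next
      usable <- chr_len[[ch]] - 2L * margin
      if (usable < (k - 1L) * min_gap)
        stop_("genome too short to place %d non-overlapping sites on %s",
              k, ch)
      # jittered grid keeps placement O(n) and non-overlapping by design
      slot <- usable / k
      jit <- runif(k, 0, max(slot - min_gap, 1))
      centers <- as.integer(margin + slot * (seq_len(k) - 1L) + jit)
      strand <- ifelse(runif(k) < 0.5, "+", "-")
      has_m2 <- runif(k) < config$m2_fraction
      m1s <- numeric(k); m2start <- rep(NA_integer_, k)
      for (i in seq_len(k)) {
        inst1 <- sample_from_pwm(m1_pwm)
        inst2 <- pwm_consensus(m2_pwm)   # M2 is a binary presence label
        m1s[i] <- pwm_score_seq(inst1, lo1)
        start1 <- centers[i] - w1 %/% 2L     # center = start + floor(w/2)
        if (strand[i] == "+") {
          genome[[ch]] <- splice_seq(genome[[ch]], start1, inst1)
          if (has_m2[i]) {
            m2start[i] <- centers[i] + config$m2_offset
            genome[[ch]] <- splice_seq(genome[[ch]], m2start[i],
                                       inst2)
          }
        } else {
          genome[[ch]] <- splice_seq(genome[[ch]], start1, revcomp(inst1))
          if (has_m2[i]) {
            # M2 start m2_offset bp 3' of center in motif orientation:
            # on minus, 3' runs leftward and the oriented M2 start is the
            # rightmost base of the reverse-complemented instance
            m2start[i] <- centers[i] - config$m2_offset - w2 + 1L
            genome[[ch]] <- splice_seq(genome[[ch]], m2start[i],
                                       revcomp(inst2))
          }
        }
      }
      sites[[ch]] <- data.frame(chrom = ch, start = centers - w1 %/% 2L,
                                end = centers - w1 %/% 2L + w1,
                                strand = strand, center = centers,
                                m1_score = m1s, has_m2 = has_m2,
                                m2_start = m2start)
    }
    sites <- do.call(rbind, sites)
    sites <- sites[order(match(sites$chrom, config$chrom_names),
                         sites$start), ]
    sites$site_id <- sprintf("site_%05d", seq_len(nrow(sites)))
    rownames(sites) <- NULL
    list(genome = genome,
         sites = sites[c("site_id", "chrom", "start", "end", "strand",
                         "center", "m1_score", "has_m2", "m2_start")])
  })
}

#' Extract oriented site sequences
#'
#' Returns the `length`-bp window centered on each site, reverse
#' complemented for minus-strand sites so all sequences read in motif
#' orientation.
#'
#' @param genome named list of sequences.
#' @param sites site table with `chrom`, `center`, `strand`.
#' @param length window length (default 150).
#' @return Character vector of sequences (names = site ids).
#' @export
site_sequences <- function(genome, sites, length = 150L) {
  genome <- as_genome(genome)
  h <- length %/% 2L
  out <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    minus <- sites$strand[i] == "-"
    # oriented window spans relative -h .. h-1 on both strands
    s0 <- sites$center[i] - h + 1L + if (minus) 1L else 0L
    seqi <- substr(genome[[sites$chrom[i]]], s0, s0 + length - 1L)
    out[i] <- if (minus) revcomp(seqi) else seqi
  }
  names(out) <- sites$site_id
  out
}

#' Simulate phased nucleosomal fragments
#'
#' For every cell and anchor, dyads are placed at
#' `anchor +/- k * nrl + Normal(0, dyad_jitter_sd)` for
#' `k = 1..n_arrays_per_boundary` on both sides; each dyad emits one
#' fragment of length ~ Normal(147, 10) centered on the dyad, with both
#' strands equiprobable.  Uniform background fragments are added at
#' `background_rate` per planted fragment.
#'
#' @param genome_length chromosome length in bp.
#' @param anchors numeric vector of anchor positions (bp) on one
#'   chromosome.
#' @param config a [synthetic_config()]; uses `nrl`, `dyad_jitter_sd`,
#'   `n_arrays_per_boundary`, `n_cells`, `background_rate`, `seed`.
#' @param chrom chromosome label for the output table.
#' @return A [fragment_table()]; attribute `dyad_lattice` records the
#'   noise-free dyad positions.
#' @export
simulate_nucleosome_fragments <- function(genome_length, anchors, config,
                                          chrom = "chr1") {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_cells < 1L) stop_("n_cells must be >= 1")
  k <- seq_len(config$n_arrays_per_boundary)
  offsets <- c(-rev(k), k) * config$nrl
  lattice <- as.vector(outer(anchors, offsets, `+`))
  with_seed(config$seed + 1L, {
    dyads <- rep(lattice, config$n_cells) +
      if (config$dyad_jitter_sd > 0)
        rnorm(length(lattice) * config$n_cells, 0, config$dyad_jitter_sd)
      else 0
    len <- pmax(50L, as.integer(round(rnorm(length(dyads), 147, 10))))
    start <- as.integer(round(dyads)) - len %/% 2L
    nbg <- as.integer(round(config$background_rate * length(dyads)))
    if (nbg > 0L) {
      blen <- pmax(50L, as.integer(round(rnorm(nbg, 147, 10))))
      bstart <- as.integer(floor(runif(nbg, 0, genome_length - blen)))
      start <- c(start, bstart); len <- c(len, blen)
    }
    keep <- start >= 0L & start + len <= genome_length
    start <- start[keep]; len <- len[keep]
    strand <- ifelse(runif(length(start)) < 0.5, "+", "-")
    ft <- fragment_table(chrom, start, start + len, strand,
                         sample_label = "mnase_sim")
    attr(ft, "dyad_lattice") <- lattice
    ft
  })
}

#' Simulate IP and input fragment tables
#'
#' The input sample is uniform over the genome.  The IP sample draws
#' exactly `read_depth` fragments from a density that is 1 per bp
#' outside and `enrichment_factor` per bp inside the 251-bp windows of
#' bound sites, so the expected IP/input *density* ratio is the
#' enrichment factor at bound sites and 1 at decoys.  Because the
#' enrichment score normalizes by library size, the measured bound-site
#' log2 enrichment has the closed form `log2(F * L / Z)` with
#' `Z = L + n_bound (F - 1) w`; see the package vignette.
#'
#' @param sites site table (`chrom`, `center`).
#' @param config a [synthetic_config()]; uses `read_depth`,
#'   `enrichment_factor`, `genome_length`, `chrom_names`, `seed`.
#' @param bound logical vector marking truly bound sites (default all).
#' @param window site window width (default 251).
#' @return list `ip`, `input` of [fragment_table()]s (each of exactly
#'   `read_depth` fragments; depth 0 gives empty tables flagged in the
#'   `sample_label`), and `bound` echoing the ground truth.
#' @export
simulate_ip_fragments <- function(sites, config,
                                  bound = rep(TRUE, nrow(sites)),
                                  window = 251L) {
  stopifnot(inherits(config, "synthetic_config"))
  D <- as.integer(config$read_depth)
  n_chr <- length(config$chrom_names)
  chr_len <- rep(config$genome_length %/% n_chr, n_chr)
  names(chr_len) <- config$chrom_names
  L <- sum(chr_len)
  FF <- config$enrichment_factor
  h <- (window - 1L) %/% 2L
  bsites <- sites[bound, , drop = FALSE]
  if (D == 0L) {
    e <- fragment_table(character(), integer(), integer(),
                        sample_label = "empty (depth 0)")
    return(list(ip = e, input = e, bound = bound))
  }
  with_seed(config$seed + 2L, {
    mk_uniform <- function(n) {
      ch <- sample(config$chrom_names, n, replace = TRUE,
                   prob = chr_len / L)
      len <- pmax(60L, as.integer(round(rnorm(n, 200, 20))))
      mid <- as.integer(floor(runif(n, 0, chr_len[ch])))
      start <- pmax(0L, mid - len %/% 2L)
      list(chrom = ch, start = start, end = start + len)
    }
    input <- mk_uniform(D)
    input <- fragment_table(input$chrom, input$start, input$end,
                            c("+", "-")[sample.int(2L, D, TRUE)],
                            sample_label = "input_sim")
    # IP: weight L over background, (F-1)*w extra per bound site
    extra_w <- nrow(bsites) * (FF - 1) * window
    n_site <- stats::rbinom(1L, D, extra_w / (L + extra_w))
    n_bg <- D - n_site
    bg <- mk_uniform(n_bg)
    chs <- character(0); sts <- integer(0); ens <- integer(0)
    if (n_site > 0L) {
      pick <- sample.int(nrow(bsites), n_site, replace = TRUE)
      pos <- bsites$center[pick] +
        sample.int(window, n_site, replace = TRUE) - 1L - h
      len <- pmax(60L, as.integer(round(rnorm(n_site, 200, 20))))
      st <- pmax(0L, pos - len %/% 2L)
      chs <- bsites$chrom[pick]; sts <- st; ens <- st + len
    }
    ip <- fragment_table(c(bg$chrom, chs), c(bg$start, sts),
                         c(bg$end, ens),
                         c("+", "-")[sample.int(2L, D, TRUE)],
                         sample_label = "ip_sim")
    list(ip = ip, input = input, bound = bound)
  })
}

#' Simulate single-molecule footprinting calls
#'
#' For each molecule over the amplicon centered on a site, the molecule
#' is occupied with probability `occupancy`; every unambiguous GpC
#' position is methylated with `p_meth_protected` when it lies within
#' `footprint_halfwidth` of the center of an occupied site, and with
#' `p_meth_accessible` otherwise.
#'
#' @param genome named list of sequences.
#' @param site one site row (`chrom`, `center`) around which the
#'   amplicon is placed.
#' @param config a [synthetic_config()].
#' @return list with `calls` (data.frame `molecule_id, position,
#'   is_methylated, context`), `amplicon` (`c(start, end)`), and
#'   `occupied` (per-molecule ground truth).  An amplicon without GpC
#'   positions returns empty calls with a warning.
#' @export
simulate_smf_molecules <- function(genome, site, config) {
  stopifnot(inherits(config, "synthetic_config"))
  genome <- as_genome(genome)
  half <- config$amplicon_length %/% 2L
  amp <- c(site$center - half, site$center + half)
  s <- genome[[site$chrom]]
  cand <- which(strsplit(substr(s, amp[1] + 1L, amp[2]), "")[[1]] == "C") +
    amp[1] - 1L
  ctx <- classify_contexts(s, cand, strand = "+")
  gpc <- cand[ctx$context == "GpC"]
  if (!length(gpc)) {
    warn_("amplicon has no unambiguous GpC position")
    return(list(calls = data.frame(molecule_id = integer(),
                                   position = integer(),
                                   is_methylated = integer(),
                                   context = character()),
                amplicon = amp, occupied = logical(0)))
  }
  with_seed(config$seed + 3L, {
    nm <- config$n_molecules
    occupied <- runif(nm) < config$occupancy
    inside <- abs(gpc - site$center) <= config$footprint_halfwidth
    p <- outer(occupied, inside, function(o, i)
      ifelse(o & i, config$p_meth_protected, config$p_meth_accessible))
    meth <- matrix(runif(nm * length(gpc)) < p, nm)
    list(calls = data.frame(
           molecule_id = rep(seq_len(nm), each = length(gpc)),
           position = rep(gpc, nm),
           is_methylated = as.integer(t(meth)),
           context = "GpC"),
         amplicon = amp, occupied = occupied)
  })
}

#' Simulate a TAD-structured contact matrix
#'
#' Expected counts between bins i and j follow a power-law distance
#' decay `C * max(|i-j|, 1)^ps_exponent`, divided by `boundary_strength`
#' for every TAD boundary the pair straddles; `C` scales the matrix to
#' the configured depth.  Counts are Poisson-sampled unless `noiseless`,
#' in which case the expected values themselves are returned (for exact
#' analytic tests).
#'
#' @param config a [synthetic_config()]; uses `hic_n_bins`,
#'   `hic_resolution`, `hic_depth`, `ps_exponent`, `tad_boundaries`,
#'   `boundary_strength`, `seed`.
#' @param noiseless emit expected values instead of Poisson samples.
#' @return A [contact_matrix()]; attributes `expected_decay` (the
#'   analytic decay by distance, for [observed_over_expected()]'s
#'   `expected` argument) and `tad_boundaries` record the ground truth.
#' @export
simulate_contact_matrix <- function(config, noiseless = FALSE) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$hic_n_bins
  d <- abs(row(diag(n)) - col(diag(n)))
  base <- pmax(d, 1)^config$ps_exponent
  bnd <- config$tad_boundaries %||% integer(0)
  if (length(bnd)) {
    # pair (i,j), i<j straddles boundary b when i <= b < j (0-based bins)
    i0 <- pmin(row(diag(n)), col(diag(n))) - 1L
    j0 <- pmax(row(diag(n)), col(diag(n))) - 1L
    crossings <- Reduce(`+`, lapply(bnd, function(b)
      (i0 <= b) & (j0 > b)))
    base <- base / config$boundary_strength^crossings
  }
  C <- config$hic_depth / sum(base)
  expected <- C * base
  counts <- if (noiseless) expected else with_seed(config$seed + 4L, {
    ut <- upper.tri(expected, diag = TRUE)
    m <- matrix(0, n, n)
    m[ut] <- rpois(sum(ut), expected[ut])
    m + t(m) - diag(diag(m))
  })
  cm <- contact_matrix(counts, resolution = config$hic_resolution,
                       chrom = config$chrom_names[1])
  attr(cm, "expected_decay") <- C * pmax(0:(n - 1L), 1)^config$ps_exponent
  attr(cm, "tad_boundaries") <- bnd
  cm
}

#' Simulate per-site binding-change labels
#'
#' Ground-truth labels for the sequence model:
#' `delta = a * standardize(m1_score) + b * has_m2 + Normal(0, noise_sd)`.
#'
#' @param sites site table with `m1_score` and `has_m2`.
#' @param a,b coefficients on the standardized M1 score and the M2
#'   indicator.
#' @param noise_sd Gaussian noise s.d. (>= 0).
#' @param seed integer seed.
#' @return `sites` with a `delta` column; attributes `coefficients` and
#'   `noise_sd` record the generative truth.
#' @export
simulate_binding_response <- function(sites, a = 0.5, b = 0.8,
                                      noise_sd = 0.3, seed = 1L) {
  if (!all(c("m1_score", "has_m2") %in% names(sites)))
    stop_("sites must carry m1_score and has_m2")
  if (noise_sd < 0) stop_("noise_sd must be >= 0")
  z <- as.numeric(scale(sites$m1_score))
  if (anyNA(z)) z <- rep(0, nrow(sites))   # constant scores
  delta <- a * z + b * as.numeric(sites$has_m2)
  if (noise_sd > 0)
    delta <- delta + with_seed(seed + 5L, rnorm(nrow(sites), 0, noise_sd))
  sites$delta <- delta
  attr(sites, "coefficients") <- c(a = a, b = b)
  attr(sites, "noise_sd") <- noise_sd
  sites
}

#' Write a site table as BED6+
#'
#' BED6 columns are `chrom, start, end, name = site_id, score =
#' round(100 * m1_score), strand`; any further columns (`pwm_score`,
#' `bound`, `enrichment`, responses) are appended.
#'
#' @param sites site table.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_sites_bed <- function(sites, path) {
  score <- if (!is.null(sites$m1_score)) round(sites$m1_score * 100)
           else if (!is.null(sites$pwm_score)) round(sites$pwm_score * 100)
           else 0L
  extra <- setdiff(names(sites), c("site_id", "chrom", "start", "end",
                                   "strand", "center"))
  bed <- data.frame(sites$chrom, sites$start, sites$end, sites$site_id,
                    score, sites$strand)
  if (length(extra)) bed <- cbind(bed, sites[extra])
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
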