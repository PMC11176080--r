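#' Anchor intervals for oriented profiles
#'
#' Anchors are motif matches or other reference points given as 0-based
#' half-open intervals with a strand.  The anchor center, relative
#' position 0 of every profile, is `start + floor(width/2)`.
#'
#' @param x data.frame with columns `chrom`, `start`, `end` and optionally
#'   `strand` (default `"+"`) and `site_id`.
#' @return The data.frame with a `center` column added and ids filled in.
#' @export
as_anchors <- function(x) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  x <- as.data.frame(x)
  if (is.null(x$strand)) x$strand <- "+"
  if (is.null(x$site_id)) x$site_id <- sprintf("site_%05d", seq_len(nrow(x)))
  x$center <- x$start + (x$end - x$start) %/% 2L
  x
}

#' Motif-anchored signal profile matrix
#'
#' Counts fragment signal in a window centered on each oriented anchor,
#' producing a sites-by-positions matrix.  Relative position 0 is the
#' anchor center and positive positions are 3' of the motif: profiles at
#' minus-strand anchors have their position axis reversed before
#' stacking, so all rows share one motif-oriented coordinate system.
#'
#' @param fragments a [fragment_table()].
#' @param anchors oriented intervals (see [as_anchors()]).
#' @param window window width in bp (even, default 2000); relative
#'   positions span `-window/2 .. window/2 - 1`.
#' @param mode `"midpoint"` counts each fragment once at
#'   `start + floor(length/2)` (the half-insert shift used for MNase
#'   midpoints); `"five_prime"` counts the strand-aware 5' end;
#'   `"full_cover"` increments every position covered by the fragment.
#' @return A `signal_profile` object: matrix `values` (sites x positions),
#'   integer `positions`, `site_id`, a `skipped` count of anchors whose
#'   window ran off the chromosome, the source `library_size` and a
#'   `normalization` provenance tag (initially `"raw"`).
#' @details Chromosome bounds are taken from the fragments present: an
#'   anchor window is only dropped when it extends below coordinate 0
#'   (fragment tables carry no chromosome lengths); callers with explicit
#'   chromosome sizes should pre-filter anchors.
#' @examples
#' fr <- fragment_table("chr1", 100L, 148L)     # midpoint 124
#' an <- as_anchors(data.frame(chrom = "chr1", start = 124L, end = 125L))
#' p <- anchored_profile(fr, an, window = 50L)
#' p$values[1, p$positions == 0]                # the single count at 0
#' @export
anchored_profile <- function(fragments, anchors,
                             window = 2000L,
                             mode = c("midpoint", "five_prime", "full_cover")) {
  mode <- match.arg(mode)
  window <- as.integer(window)
  if (window %% 2L != 0L || window < 2L) stop_("window must be even and >= 2")
  anchors <- as_anchors(anchors)
  h <- window %/% 2L
  positions <- seq.int(-h, h - 1L)
  n_sites <- nrow(anchors)
  values <- matrix(0, n_sites, window,
                   dimnames = list(anchors$site_id, positions))
  skipped <- 0L

  by_chr <- split(seq_len(nrow(fragments)), fragments$chrom)
  pt <- switch(mode,
               midpoint = frag_midpoint(fragments),
               five_prime = frag_five_prime(fragments),
               full_cover = NULL)

  for (i in seq_len(n_sites)) {
    ctr <- anchors$center[i]
    minus <- identical(anchors$strand[i], "-")
    lo <- if (minus) ctr - h + 1L else ctr - h
    hi <- lo + window - 1L                       # inclusive genomic range
    if (lo < 0L) { skipped <- skipped + 1L; next }
    idx <- by_chr[[anchors$chrom[i]]]
    if (is.null(idx)) next
    if (mode == "full_cover") {
      s <- pmax(fragments$start[idx], lo)
      e <- pmin(fragments$end[idx] - 1L, hi)
      ok <- which(s <= e)
      if (!length(ok)) next
      cov <- numeric(window + 1L)
      a <- s[ok] - lo + 1L; b <- e[ok] - lo + 2L
      for (j in seq_along(a)) {
        cov[a[j]] <- cov[a[j]] + 1
        cov[b[j]] <- cov[b[j]] - 1
      }
      row <- cumsum(cov[seq_len(window)])
    } else {
      p <- pt[idx]
      inw <- p >= lo & p <= hi
      if (!any(inw)) next
      row <- tabulate(p[inw] - lo + 1L, nbins = window)
    }
    if (minus) row <- rev(row)
    values[i, ] <- values[i, ] + row
  }

  structure(list(values = values, positions = positions,
                 site_id = anchors$site_id, window = window, mode = mode,
                 skipped = skipped,
                 library_size = library_size(fragments),
                 sample_label = attr(fragments, "sample_label"),
                 normalization = "raw", smoothing_window = 1L),
            class = "signal_profile")
}

#' @export
print.signal_profile <- function(x, ...) {
  cat(sprintf(
    "signal_profile: %d sites x %d positions (%s, norm=%s, smooth=%d bp)\n",
    nrow(x$values), ncol(x$values), x$mode, x$normalization,
    x$smoothing_window))
  invisible(x)
}

#' Average (meta)profile of a signal profile matrix
#' @param x a `signal_profile`.
#' @param fun `"mean"` (per-site average) or `"sum"`.
#' @return Named numeric vector over relative positions.
#' @export
avg_profile <- function(x, fun = c("mean", "sum")) {
  fun <- match.arg(fun)
  v <- if (fun == "mean") colMeans(x$values) else colSums(x$values)
  stats::setNames(v, x$positions)
}

#' Centered running-mean smoothing
#'
#' Centered moving average with an odd window; at the edges the window is
#' truncated to the available positions, so a constant input is returned
#' unchanged everywhere.  Profiles are typically smoothed with 21 bp
#' (ATAC/ChIP/MNase metaprofiles) or 51 bp (CUT&RUN).
#'
#' @param x numeric vector, matrix (rows smoothed), or `signal_profile`.
#' @param w odd window width, >= 1.
#' @return Object of the same shape; a `signal_profile` records `w` in
#'   `smoothing_window`.
#' @export
smooth_running_mean <- function(x, w = 21L) {
  w <- as.integer(w)
  if (w < 1L || w %% 2L == 0L)
    stop_("smoothing window must be odd and >= 1 (got %d)", w)
  if (inherits(x, "signal_profile")) {
    x$values <- smooth_running_mean(x$values, w)
    x$smoothing_window <- w
    return(x)
  }
  if (is.matrix(x)) return(t(apply(x, 1L, runmean_trunc, w = w)))
  runmean_trunc(x, w)
}

runmean_trunc <- function(x, w) {
  n <- length(x)
  if (w == 1L || n == 0L) return(x)
  h <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L); hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Depth and metaprofile normalization schemes
#'
#' Three schemes used for anchored profiles:
#' \describe{
#'   \item{`atac_x100`}{counts divided by library size, multiplied by 100.}
#'   \item{`chip_per_site_x1000`}{counts divided by library size, divided
#'     by the number of sites, multiplied by 1000 (metaprofile scale).}
#'   \item{`mnase_median`}{each co-normalized sample's profile is divided
#'     by its own median and multiplied by the median of all sample
#'     medians, so the samples share a common median; requires all
#'     samples to be supplied together.}
#' }
#' The multiplicative constants are display scalings; the scheme applied
#' is recorded in the `normalization` provenance tag.
#'
#' @param x a `signal_profile`, a numeric vector/matrix, or for
#'   `mnase_median` a list of these (one per sample).
#' @param scheme one of `"atac_x100"`, `"chip_per_site_x1000"`,
#'   `"mnase_median"`.
#' @param library_size,n_sites overrides for plain vectors/matrices;
#'   taken from the `signal_profile` otherwise.
#' @return Same shape as the input (a list for `mnase_median` given a
#'   list), with normalization provenance recorded on profiles.
#' @export
normalize_profile <- function(x, scheme = c("atac_x100", "mnase_median",
                                            "chip_per_site_x1000"),
                              library_size = NULL, n_sites = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "mnase_median") return(normalize_mnase_median(x))
  scale_one <- function(p) {
    if (inherits(p, "signal_profile")) {
      N <- library_size %||% p$library_size
      ns <- n_sites %||% nrow(p$values)
      p$values <- p$values / N * if (scheme == "atac_x100") 100 else 1000 / ns
      p$normalization <- scheme
      p
    } else {
      N <- library_size
      if (is.null(N)) stop_("library_size required for plain numeric input")
      if (scheme == "atac_x100") p / N * 100
      else {
        if (is.null(n_sites)) stop_("n_sites required for chip_per_site_x1000")
        p / N / n_sites * 1000
      }
    }
  }
  scale_one(x)
}

normalize_mnase_median <- function(x) {
  single <- !is.list(x) || inherits(x, "signal_profile")
  xs <- if (single) list(x) else x
  vecs <- lapply(xs, function(p)
    if (inherits(p, "signal_profile")) avg_profile(p) else p)
  meds <- vapply(vecs, stats::median, 0)
  if (any(meds == 0)) stop_("degenerate profile: median is 0")
  m <- stats::median(meds)
  out <- Map(function(p, v, md) {
    scaled <- v / md * m
    if (inherits(p, "signal_profile")) {
      p$values <- p$values / md * m
      p$normalization <- "mnase_median"
      p$avg <- scaled
      p
    } else scaled
  }, xs, vecs, meds)
  if (single) out[[1]] else out
}

#' Count fragments in fixed-width windows around intervals
#'
#' Fragments are assigned to a window by their (optionally half-insert
#' shifted) position; with `pseudo_log` the returned value is
#' `log2(n_norm + 8)`, where `n_norm` is the count scaled to the median
#' library size of the co-analyzed samples, so that enrichment over a
#' control is the difference of two such values.
#'
#' @param fragments a [fragment_table()].
#' @param intervals data.frame of regions of interest (centers used).
#' @param width window width in bp (default 250), centered on each
#'   interval center: `[center - floor(w/2), center + ceiling(w/2))`.
#' @param shift_half_insert if `TRUE` (default) fragments count at their
#'   midpoint (5' end shifted by half the insert); otherwise at the
#'   strand-aware 5' end.
#' @param pseudo_log return `log2(n_norm + 8)` instead of raw counts.
#' @param median_library_size the median library size over all samples in
#'   the analysis; defaults to this sample's own library size.
#' @return Numeric vector, one value per interval.
#' @export
count_in_windows <- function(fragments, intervals, width = 250L,
                             shift_half_insert = TRUE, pseudo_log = TRUE,
                             median_library_size = NULL) {
  width <- as.integer(width)
  if (width <= 0L) stop_("width must be positive")
  intervals <- as_anchors(intervals)
  p <- if (shift_half_insert) frag_midpoint(fragments)
       else frag_five_prime(fragments)
  n <- window_counts(fragments$chrom, p, intervals, width)
  if (!pseudo_log) return(n)
  N <- library_size(fragments)
  medN <- median_library_size %||% N
  n_norm <- if (N > 0) n / N * medN else n
  log2(n_norm + 8)
}

# shared midpoint-in-window counter: windows [center-floor(w/2),
# center+ceiling(w/2)) per interval, counts of positions p falling inside
window_counts <- function(chrom, p, intervals, width) {
  lo <- intervals$center - width %/% 2L
  hi <- lo + width - 1L
  out <- numeric(nrow(intervals))
  by_chr <- split(p, chrom)
  for (ch in unique(intervals$chrom)) {
    pv <- by_chr[[ch]]
    ii <- which(intervals$chrom == ch)
    if (is.null(pv) || !length(pv)) next
    pv <- sort(pv)
    out[ii] <- findInterval(hi[ii], pv) - findInterval(lo[ii] - 1L, pv)
  }
  out
}
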