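#' Pseudocount-stabilized ChIP enrichment
#'
#' The log2 enrichment of a region between two samples,
#' \deqn{e_i = \log_2 \frac{n_i/N_i \cdot \mathrm{median}(N) + c}
#'                         {n_j/N_j \cdot \mathrm{median}(N) + c},}
#' where \eqn{n_i, n_j} are the window counts in samples \eqn{i} (for
#' example an immunoprecipitation) and \eqn{j} (its input), \eqn{N_i,
#' N_j} the library sizes, median(N) the median library size over all
#' co-analyzed samples, and \eqn{c} a pseudocount (default 8) that damps
#' noise at low counts.  The same formula scores IP-versus-input
#' enrichment and changes between two immunoprecipitated samples.
#'
#' @param n_i,n_j region counts (vectors allowed).
#' @param N_i,N_j library sizes, > 0.
#' @param median_N median library size across the sample set.
#' @param pseudocount pseudocount c > 0, default 8.
#' @return Numeric log2 enrichment.
#' @examples
#' chip_enrichment(92, 1e6, 10, 1e6, 1e6)   # log2(100/18)
#' @export
chip_enrichment <- function(n_i, N_i, n_j, N_j,
                            median_N = stats::median(c(N_i, N_j)),
                            pseudocount = 8) {
  if (any(N_i <= 0) || any(N_j <= 0)) stop_("library sizes must be > 0")
  if (any(n_i < 0) || any(n_j < 0)) stop_("counts must be >= 0")
  if (pseudocount <= 0) stop_("pseudocount must be > 0")
  log2((n_i / N_i * median_N + pseudocount) /
       (n_j / N_j * median_N + pseudocount))
}

#' Enrichment model parameters
#'
#' Bundles the constants of the enrichment/bound-calling stage: the
#' pseudocount, the window width centered on the motif, the bound-call
#' threshold in log2 units (at least 1.0, i.e. twofold), and optionally a
#' fixed median library size shared across an analysis.
#'
#' @param pseudocount pseudocount, > 0 (default 8).
#' @param window odd window width in bp (default 251).
#' @param bound_threshold log2 enrichment at or above which a motif is
#'   called bound (default 1.0).
#' @param median_library_size optional fixed median(N); when `NULL` it is
#'   recomputed from the samples supplied to each call.
#' @return An `enrichment_model` list.
#' @export
enrichment_model <- function(pseudocount = 8, window = 251L,
                             bound_threshold = 1.0,
                             median_library_size = NULL) {
  window <- as.integer(window)
  if (pseudocount <= 0) stop_("pseudocount must be > 0")
  if (window %% 2L == 0L) stop_("window must be odd")
  structure(list(pseudocount = pseudocount, window = window,
                 bound_threshold = bound_threshold,
                 median_library_size = median_library_size),
            class = "enrichment_model")
}

# counts at site windows: the model's odd window is centered on the motif
# center as [center - h, center + h] with h = (window-1)/2; fragments are
# assigned by midpoint.
site_window_counts <- function(sites, fragments, window) {
  sites <- as_anchors(sites)
  h <- (window - 1L) %/% 2L
  p <- frag_midpoint(fragments)
  lo <- sites$center - h; hi <- sites$center + h
  out <- numeric(nrow(sites))
  by_chr <- split(p, fragments$chrom)
  for (ch in unique(sites$chrom)) {
    pv <- by_chr[[ch]]
    ii <- which(sites$chrom == ch)
    if (is.null(pv) || !length(pv)) next
    pv <- sort(pv)
    out[ii] <- findInterval(hi[ii], pv) - findInterval(lo[ii] - 1L, pv)
  }
  out
}

#' Call bound motif sites from IP and input fragments
#'
#' Counts IP and input fragments in a window centered on each motif,
#' scores [chip_enrichment()] and flags sites whose log2 enrichment is at
#' least the model's threshold as bound.
#'
#' @param sites motif site table (from [scan_pwm()] or the generator).
#' @param ip,input [fragment_table()]s for the immunoprecipitated and
#'   input samples.
#' @param model an [enrichment_model()].
#' @return `sites` with columns `enrichment` and `bound` added.
#' @export
call_bound <- function(sites, ip, input, model = enrichment_model()) {
  n_i <- site_window_counts(sites, ip, model$window)
  n_j <- site_window_counts(sites, input, model$window)
  N_i <- library_size(ip); N_j <- library_size(input)
  medN <- model$median_library_size %||% stats::median(c(N_i, N_j))
  sites$enrichment <- chip_enrichment(n_i, N_i, n_j, N_j, medN,
                                      model$pseudocount)
  sites$bound <- sites$enrichment >= model$bound_threshold
  sites
}

#' Between-condition binding and accessibility response scores
#'
#' Per site, the change in ChIP enrichment between mutant and wild-type
#' IPs and the change in accessibility between mutant and wild-type ATAC
#' samples, both via the same pseudocount formula and expressed as log2
#' fold changes with respect to the wild-type control.
#'
#' @param sites motif site table.
#' @param ip_mut,ip_wt,atac_mut,atac_wt [fragment_table()]s; all four are
#'   required.
#' @param model an [enrichment_model()]; median(N) is computed per assay
#'   pair unless fixed in the model.
#' @return `sites` with columns `delta_chip` and `delta_atac` added.
#' @export
response_scores <- function(sites, ip_mut, ip_wt, atac_mut, atac_wt,
                            model = enrichment_model()) {
  for (nm in c("ip_mut", "ip_wt", "atac_mut", "atac_wt"))
    if (is.null(get(nm)) || !inherits(get(nm), "fragment_table"))
      stop_("missing or invalid sample: %s", nm)
  pair_score <- function(a, b) {
    n_a <- site_window_counts(sites, a, model$window)
    n_b <- site_window_counts(sites, b, model$window)
    N_a <- library_size(a); N_b <- library_size(b)
    medN <- model$median_library_size %||% stats::median(c(N_a, N_b))
    chip_enrichment(n_a, N_a, n_b, N_b, medN, model$pseudocount)
  }
  sites$delta_chip <- pair_score(ip_mut, ip_wt)
  sites$delta_atac <- pair_score(atac_mut, atac_wt)
  sites
}
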