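#' k-means clustering of site response profiles
#'
#' Clusters sites by their accessibility and binding responses (log2
#' fold changes) using Lloyd's algorithm with k-means++ initialization,
#' keeping the best of several restarts by total within-cluster sum of
#' squares.  Clusters are relabeled in decreasing order of mean
#' `delta_atac` so that the numbering is reproducible across seeds.
#'
#' @param table data.frame with feature columns (default `delta_atac`,
#'   `delta_chip`); all features must be finite.
#' @param k number of clusters (default 5).
#' @param seed integer seed.
#' @param n_restarts restarts, best kept (default 25).
#' @param features feature column names.
#' @param scale_features z-score features first (default `FALSE`; log2
#'   fold changes are already commensurate).
#' @param iter_max Lloyd iterations per restart.
#' @return `table` with a `cluster` column (1..k), plus attributes
#'   `centers` and `tot_withinss`.
#' @export
kmeans_cluster <- function(table, k = 5L, seed = 1L, n_restarts = 25L,
                           features = c("delta_atac", "delta_chip"),
                           scale_features = FALSE, iter_max = 100L) {
  x <- as.matrix(table[, features, drop = FALSE])
  if (!all(is.finite(x))) stop_("features contain non-finite values")
  if (k < 2L) stop_("k must be >= 2")
  if (k > nrow(x)) stop_("k (%d) exceeds the number of sites (%d)", k, nrow(x))
  if (scale_features) x <- scale(x)
  fit <- with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      ctrs <- kmeanspp_init(x, k)
      km <- suppressWarnings(
        stats::kmeans(x, centers = ctrs, iter.max = iter_max,
                      algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best
  })
  # relabel by decreasing mean delta_atac (first feature as tie-break axis)
  key <- if ("delta_atac" %in% features) "delta_atac" else features[1]
  mu <- tapply(table[[key]], fit$cluster, mean)
  ord <- order(-mu)
  relab <- integer(k); relab[as.integer(names(mu))[ord]] <- seq_len(k)
  table$cluster <- relab[fit$cluster]
  attr(table, "centers") <- fit$centers[as.integer(names(mu))[ord], ,
                                        drop = FALSE]
  attr(table, "tot_withinss") <- fit$tot.withinss
  table
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance to the nearest chosen center
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) {
      centers[j, ] <- x[sample.int(n, 1L), ]
    } else {
      pick <- sample.int(n, 1L, prob = d2)
      centers[j, ] <- x[pick, ]
      d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                         byrow = TRUE))^2))
    }
  }
  # jitter exact duplicates minimally so stats::kmeans accepts the centers
  dup <- duplicated(centers)
  if (any(dup))
    centers[dup, ] <- centers[dup, , drop = FALSE] +
      matrix(stats::rnorm(sum(dup) * ncol(x), 0, 1e-9), sum(dup))
  centers
}

#' Within-cluster sum of squares across k (elbow scan)
#'
#' Runs [kmeans_cluster()] for each k in a range and returns the total
#' within-cluster sum of squares, for choosing k by the elbow criterion;
#' no automatic choice is made.
#'
#' @inheritParams kmeans_cluster
#' @param k_range integer vector of k values (within `2..n-1`; `k = n`
#'   is allowed and gives WCSS 0 for distinct points).
#' @return data.frame with columns `k` and `wcss`.
#' @export
elbow_scan <- function(table, k_range = 2:10, seed = 1L, n_restarts = 10L,
                       features = c("delta_atac", "delta_chip")) {
  wcss <- vapply(k_range, function(k) {
    fit <- kmeans_cluster(table, k = k, seed = seed, n_restarts = n_restarts,
                          features = features)
    attr(fit, "tot_withinss")
  }, 0)
  data.frame(k = as.integer(k_range), wcss = wcss)
}

#' Persistent-binding site groups by accessibility change
#'
#' Selects sites whose binding change is within a linear fold-change
#' window (default [0.8, 1.2], i.e. less than 20 percent variation in
#' binding; endpoints included) and splits the persistent set into
#' groups by `delta_atac` quantile: group 1 has the least accessibility
#' loss, the last group the strongest loss.
#'
#' @param table data.frame with `delta_chip` and `delta_atac` (log2 FC).
#' @param fc_window closed linear fold-change interval, default
#'   `c(0.8, 1.2)`.
#' @param n_groups number of quantile groups (default 4).
#' @return `table` with logical `persistent` and integer `group`
#'   (`NA` for non-persistent sites) columns.
#' @export
persistent_groups <- function(table, fc_window = c(0.8, 1.2), n_groups = 4L) {
  fc <- 2^table$delta_chip
  # closed interval; the relative tolerance absorbs the one-ulp error of
  # the log2/exp2 round trip so boundary fold changes stay included
  persistent <- fc >= fc_window[1] * (1 - 1e-9) &
    fc <= fc_window[2] * (1 + 1e-9)
  np <- sum(persistent)
  if (np < n_groups)
    stop_("persistent set (%d sites) smaller than n_groups (%d)", np,
          n_groups)
  grp <- rep(NA_integer_, nrow(table))
  r <- rank(-table$delta_atac[persistent], ties.method = "first")
  grp[persistent] <- as.integer(ceiling(r * n_groups / np))
  table$persistent <- persistent
  table$group <- grp
  table
}

#' Annotate sites with chromatin states by priority
#'
#' Assigns each site the highest-priority chromatin state it overlaps.
#' State labels are first streamlined through a merge map (for example
#' strong/weak enhancer states into `Enhancer` and
#' heterochromatin/repressed states into `RepressedChromatin`); sites
#' without any overlap are `Intergenic`.
#'
#' @param sites data.frame with `chrom`, `start`, `end`.
#' @param state_intervals data.frame with `chrom`, `start`, `end`,
#'   `state` (labeled BED).
#' @param priority ordered labels, highest priority first; default
#'   `ActivePromoter, BivalentChromatin, Enhancer, RepressedChromatin,
#'   Insulator, Intergenic`.
#' @param merge_map named character vector mapping raw labels to merged
#'   ones; unknown labels (after merging, not in `priority`) are an
#'   error listing them.
#' @return Character vector of state labels, one per site.
#' @export
annotate_state <- function(sites, state_intervals,
                           priority = c("ActivePromoter",
                                        "BivalentChromatin", "Enhancer",
                                        "RepressedChromatin", "Insulator",
                                        "Intergenic"),
                           merge_map = c(StrongEnhancer = "Enhancer",
                                         WeakEnhancer = "Enhancer",
                                         Heterochromatin = "RepressedChromatin",
                                         Repressed = "RepressedChromatin")) {
  st <- as.character(state_intervals$state)
  mapped <- ifelse(st %in% names(merge_map), merge_map[st], st)
  unknown <- setdiff(unique(mapped), priority)
  if (length(unknown))
    stop_("unknown state label(s): %s", paste(unknown, collapse = ", "))
  prio <- match(mapped, priority)
  out <- rep("Intergenic", nrow(sites))
  for (ch in unique(sites$chrom)) {
    si <- which(sites$chrom == ch)
    ti <- which(state_intervals$chrom == ch)
    if (!length(ti)) next
    q <- IRanges::IRanges(sites$start[si] + 1L, sites$end[si])
    s <- IRanges::IRanges(state_intervals$start[ti] + 1L,
                          state_intervals$end[ti])
    ov <- IRanges::findOverlaps(q, s)
    if (!length(ov)) next
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    best <- tapply(prio[ti][sh], qh, min)
    out[si[as.integer(names(best))]] <- priority[best]
  }
  out
}
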