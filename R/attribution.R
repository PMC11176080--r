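#' Dinucleotide-preserving sequence shuffle
#'
#' Generates shuffles of a sequence that preserve the exact dinucleotide
#' count multiset (and hence mononucleotide counts), by sampling a
#' random Euler path through the dinucleotide multigraph: for every
#' vertex except the terminal one a final exit edge is drawn and
#' accepted when the final edges form an arborescence into the terminal
#' vertex, the remaining edge lists are permuted uniformly, and the walk
#' is read off.  Such shuffles are the reference sequences for
#' attribution (100 per site by default, matching common practice).
#' Segments separated by `N` are shuffled independently.
#'
#' @param sequence string over `ACGTN`.
#' @param n_shuffles number of shuffles.
#' @param seed integer seed.
#' @return Character vector of `n_shuffles` sequences.
#' @export
dinucleotide_shuffle <- function(sequence, n_shuffles = 100L, seed = 1L) {
  has_n <- grepl("N", sequence, fixed = TRUE)
  with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      if (!has_n) return(euler_shuffle_one(sequence))
      runs <- regmatches(sequence,
                         gregexpr("[^N]+", sequence))[[1]]
      rebuild_with_N(sequence, vapply(runs, euler_shuffle_one, ""))
    }, "")
  })
}

# reassemble shuffled non-N runs into the original N skeleton
rebuild_with_N <- function(sequence, shuffled_runs) {
  chars <- strsplit(sequence, "")[[1]]
  is_n <- chars == "N"
  out <- chars
  ri <- 0L; i <- 1L
  n <- length(chars)
  while (i <= n) {
    if (!is_n[i]) {
      j <- i
      while (j <= n && !is_n[j]) j <- j + 1L
      ri <- ri + 1L
      out[i:(j - 1L)] <- strsplit(shuffled_runs[ri], "")[[1]]
      i <- j
    } else i <- i + 1L
  }
  paste(out, collapse = "")
}

euler_shuffle_one <- function(s) {
  n <- nchar(s)
  if (n <= 2L) return(s)
  b <- strsplit(s, "")[[1]]
  verts <- unique(b)
  if (length(verts) == 1L) return(s)
  from <- b[-n]; to <- b[-1]
  root <- b[n]
  # per-vertex outgoing edge targets
  out_edges <- split(to, from)
  repeat {
    last_edge <- vapply(verts, function(u) {
      es <- out_edges[[u]]
      if (is.null(es) || u == root) NA_character_
      else es[sample.int(length(es), 1L)]
    }, "")
    names(last_edge) <- verts
    if (arborescence_ok(last_edge, root, verts)) break
  }
  # permute remaining edges; designated last edge goes last
  lists <- lapply(verts, function(u) {
    es <- out_edges[[u]]
    if (is.null(es)) return(character(0))
    if (u != root) {
      drop1 <- match(last_edge[[u]], es)
      rest <- es[-drop1]
      c(if (length(rest)) rest[sample.int(length(rest))] else character(0),
        last_edge[[u]])
    } else {
      es[sample.int(length(es))]
    }
  })
  names(lists) <- verts
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  res <- character(n)
  cur <- b[1]
  res[1] <- cur
  for (i in 2L:n) {
    nxt <- lists[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    res[i] <- nxt
    cur <- nxt
  }
  paste(res, collapse = "")
}

# do the chosen last edges lead every vertex (with out-edges) to the root?
arborescence_ok <- function(last_edge, root, verts) {
  for (u in verts) {
    if (u == root || is.na(last_edge[[u]])) next
    seen <- character(0)
    cur <- u
    while (cur != root) {
      if (cur %in% seen) return(FALSE)
      seen <- c(seen, cur)
      cur <- last_edge[[cur]]
      if (is.na(cur)) return(FALSE)
    }
  }
  TRUE
}

#' Per-nucleotide contribution scores
#'
#' Computes contribution scores of every nucleotide of each sequence for
#' a trained model, against dinucleotide-shuffled reference sequences.
#'
#' `method = "expected_gradients"` integrates the input gradient along
#' the straight path from each reference to the input (midpoint rule
#' with `n_steps` points) and averages `(input - reference) * gradient`
#' over references — a SHAP-style reference-based attribution whose
#' scores sum to approximately `f(input) - mean f(references)`
#' (completeness).  `method = "ism"` is the model-agnostic in-silico
#' mutagenesis oracle: the per-position score is the prediction of the
#' original sequence minus the mean prediction over the three possible
#' substitutions, placed at the observed base.
#'
#' @param model a trained [train_cnn()] model.
#' @param sequences character vector of oriented input-length sequences.
#' @param references optional list (one element per sequence) of
#'   reference sequence vectors; generated by [dinucleotide_shuffle()]
#'   when `NULL`.
#' @param method `"expected_gradients"` or `"ism"`.
#' @param n_refs references per sequence when generating (default 100).
#' @param n_steps interpolation points per reference (default 16).
#' @param seed seed for reference generation.
#' @return An `attribution_set`: list with `scores` (per sequence a
#'   4 x length matrix, rows A,C,G,T), `method`, `f_x` (model output per
#'   sequence) and `f_ref_mean` (mean reference output;
#'   expected-gradients only).
#' @export
attribute <- function(model, sequences, references = NULL,
                      method = c("expected_gradients", "ism"),
                      n_refs = 100L, n_steps = 16L, seed = 1L) {
  method <- match.arg(method)
  if (!inherits(model, "ctcf_cnn") || is.null(model$params))
    stop_("model must be a trained ctcf_cnn")
  L <- model$spec$input_length
  f_x <- predict(model, sequences)
  if (method == "ism") {
    scores <- lapply(seq_along(sequences), function(i)
      ism_scores(model, sequences[i], f_x[i]))
    return(structure(list(scores = scores, method = method, f_x = f_x,
                          f_ref_mean = NULL),
                     class = "attribution_set"))
  }
  if (is.null(references))
    references <- lapply(seq_along(sequences), function(i)
      dinucleotide_shuffle(sequences[i], n_refs, seed = seed + i))
  alphas <- (seq_len(n_steps) - 0.5) / n_steps
  scores <- vector("list", length(sequences))
  f_ref_mean <- numeric(length(sequences))
  for (i in seq_along(sequences)) {
    x <- t(one_hot(sequences[i], L))               # len x 4
    refs <- references[[i]]
    nr <- length(refs)
    Rarr <- one_hot_batch(refs, L)                 # len x 4 x nr
    f_ref_mean[i] <- mean(cnn_predict_arr(model$params, Rarr, model$spec))
    interp <- array(0, c(L, 4L, nr * n_steps))
    for (r in seq_len(nr)) {
      dxr <- x - Rarr[, , r]
      for (t in seq_len(n_steps))
        interp[, , (r - 1L) * n_steps + t] <- Rarr[, , r] + alphas[t] * dxr
    }
    g <- cnn_input_gradient(model, interp)
    contrib <- matrix(0, L, 4L)
    for (r in seq_len(nr)) {
      gm <- g[, , (r - 1L) * n_steps + seq_len(n_steps), drop = FALSE]
      avg_g <- apply(gm, c(1L, 2L), mean)
      contrib <- contrib + (x - Rarr[, , r]) * avg_g
    }
    scores[[i]] <- t(contrib / nr)                 # 4 x len
    rownames(scores[[i]]) <- DNA_BASES
  }
  structure(list(scores = scores, method = method, f_x = f_x,
                 f_ref_mean = f_ref_mean),
            class = "attribution_set")
}

ism_scores <- function(model, sequence, f0) {
  L <- model$spec$input_length
  b <- strsplit(sequence, "")[[1]]
  muts <- character(0); pos <- integer(0)
  for (p in seq_len(L)) {
    others <- setdiff(DNA_BASES, b[p])
    for (o in others) {
      s2 <- b; s2[p] <- o
      muts <- c(muts, paste(s2, collapse = ""))
      pos <- c(pos, p)
    }
  }
  fm <- predict(model, muts)
  per_pos <- tapply(fm, pos, mean)
  sc <- matrix(0, 4L, L, dimnames = list(DNA_BASES, NULL))
  iv <- seq_to_int(sequence)
  ok <- which(!is.na(iv))
  sc[cbind(iv[ok], ok)] <- f0 - per_pos[as.character(ok)]
  sc
}

#' @export
print.attribution_set <- function(x, ...) {
  cat(sprintf("attribution_set: %d sequences, method = %s\n",
              length(x$scores), x$method))
  invisible(x)
}

#' Contribution weight matrix
#'
#' Summarizes per-sequence contribution tensors over aligned, oriented
#' sequences: cell (base, position) is the average contribution score at
#' that position over the sequences whose base there is that base.
#' Cells for bases never observed at a position are `NA`.
#'
#' @param attribution an [attribute()] result (or a list of 4 x length
#'   score matrices).
#' @param sequences the sequences the scores belong to, aligned at the
#'   motif center and oriented.
#' @return A `cwm` object: 4 x length matrix with rows A,C,G,T and an
#'   `n_obs` attribute of per-cell observation counts.
#' @export
contribution_weight_matrix <- function(attribution, sequences) {
  scores <- if (inherits(attribution, "attribution_set"))
    attribution$scores else attribution
  stopifnot(length(scores) == length(sequences))
  L <- ncol(scores[[1]])
  acc <- matrix(0, 4L, L, dimnames = list(DNA_BASES, NULL))
  cnt <- matrix(0L, 4L, L)
  for (i in seq_along(sequences)) {
    iv <- seq_to_int(sequences[i])
    ok <- which(!is.na(iv))
    ij <- cbind(iv[ok], ok)
    acc[ij] <- acc[ij] + scores[[i]][ij]
    cnt[ij] <- cnt[ij] + 1L
  }
  cwm <- acc / cnt
  cwm[cnt == 0L] <- NA
  structure(cwm, n_obs = cnt, class = c("cwm", "matrix", "array"))
}

#' @export
print.cwm <- function(x, ...) {
  cat(sprintf("cwm: 4 x %d contribution weight matrix (%.1f%% cells observed)\n",
              ncol(x), 100 * mean(attr(x, "n_obs") > 0)))
  invisible(x)
}

#' Plot a contribution weight matrix as stacked per-base profiles
#' @param x a `cwm`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cwm <- function(x, ...) {
  h <- ncol(x) %/% 2L
  graphics::matplot(seq.int(-h, h - 1L), t(unclass(x)), type = "l",
                    lty = 1, xlab = "position relative to motif center",
                    ylab = "contribution", ...)
  graphics::legend("topright", legend = rownames(x), col = 1:4, lty = 1,
                   cex = 0.8)
  invisible(x)
}

#' Fraction of absolute CWM mass in given windows
#'
#' @param cwm a [contribution_weight_matrix()].
#' @param windows list of `c(from, to)` relative-position ranges
#'   (inclusive, position 0 = motif center at column `ncol/2 + 1`).
#' @return Fraction of summed |contribution| (over observed cells)
#'   inside the windows.
#' @export
cwm_mass_fraction <- function(cwm, windows) {
  L <- ncol(cwm)
  h <- L %/% 2L
  rel <- seq.int(-h, h - 1L)
  inw <- rep(FALSE, L)
  for (w in windows) inw <- inw | (rel >= w[1] & rel <= w[2])
  tot <- sum(abs(cwm), na.rm = TRUE)
  if (tot == 0) return(0)
  sum(abs(cwm[, inw]), na.rm = TRUE) / tot
}

#' Scan oriented site windows for the M2 motif
#'
#' Scores the oriented input window of each site with the M2 PWM (9
#' columns) in the motif orientation and flags sites with a hit at or
#' above the threshold, recording the best hit's offset from the M1
#' center (a planted M2 sits at offset +21).
#'
#' @param sequences oriented site sequences (e.g. [site_sequences()]).
#' @param m2_pwm 4 x width PFM.
#' @param score_threshold fraction of the maximal score (default 0.8).
#' @return data.frame `has_m2`, `m2_offset` (bp from the motif center to
#'   the hit start; `NA` when no hit), `m2_score`.
#' @export
m2_site_scan <- function(sequences, m2_pwm = default_m2_pwm(),
                         score_threshold = 0.8) {
  lo <- pwm_log_odds(m2_pwm)
  thr <- score_threshold * sum(apply(lo, 2L, max))
  L <- nchar(sequences[1])
  ctr <- L %/% 2L + 1L                     # 1-based index of position 0
  res <- lapply(sequences, function(s) {
    sc <- pwm_score_positions(seq_to_int(s), lo)
    if (!length(sc) || max(sc) < thr)
      return(data.frame(has_m2 = FALSE, m2_offset = NA_integer_,
                        m2_score = if (length(sc)) max(sc) else NA_real_))
    best <- which.max(sc)
    data.frame(has_m2 = TRUE, m2_offset = best - ctr,
               m2_score = sc[best])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
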