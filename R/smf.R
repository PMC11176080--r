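#' Classify cytosine trinucleotide contexts
#'
#' Labels each cytosine by its trinucleotide context for single-molecule
#' footprinting: `GpC` (GCH, the exogenous methyltransferase substrate),
#' `CpG` (HCG, endogenous methylation), or the ambiguous overlap contexts
#' `GCG` and `CCG`, which cannot be attributed to one enzyme and are
#' excluded from both sets.  Positions on the minus strand are classified
#' on the reverse complement.
#'
#' @param genome a single sequence (character) or named list; when a list,
#'   `chrom` selects the sequence.
#' @param positions 0-based positions of cytosines (on the given strand).
#' @param strand `"+"` or `"-"`, recycled.
#' @param chrom chromosome name when `genome` is multi-sequence.
#' @return data.frame with `position`, `strand`, `context` in
#'   `c("GpC","CpG","GCG","CCG","other")`, `ambiguous` flag, and `error`
#'   (`NA` or a message for positions that are not a C on that strand).
#' @export
classify_contexts <- function(genome, positions, strand = "+", chrom = NULL) {
  g <- as_genome(genome)
  s <- if (is.null(chrom)) g[[1]] else g[[chrom]]
  if (is.null(s)) stop_("chromosome not found")
  strand <- rep_len(strand, length(positions))
  n <- nchar(s)
  ctx <- character(length(positions))
  err <- rep(NA_character_, length(positions))
  chars <- strsplit(toupper(s), "")[[1]]
  for (i in seq_along(positions)) {
    p <- positions[i] + 1L            # 1-based
    if (p < 1L || p > n) { ctx[i] <- "other"; err[i] <- "out of range"; next }
    base <- chars[p]
    if (strand[i] == "+") {
      if (base != "C") { ctx[i] <- "other"; err[i] <- "not a C on + strand"; next }
      prev <- if (p > 1L) chars[p - 1L] else "N"
      nxt <- if (p < n) chars[p + 1L] else "N"
    } else {
      if (base != "G") { ctx[i] <- "other"; err[i] <- "not a C on - strand"; next }
      # reverse complement: C at this position reading the minus strand;
      # its 5' neighbour is plus-strand p+1 complemented, 3' is p-1
      prev <- comp1(if (p < n) chars[p + 1L] else "N")
      nxt <- comp1(if (p > 1L) chars[p - 1L] else "N")
    }
    ctx[i] <- trinuc_context(prev, nxt)
  }
  data.frame(position = positions, strand = strand, context = ctx,
             ambiguous = ctx %in% c("GCG", "CCG"), error = err,
             stringsAsFactors = FALSE)
}

comp1 <- function(b) {
  v <- c(A = "T", C = "G", G = "C", T = "A")[b]
  if (is.na(v)) "N" else unname(v)
}

# context of a C with given 5' and 3' neighbours (already strand-oriented)
trinuc_context <- function(prev, nxt) {
  if (prev == "G" && nxt == "G") return("GCG")
  if (nxt == "G") {
    if (prev == "C") return("CCG")
    return("CpG")
  }
  if (prev == "G") return("GpC")
  "other"
}

#' Build a single-molecule methylation call matrix
#'
#' Assembles per-molecule methylation calls over an amplicon into a
#' molecules-by-positions matrix, classifies each position's context from
#' the genome, and retains only unambiguous GpC columns (GCG and CCG
#' contexts are removed; CpG columns are kept separately accessible via
#' the recorded contexts but excluded from the footprint matrix).
#'
#' @param calls data.frame with columns `molecule_id`, `position`
#'   (0-based) and `is_methylated` (0/1 or logical); missing
#'   molecule/position combinations become `NA` (no call).
#' @param genome sequence (see [classify_contexts()]).
#' @param amplicon optional `c(start, end)` restricting positions.
#' @param strand strand of the calls, default `"+"`; both-strand calls
#'   pooled per position may be supplied with `strand = "+"` on the
#'   G-complement positions pre-mapped by the caller.
#' @param chrom chromosome name for multi-sequence genomes.
#' @return An `smf_matrix`: logical matrix `calls` (molecules x GpC
#'   positions, `TRUE` = methylated, `NA` = missing), `positions`,
#'   `contexts` (the full pre-filter classification), `coverage` per
#'   retained column.  An amplicon without any GpC position yields a
#'   zero-column matrix with a warning.
#' @export
smf_matrix <- function(calls, genome, amplicon = NULL, strand = "+",
                       chrom = NULL) {
  stopifnot(all(c("molecule_id", "position", "is_methylated") %in%
                  names(calls)))
  if (!is.null(amplicon))
    calls <- calls[calls$position >= amplicon[1] &
                     calls$position < amplicon[2], , drop = FALSE]
  pos <- sort(unique(calls$position))
  ctx <- classify_contexts(genome, pos, strand = strand, chrom = chrom)
  keep_pos <- pos[ctx$context == "GpC"]
  if (!length(keep_pos))
    warn_("amplicon contains no unambiguous GpC position")
  mols <- sort(unique(calls$molecule_id))
  m <- matrix(NA, length(mols), length(keep_pos),
              dimnames = list(mols, keep_pos))
  sel <- calls$position %in% keep_pos
  ri <- match(calls$molecule_id[sel], mols)
  ci <- match(calls$position[sel], keep_pos)
  m[cbind(ri, ci)] <- as.logical(calls$is_methylated[sel])
  structure(list(calls = m, positions = keep_pos, contexts = ctx,
                 coverage = colSums(!is.na(m)), amplicon = amplicon,
                 strand = strand),
            class = "smf_matrix")
}

#' @export
print.smf_matrix <- function(x, ...) {
  cat(sprintf("smf_matrix: %d molecules x %d GpC positions\n",
              nrow(x$calls), ncol(x$calls)))
  invisible(x)
}

#' Footprint profile from methylation calls
#'
#' Per GpC position, the footprint is 1 minus the methylation rate over
#' informative (non-missing) calls.  With several replicates, the mean of
#' the replicate profiles is reported together with the per-replicate
#' values and their standard deviation.
#'
#' @param x an [smf_matrix()], or a list of them (replicates).
#' @param min_coverage positions with fewer informative calls are set to
#'   `NA` (missing, not zero); default 10.
#' @return data.frame with `position`, `footprint` (mean across
#'   replicates), `sd` (across replicates, `NA` for a single one),
#'   `coverage` (summed), and one `rep<i>` column per replicate.
#' @export
footprint_profile <- function(x, min_coverage = 10L) {
  reps <- if (inherits(x, "smf_matrix")) list(x) else x
  stopifnot(length(reps) >= 1L,
            all(vapply(reps, inherits, TRUE, "smf_matrix")))
  pos <- sort(unique(unlist(lapply(reps, `[[`, "positions"))))
  per_rep <- vapply(reps, function(r) {
    idx <- match(pos, r$positions)
    meth <- colMeans(r$calls, na.rm = TRUE)
    cov <- colSums(!is.na(r$calls))
    v <- 1 - meth[idx]
    v[is.na(idx) | cov[idx] < min_coverage] <- NA
    v
  }, numeric(length(pos)))
  per_rep <- matrix(per_rep, nrow = length(pos))
  cov_tot <- rowSums(vapply(reps, function(r) {
    idx <- match(pos, r$positions)
    cv <- colSums(!is.na(r$calls))[idx]
    cv[is.na(cv)] <- 0L
    as.numeric(cv)
  }, numeric(length(pos))))
  out <- data.frame(position = pos,
                    footprint = rowMeans(per_rep, na.rm = FALSE),
                    sd = if (length(reps) > 1L) apply(per_rep, 1L, stats::sd)
                         else NA_real_,
                    coverage = cov_tot)
  colnames(per_rep) <- paste0("rep", seq_along(reps))
  cbind(out, per_rep)
}

#' Order and partition molecules by window methylation
#'
#' Orders molecules by their mean methylation inside a site window
#' (ascending, i.e. most protected first) with ties broken by molecule
#' id, and partitions them into bound-like (window methylation below the
#' threshold) and accessible-like molecules.
#'
#' @param x an [smf_matrix()].
#' @param site_window `c(start, end)` in genomic bp, within the amplicon.
#' @param threshold methylation fraction separating the partitions
#'   (default 0.5).
#' @return data.frame with `molecule_id`, `window_methylation`, `label`
#'   (`"bound_like"`/`"accessible_like"`), ordered; molecules without an
#'   informative call in the window get `NA` methylation and sort last.
#' @export
molecule_sort <- function(x, site_window, threshold = 0.5) {
  stopifnot(inherits(x, "smf_matrix"))
  inw <- x$positions >= site_window[1] & x$positions < site_window[2]
  if (!any(inw)) stop_("site window contains no GpC position")
  wm <- rowMeans(x$calls[, inw, drop = FALSE], na.rm = TRUE)
  wm[is.nan(wm)] <- NA
  ids <- rownames(x$calls)
  ord <- order(wm, ids, na.last = TRUE)
  data.frame(molecule_id = ids[ord], window_methylation = wm[ord],
             label = ifelse(is.na(wm[ord]), NA_character_,
                            ifelse(wm[ord] < threshold, "bound_like",
                                   "accessible_like")),
             stringsAsFactors = FALSE, row.names = NULL)
}
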