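#' Read a JASPAR-format position frequency matrix
#'
#' Parses the JASPAR text layout: a `>ID name` header line followed by
#' four rows `A [ 1 2 ... ]`, `C [...]`, `G [...]`, `T [...]` (brackets
#' optional).
#'
#' @param path path to the PFM text file.
#' @return Numeric 4 x width matrix with rownames `A,C,G,T` and attribute
#'   `motif_id`.
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  id <- NA_character_
  if (startsWith(lines[1], ">")) {
    id <- trimws(sub("^>", "", lines[1]))
    lines <- lines[-1]
  }
  if (length(lines) < 4L) stop_("PFM needs 4 base rows, got %d", length(lines))
  rows <- lapply(lines[1:4], function(l) {
    l <- gsub("[][]", " ", l)
    parts <- strsplit(trimws(l), "\\s+")[[1]]
    base <- parts[1]
    vals <- suppressWarnings(as.numeric(parts[-1]))
    if (anyNA(vals)) stop_("non-numeric PFM entries in row '%s'", base)
    list(base = toupper(base), vals = vals)
  })
  bases <- vapply(rows, `[[`, "", "base")
  if (!setequal(bases, c("A", "C", "G", "T")))
    stop_("PFM rows must be labeled A, C, G, T")
  w <- unique(lengths(lapply(rows, `[[`, "vals")))
  if (length(w) != 1L) stop_("PFM rows have unequal widths")
  m <- do.call(rbind, lapply(rows, `[[`, "vals"))
  rownames(m) <- bases
  m <- m[c("A", "C", "G", "T"), , drop = FALSE]
  structure(m, motif_id = id)
}

#' Write a matrix in JASPAR PFM layout
#' @param pfm 4 x width matrix with rownames A,C,G,T.
#' @param path output path.
#' @param id header identifier.
#' @return Invisibly, `path`.
#' @export
write_jaspar_pfm <- function(pfm, path, id = "motif") {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0(">", id), con)
  for (b in c("A", "C", "G", "T"))
    writeLines(sprintf("%s [ %s ]", b,
                       paste(format(pfm[b, ], trim = TRUE), collapse = " ")),
               con)
  invisible(path)
}

#' Log2-odds scoring matrix from a PFM
#'
#' Column counts are converted to probabilities, a flat pseudo-probability
#' of 0.01 is added per cell, and scores are log2 odds against a uniform
#' background (0.25 per base).
#'
#' @param pfm 4 x width count or probability matrix (rows A,C,G,T).
#' @param pseudo_prob per-cell pseudo-probability (default 0.01).
#' @return 4 x width log2-odds matrix.
#' @export
pwm_log_odds <- function(pfm, pseudo_prob = 0.01) {
  cs <- colSums(pfm)
  if (any(cs <= 0)) stop_("PFM column sums must be positive")
  p <- sweep(pfm, 2L, cs, "/")
  log2((p + pseudo_prob) / (0.25 + pseudo_prob))
}

DNA_BASES <- c("A", "C", "G", "T")

seq_to_int <- function(s) {
  v <- match(strsplit(toupper(s), "")[[1]], DNA_BASES)
  v   # NA for non-ACGT
}

revcomp <- function(s) {
  chartr("ACGTacgtN", "TGCAtgcaN", paste(rev(strsplit(s, "")[[1]]),
                                         collapse = ""))
}

# score a log-odds matrix at every start position of an integer-coded
# sequence; positions containing non-ACGT get -Inf
pwm_score_positions <- function(iv, lo) {
  w <- ncol(lo); n <- length(iv)
  if (n < w) return(numeric(0))
  np <- n - w + 1L
  sc <- numeric(np)
  ok <- rep(TRUE, np)
  for (j in seq_len(w)) {
    b <- iv[j:(j + np - 1L)]
    nas <- is.na(b)
    if (any(nas)) { ok[nas] <- FALSE; b[nas] <- 1L }
    sc <- sc + lo[cbind(b, j)]
  }
  sc[!ok] <- -Inf
  sc
}

#' Scan a genome with a position weight matrix
#'
#' Scores every position on both strands with the log2-odds matrix of the
#' PFM and reports matches above the threshold.  Overlapping same-strand
#' hits are resolved greedily, keeping the higher-scoring match.
#'
#' @param genome named character vector of chromosome sequences (or a
#'   single unnamed sequence, reported as `"chr1"`), or a
#'   `Biostrings::DNAStringSet`.
#' @param pwm 4 x width PFM (counts or probabilities); converted with
#'   [pwm_log_odds()].
#' @param score_threshold threshold for reporting a hit.
#' @param threshold_type `"fraction_of_max"` (default; threshold is a
#'   fraction of the maximal attainable score, default 0.8) or
#'   `"absolute"` (minimum log2-odds score).
#' @return A data.frame of motif sites: `site_id`, `chrom`, `start`,
#'   `end` (0-based half-open match coordinates), `strand`, `pwm_score`,
#'   plus a `center` column (`start + floor(width/2)`).  Empty, with a
#'   warning, when the PWM is wider than every sequence.
#' @export
scan_pwm <- function(genome, pwm, score_threshold = 0.8,
                     threshold_type = c("fraction_of_max", "absolute")) {
  threshold_type <- match.arg(threshold_type)
  genome <- as_genome(genome)
  lo <- pwm_log_odds(pwm)
  w <- ncol(lo)
  thr <- if (threshold_type == "fraction_of_max")
    score_threshold * sum(apply(lo, 2L, max)) else score_threshold
  out <- list()
  for (ch in names(genome)) {
    s <- genome[[ch]]
    if (nchar(s) < w) next
    iv <- seq_to_int(s)
    fw <- pwm_score_positions(iv, lo)
    rv_iv <- rev(5L - ifelse(is.na(iv), NA, iv))  # complement, reversed
    rv <- pwm_score_positions(rv_iv, lo)
    n <- nchar(s)
    hits_f <- which(fw >= thr)
    hits_r <- which(rv >= thr)
    df <- rbind(
      if (length(hits_f))
        data.frame(chrom = ch, start = hits_f - 1L, strand = "+",
                   pwm_score = fw[hits_f]),
      if (length(hits_r))
        data.frame(chrom = ch, start = n - w + 1L - hits_r, strand = "-",
                   pwm_score = rv[hits_r]))
    if (!is.null(df) && nrow(df)) out[[ch]] <- df
  }
  if (!length(out)) {
    if (all(nchar(unlist(genome)) < w))
      warn_("PWM wider than every sequence; returning empty site set")
    return(empty_sites(w))
  }
  df <- do.call(rbind, out)
  df$end <- df$start + w
  df <- resolve_overlaps(df)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  df$site_id <- sprintf("site_%05d", seq_len(nrow(df)))
  df$center <- df$start + w %/% 2L
  rownames(df) <- NULL
  df[c("site_id", "chrom", "start", "end", "strand", "pwm_score", "center")]
}

empty_sites <- function(w) {
  data.frame(site_id = character(), chrom = character(), start = integer(),
             end = integer(), strand = character(), pwm_score = numeric(),
             center = integer())
}

# greedy per-strand overlap resolution, higher score wins
resolve_overlaps <- function(df) {
  keep <- logical(nrow(df))
  for (key in unique(paste(df$chrom, df$strand))) {
    idx <- which(paste(df$chrom, df$strand) == key)
    ord <- idx[order(-df$pwm_score[idx], df$start[idx])]
    taken_s <- integer(0); taken_e <- integer(0)
    for (i in ord) {
      if (!any(df$start[i] < taken_e & df$end[i] > taken_s)) {
        keep[i] <- TRUE
        taken_s <- c(taken_s, df$start[i]); taken_e <- c(taken_e, df$end[i])
      }
    }
  }
  df[keep, , drop = FALSE]
}

# normalize genome representations to a named list of character sequences
as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    out <- as.list(as.character(genome))
    if (is.null(names(out))) names(out) <- paste0("chr", seq_along(out))
    return(out)
  }
  if (is.character(genome)) {
    out <- as.list(genome)
    if (is.null(names(out)) || any(!nzchar(names(out))))
      names(out) <- paste0("chr", seq_along(out))
    return(out)
  }
  if (is.list(genome)) {
    if (is.null(names(genome))) names(genome) <- paste0("chr",
                                                        seq_along(genome))
    return(genome)
  }
  stop_("unsupported genome representation")
}

#' Write genome sequences as FASTA
#' @param genome named character vector/list of sequences.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_genome_fasta <- function(genome, path) {
  genome <- as_genome(genome)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(genome)), path)
  invisible(path)
}

#' Read genome sequences from FASTA
#' @param path FASTA path.
#' @return Named list of character sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.list(as.character(x)),
                  vapply(strsplit(names(x), "\\s+"), `[[`, "", 1L))
}
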