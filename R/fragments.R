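#' Construct a fragment table
#'
#' A fragment table holds aligned sequencing fragments as 0-based,
#' half-open intervals, one row per fragment, and is the common input of
#' all profile, counting and phasing operations.  The library size (total
#' fragment count) is carried as an attribute and used by every
#' depth-normalization step.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open; `end > start`.
#' @param strand character vector in `"+"`, `"-"`, `"."` (recycled).
#' @param sample_label optional label recorded on the table.
#' @return A `data.frame` of class `fragment_table` with columns
#'   `chrom`, `start`, `end`, `strand` and attributes `library_size` and
#'   `sample_label`.
#' @examples
#' ft <- fragment_table("chr1", c(0L, 10L), c(50L, 150L))
#' library_size(ft)
#' @export
fragment_table <- function(chrom, start, end, strand = ".",
                           sample_label = NA_character_) {
  n <- length(start)
  if (length(end) != n)
    stop_("start/end lengths disagree")
  if (n > 0 && !(length(chrom) == 1L || length(chrom) == n))
    stop_("chrom length must be 1 or match start/end")
  start <- as.integer(start); end <- as.integer(end)
  bad <- which(!(end > start))
  if (length(bad))
    stop_("fragment %d has end <= start (%d <= %d)", bad[1], end[bad[1]],
          start[bad[1]])
  df <- data.frame(chrom = as.character(rep_len(chrom, n)),
                   start = start, end = end,
                   strand = as.character(rep_len(strand, n)),
                   stringsAsFactors = FALSE)
  structure(df, class = c("fragment_table", "data.frame"),
            library_size = n, sample_label = sample_label)
}

#' Library size of a fragment table
#' @param x a [fragment_table()].
#' @return Integer total fragment count.
#' @export
library_size <- function(x) attr(x, "library_size") %||% nrow(x)

#' @export
print.fragment_table <- function(x, ...) {
  cat(sprintf("fragment_table: %d fragments on %d chromosome(s)%s\n",
              nrow(x), length(unique(x$chrom)),
              if (!is.na(attr(x, "sample_label") %||% NA))
                paste0(" [", attr(x, "sample_label"), "]") else ""))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Read aligned fragments from a BED-like TSV or a BAM file
#'
#' The TSV dialect is BED3 plus an optional strand column
#' (`chrom  start  end  [strand]`, 0-based half-open, no header).  BAM
#' input (requires the Rsamtools package) collapses properly paired
#' records to one fragment per pair.
#'
#' @param path path to the file.
#' @param format `"bed_tsv"` (default) or `"bam"`.
#' @param sample_label label stored on the returned table; defaults to the
#'   file name.
#' @return A [fragment_table()].  Malformed TSV lines raise an error
#'   naming the first offending line; an empty file returns an empty table
#'   with a warning.
#' @export
read_fragments <- function(path, format = c("bed_tsv", "bam"),
                           sample_label = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_("file not found: %s", path)
  if (format == "bam") return(read_fragments_bam(path, sample_label))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warn_("empty fragment file: %s", path)
    return(fragment_table(character(), integer(), integer(),
                          sample_label = sample_label))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop_("line %d: fewer than 3 tab-separated fields",
          which(nf < 3L)[1])
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop_("line %d: non-integer coordinates", bad[1])
  bad <- which(end <= start)
  if (length(bad))
    stop_("line %d: end <= start (%d <= %d)", bad[1], end[bad[1]],
          start[bad[1]])
  strand <- ifelse(nf >= 4L, vapply(parts, function(p)
    if (length(p) >= 4L) p[[4L]] else ".", ""), ".")
  fragment_table(chrom, start, end, strand, sample_label = sample_label)
}

read_fragments_bam <- function(path, sample_label) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop_("BAM input requires the Rsamtools package")
  p <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isProperPair = TRUE, isFirstMateRead = TRUE),
    what = c("rname", "pos", "mpos", "isize", "strand"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  keep <- !is.na(b$isize) & b$isize != 0L
  pos <- b$pos[keep]; isz <- b$isize[keep]
  # leftmost mate start (0-based) and fragment length |isize|
  left <- pmin(pos, b$mpos[keep]) - 1L
  fragment_table(as.character(b$rname[keep]), left, left + abs(isz),
                 as.character(b$strand[keep]), sample_label = sample_label)
}

#' Write a fragment table as BED3+strand TSV
#' @param x a [fragment_table()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_fragments <- function(x, path) {
  utils::write.table(as.data.frame(x)[c("chrom", "start", "end", "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Downsample fragment tables to a common depth
#'
#' Subsamples every table, without replacement, to the library size of the
#' shallowest sample, mirroring depth matching in which the number of
#' mapped reads of each sample is scaled down to the sample with the
#' lowest number of mapped reads.
#'
#' @param samples list of [fragment_table()]s (at least two).
#' @param seed integer seed; the subsampling is deterministic given it.
#' @return List of fragment tables, all with equal library size.
#' @export
downsample_to_min <- function(samples, seed = 1L) {
  if (!is.list(samples) || length(samples) < 2L)
    stop_("need a list of at least two fragment tables")
  sizes <- vapply(samples, nrow, 0L)
  if (any(sizes == 0L)) stop_("sample %d is empty", which(sizes == 0L)[1])
  m <- min(sizes)
  with_seed(seed, lapply(samples, function(s) {
    if (nrow(s) == m) return(s)
    keep <- sort(sample.int(nrow(s), m))
    fragment_table(s$chrom[keep], s$start[keep], s$end[keep], s$strand[keep],
                   sample_label = attr(s, "sample_label"))
  }))
}

# Fragment reference positions used across modules.
# midpoint: start + floor(length/2) (right-of-center base for even lengths)
# five_prime: strand-aware 5' end; full cover handled by callers.
frag_midpoint <- function(x) x$start + (x$end - x$start) %/% 2L

frag_five_prime <- function(x) ifelse(x$strand == "-", x$end - 1L, x$start)
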