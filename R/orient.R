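#' Orientation configuration for telomere-like read pairs
#'
#' Telomere-like fragments can be sequenced from either strand; before
#' building a per-base motif matrix the pairs are reoriented so that the
#' G-rich (TTAGGG) strand is always read 1. A pair is flipped — both mates
#' reverse complemented and swapped — when the G fraction of R1, measured
#' over `assess_window` bases from its 5' end (whole read by default), falls
#' below `g_fraction_threshold`.
#'
#' @param g_fraction_threshold Flip when R1's G fraction is below this
#'   (default 0.5).
#' @param assess_window Number of 5' bases to assess, or `NULL` for the
#'   whole read (default).
#' @return An object of class `orient_config`.
#' @export
orient_config <- function(g_fraction_threshold = 0.5, assess_window = NULL) {
  if (g_fraction_threshold <= 0 || g_fraction_threshold >= 1) {
    rlang::abort("g_fraction_threshold must be in (0, 1)")
  }
  structure(
    list(g_fraction_threshold = g_fraction_threshold,
         assess_window = assess_window),
    class = "orient_config"
  )
}

#' Reference-free reorientation of read pairs
#'
#' Both mates are expected on a common strand (fragment coordinates): the
#' raw second read of an Illumina pair reads the opposite strand, so reverse
#' complement it before calling this function. Under that convention the
#' operation is idempotent for telomere-like pairs — once R1 presents the
#' G-rich strand it stays put.
#'
#' @param pairs Tibble with columns `sequence` (R1) and `mate_sequence` (R2,
#'   same strand as R1); other columns are carried through.
#' @param config An [orient_config()].
#' @return The input tibble with `sequence`/`mate_sequence` reoriented and a
#'   logical `flipped` column appended. Idempotent: a flipped pair's new R1
#'   has G fraction >= the threshold whenever the original R2 was C-rich.
#' @export
#' @examples
#' orient_pairs(tibble::tibble(sequence = "CCCCCCCCCC", mate_sequence = "AACG"))
orient_pairs <- function(pairs, config = orient_config()) {
  stopifnot(all(c("sequence", "mate_sequence") %in% names(pairs)))
  if (any(!nzchar(pairs$sequence)) || any(!nzchar(pairs$mate_sequence))) {
    rlang::abort("empty read in pair: both mates must be non-empty")
  }
  gf <- g_fraction(pairs$sequence, config$assess_window)
  flip <- gf < config$g_fraction_threshold
  out <- tibble::as_tibble(pairs)
  if (any(flip)) {
    new_r1 <- revcomp(out$mate_sequence[flip])
    new_r2 <- revcomp(out$sequence[flip])
    out$sequence[flip] <- new_r1
    out$mate_sequence[flip] <- new_r2
  }
  out$flipped <- flip
  out
}

#' Per-base frequency (logo) matrix
#'
#' Stacks reads at a common length (truncating or padding with `N`) and
#' returns the per-position base frequencies — the numeric form of the
#' average motif of telomere-like reads.
#'
#' @param reads Character vector of DNA sequences (non-empty).
#' @param length Matrix length; defaults to the longest read.
#' @param include_n_in_denominator Count padding/ambiguous `N` in each
#'   column's normalisation denominator (default `TRUE`)? When `FALSE`,
#'   frequencies are over observed A/C/G/T only and the `N` column reports
#'   the raw N fraction.
#' @return A `length` x 5 matrix (columns `A`, `C`, `G`, `T`, `N`) of class
#'   `base_freq_matrix`; each row sums to 1 over the included columns.
#' @export
base_frequency_matrix <- function(reads, length = NULL,
                                  include_n_in_denominator = TRUE) {
  reads <- reads[!is.na(reads)]
  if (base::length(reads) == 0L) rlang::abort("no reads to build a matrix from")
  if (is.null(length)) length <- max(nchar(reads))
  stopifnot(length >= 1L)
  padded <- vapply(reads, function(s) {
    s <- substr(s, 1L, length)
    if (nchar(s) < length) s <- paste0(s, strrep("N", length - nchar(s)))
    s
  }, character(1), USE.NAMES = FALSE)
  cm <- t(Biostrings::consensusMatrix(Biostrings::DNAStringSet(padded),
                                      baseOnly = TRUE))
  # consensusMatrix(baseOnly) gives A,C,G,T,other; "other" here is N
  counts <- cbind(cm[, c("A", "C", "G", "T"), drop = FALSE],
                  N = cm[, "other"])
  denom <- if (include_n_in_denominator) rowSums(counts) else
    rowSums(counts[, 1:4, drop = FALSE])
  freq <- counts / ifelse(denom > 0, denom, 1)
  if (!include_n_in_denominator) {
    freq[, "N"] <- counts[, "N"] / rowSums(counts)
  }
  rownames(freq) <- seq_len(length) - 1L
  structure(freq, class = c("base_freq_matrix", "matrix"))
}

#' Write a base-frequency matrix as TSV
#'
#' Rows are 0-based positions, columns `A`, `C`, `G`, `T`, `N`.
#'
#' @param mat A [base_frequency_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_base_frequency_matrix <- function(mat, path) {
  df <- data.frame(position = as.integer(rownames(mat)),
                   unclass(mat)[, , drop = FALSE], check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
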