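#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] that
#' accepts and returns plain character vectors. `N` is preserved.
#'
#' @param x Character vector of DNA sequences (alphabet `A`, `C`, `G`, `T`, `N`).
#' @return Character vector of reverse complements, same length as `x`.
#' @export
#' @examples
#' revcomp("TTAGGG")
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  out <- rep(NA_character_, length(x))
  nonempty <- !is.na(x) & nchar(x) > 0L
  out[!is.na(x) & !nonempty] <- ""
  if (any(nonempty)) {
    out[nonempty] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nonempty]))
    )
  }
  unname(out)
}

# Validate DNA sequences: ACGTN only. Errors name the first offending
# character, per the scanner's input contract.
check_dna <- function(x, what = "sequence", allow_n = TRUE) {
  pattern <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  bad <- stringr::str_extract(x, pattern)
  hit <- which(!is.na(bad))[1]
  if (!is.na(hit)) {
    rlang::abort(sprintf(
      "invalid character '%s' in %s (element %d); only A/C/G/T%s are allowed",
      bad[hit], what, hit, if (allow_n) "/N" else ""
    ))
  }
  invisible(x)
}

# G fraction of the first `window` bases (whole string when window is NULL).
g_fraction <- function(x, window = NULL) {
  if (!is.null(window)) x <- substr(x, 1L, window)
  n <- nchar(x)
  g <- stringr::str_count(x, stringr::fixed("G"))
  ifelse(n > 0L, g / n, NA_real_)
}

# Random DNA helper used by the simulators; respects the current RNG state.
random_dna <- function(n, length, alphabet = c("A", "C", "G", "T")) {
  if (n == 0L) return(character(0))
  lens <- rep_len(length, n)
  chars <- sample(alphabet, sum(lens), replace = TRUE)
  idx <- rep.int(seq_len(n), lens)
  unname(vapply(split(chars, idx), paste0, character(1), collapse = ""))
}

# Uniform integer draw from [lo, hi] that does not fall into sample()'s
# scalar trap when lo == hi.
sample_range <- function(lo, hi, n = 1L) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

# Substring extraction with 0-based half-open coordinates, the package's
# internal convention. substring() recycles x against vector start/end,
# which base substr() does not.
substr0 <- function(x, start, end) {
  substring(x, start + 1L, end)
}
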