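#' Motif-scan configuration
#'
#' Bundles the parameters of the telomere-motif scanner: the canonical
#' telomere repeat, the minimum number of strictly tandem copies required for
#' a read to be called telomere-like, the wildcard pattern for telomere
#' variant repeats (TVRs), and whether both strands are scanned.
#'
#' The default threshold of three consecutive motifs is the standard cutoff
#' for calling a short read telomere-like; variant repeats match `T**GGG`
#' (any base at the wildcard positions) but never the canonical motif itself.
#'
#' @param canonical_motif Canonical repeat unit (default `"TTAGGG"`), A/C/G/T only.
#' @param min_consecutive Minimum tandem copies for a telomere-like call
#'   (integer >= 1, default 3).
#' @param variant_pattern Variant-repeat pattern with `*` wildcards, same
#'   length as `canonical_motif` (default `"T**GGG"`).
#' @param scan_both_strands Scan the reverse complement too? (default `TRUE`).
#' @param variant_min_run Minimum tandem copies for a variant hexamer to be
#'   counted (default 1, i.e. no run requirement).
#' @return An object of class `motif_scan_config`.
#' @export
#' @examples
#' motif_scan_config()
motif_scan_config <- function(canonical_motif = "TTAGGG",
                              min_consecutive = 3L,
                              variant_pattern = "T**GGG",
                              scan_both_strands = TRUE,
                              variant_min_run = 1L) {
  check_dna(canonical_motif, "canonical_motif", allow_n = FALSE)
  if (nchar(canonical_motif) == 0L) {
    rlang::abort("canonical_motif must be non-empty")
  }
  min_consecutive <- as.integer(min_consecutive)
  if (is.na(min_consecutive) || min_consecutive < 1L) {
    rlang::abort("min_consecutive must be an integer >= 1")
  }
  if (nchar(variant_pattern) != nchar(canonical_motif)) {
    rlang::abort("variant_pattern must have the same length as canonical_motif")
  }
  if (grepl("[^ACGT*]", variant_pattern)) {
    rlang::abort("variant_pattern may contain only A/C/G/T and '*' wildcards")
  }
  structure(
    list(
      canonical_motif = canonical_motif,
      min_consecutive = min_consecutive,
      variant_pattern = variant_pattern,
      scan_both_strands = isTRUE(scan_both_strands),
      variant_min_run = as.integer(variant_min_run)
    ),
    class = "motif_scan_config"
  )
}

#' @export
print.motif_scan_config <- function(x, ...) {
  cat("<motif_scan_config>\n")
  cat("  canonical_motif:  ", x$canonical_motif, "\n", sep = "")
  cat("  min_consecutive:  ", x$min_consecutive, "\n", sep = "")
  cat("  variant_pattern:  ", x$variant_pattern, "\n", sep = "")
  cat("  scan_both_strands:", x$scan_both_strands, "\n")
  invisible(x)
}

#' Write / read a motif-scan configuration as a flat key/value file
#'
#' @param config A [motif_scan_config()].
#' @param path File path.
#' @return `write_motif_config()` returns `path` invisibly;
#'   `read_motif_config()` returns a `motif_scan_config`.
#' @export
write_motif_config <- function(config, path) {
  stopifnot(inherits(config, "motif_scan_config"))
  lines <- c(
    paste0("canonical_motif=", config$canonical_motif),
    paste0("min_consecutive=", config$min_consecutive),
    paste0("variant_pattern=", config$variant_pattern),
    paste0("scan_both_strands=", tolower(as.character(config$scan_both_strands)))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_motif_config
#' @export
read_motif_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines[nzchar(lines)], "=", fixed = TRUE)
  vals <- stats::setNames(
    vapply(kv, function(p) paste(p[-1], collapse = "="), character(1)),
    vapply(kv, `[[`, character(1), 1)
  )
  motif_scan_config(
    canonical_motif = vals[["canonical_motif"]],
    min_consecutive = as.integer(vals[["min_consecutive"]]),
    variant_pattern = vals[["variant_pattern"]],
    scan_both_strands = identical(vals[["scan_both_strands"]], "true")
  )
}

#' Longest tandem run of a motif in a sequence
#'
#' Returns, for each sequence, the largest `k` such that `k` strictly tandem
#' (zero-gap) copies of `motif` occur as a contiguous substring. Any
#' non-matching character — including `N` — terminates a run.
#'
#' @param seq Character vector of DNA sequences (A/C/G/T/N).
#' @param motif Single motif string (A/C/G/T, non-empty).
#' @return Integer vector of maximal tandem copy numbers (0 if absent).
#' @export
#' @examples
#' max_tandem_run("TTAGGGTTAGGGTTAGGG", "TTAGGG")
max_tandem_run <- function(seq, motif) {
  if (length(motif) != 1L || is.na(motif) || nchar(motif) == 0L) {
    rlang::abort("motif must be a single non-empty string")
  }
  check_dna(motif, "motif", allow_n = FALSE)
  check_dna(seq, "seq", allow_n = TRUE)
  if (length(seq) == 0L) return(integer(0))
  pattern <- paste0("(?:", motif, ")+")
  hits <- gregexpr(pattern, seq, perl = TRUE)
  vapply(hits, function(h) {
    if (h[1] == -1L) return(0L)
    as.integer(max(attr(h, "match.length")) %/% nchar(motif))
  }, integer(1))
}

#' Classify reads as telomere-like by tandem motif runs
#'
#' Scans each read for tandem runs of the canonical motif on the forward
#' strand and (optionally) of its reverse complement, and calls a read
#' telomere-like when the larger run reaches `min_consecutive`. Input is a
#' tibble-like data frame with a `sequence` column; in paired (fragment) mode
#' a `mate_sequence` column is scanned too and the fragment qualifies if
#' either mate does.
#'
#' @param reads Data frame with at least a `sequence` column; optional
#'   `read_id`, `mate_sequence`, `barcode`, `contig` columns are carried
#'   through.
#' @param config A [motif_scan_config()].
#' @param runs Compute exact per-read maximal run lengths
#'   (`max_run_forward` / `max_run_reverse`)? With `runs = FALSE` only
#'   `is_telomere_like` is computed, via a fast fixed-substring test that is
#'   equivalent for the classification (a run of at least `k` copies is
#'   exactly the presence of the motif concatenated `k` times).
#' @return The input tibble with columns `max_run_forward`,
#'   `max_run_reverse` (when `runs = TRUE`) and `is_telomere_like` appended.
#' @export
#' @examples
#' classify_reads(tibble::tibble(sequence = c(strrep("TTAGGG", 3), "ACGTACGT")))
classify_reads <- function(reads, config = motif_scan_config(), runs = TRUE) {
  stopifnot(is.data.frame(reads), "sequence" %in% names(reads))
  reads <- tibble::as_tibble(reads)
  motif <- config$canonical_motif
  rc <- revcomp(motif)
  paired <- "mate_sequence" %in% names(reads) &&
    any(!is.na(reads$mate_sequence))
  seqs <- list(reads$sequence)
  if (paired) seqs <- c(seqs, list(reads$mate_sequence))

  if (runs) {
    fwd <- rev_ <- rep(0L, nrow(reads))
    for (s in seqs) {
      ok <- !is.na(s)
      if (!any(ok)) next
      fwd[ok] <- pmax(fwd[ok], max_tandem_run(s[ok], motif))
      if (config$scan_both_strands) {
        rev_[ok] <- pmax(rev_[ok], max_tandem_run(s[ok], rc))
      }
    }
    reads$max_run_forward <- fwd
    reads$max_run_reverse <- rev_
    reads$is_telomere_like <- pmax(fwd, rev_) >= config$min_consecutive
  } else {
    probe_f <- strrep(motif, config$min_consecutive)
    probe_r <- strrep(rc, config$min_consecutive)
    hit <- rep(FALSE, nrow(reads))
    for (s in seqs) {
      ok <- !is.na(s)
      if (!any(ok)) next
      check_dna(s[ok], "sequence")
      h <- grepl(probe_f, s[ok], fixed = TRUE)
      if (config$scan_both_strands) {
        h <- h | grepl(probe_r, s[ok], fixed = TRUE)
      }
      hit[ok] <- hit[ok] | h
    }
    reads$is_telomere_like <- hit
  }
  reads
}

# Concrete hexamers matching a wildcard pattern, canonical excluded.
variant_hexamers <- function(config) {
  chars <- strsplit(config$variant_pattern, "")[[1]]
  opts <- lapply(chars, function(ch) if (ch == "*") c("A", "C", "G", "T") else ch)
  grid <- do.call(expand.grid, c(rev(opts), stringsAsFactors = FALSE))
  all <- apply(grid[, rev(seq_along(opts)), drop = FALSE], 1, paste0, collapse = "")
  sort(setdiff(all, config$canonical_motif))
}

#' Count telomere variant repeats
#'
#' Counts non-overlapping occurrences of every concrete hexamer matching the
#' variant pattern (default `T**GGG`), excluding the canonical motif itself.
#' With `scan_both_strands` the reverse complement of each sequence is
#' scanned too and counts are attributed to the forward-strand hexamer.
#'
#' @param seq Character vector of DNA sequences.
#' @param config A [motif_scan_config()].
#' @return A tibble with columns `hexamer` and `count` (only hexamers with
#'   `count > 0`), sorted by decreasing count.
#' @export
#' @examples
#' count_variant_repeats("TAAGGGTAAGGGTTTGGG")
count_variant_repeats <- function(seq, config = motif_scan_config()) {
  check_dna(seq, "seq")
  hexes <- variant_hexamers(config)
  targets <- seq
  if (config$scan_both_strands) targets <- c(targets, revcomp(seq))
  counts <- vapply(hexes, function(h) {
    if (config$variant_min_run <= 1L) {
      return(as.integer(sum(stringr::str_count(targets, stringr::fixed(h)))))
    }
    # run-threshold mode: only copies inside tandem runs of the required
    # length contribute
    hits <- gregexpr(paste0("(?:", h, ")+"), targets, perl = TRUE)
    n <- sum(vapply(hits, function(m) {
      if (m[1] == -1L) return(0L)
      copies <- attr(m, "match.length") %/% nchar(h)
      as.integer(sum(copies[copies >= config$variant_min_run]))
    }, integer(1)))
    as.integer(n)
  }, integer(1))
  out <- tibble::tibble(hexamer = hexes, count = unname(counts))
  dplyr::arrange(dplyr::filter(out, .data$count > 0L), dplyr::desc(.data$count))
}

#' Histogram of maximal motif run lengths among telomere-like reads
#'
#' @param classified Output of [classify_reads()] with run columns.
#' @return Tibble with columns `run_length` and `n_reads`; empty when no
#'   telomere-like reads are present.
#' @export
motif_run_histogram <- function(classified) {
  stopifnot(all(c("max_run_forward", "max_run_reverse", "is_telomere_like")
                %in% names(classified)))
  tl <- dplyr::filter(classified, .data$is_telomere_like)
  if (nrow(tl) == 0L) {
    return(tibble::tibble(run_length = integer(0), n_reads = integer(0)))
  }
  tl |>
    dplyr::mutate(run_length = pmax(.data$max_run_forward, .data$max_run_reverse)) |>
    dplyr::count(.data$run_length, name = "n_reads") |>
    dplyr::arrange(.data$run_length)
}
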