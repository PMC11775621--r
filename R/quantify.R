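#' Normalized telomere abundance (nTA)
#'
#' nTA is the fraction of telomere-like reads in a library or cell:
#' `telomere_like / total`. It normalises for sequencing depth and is read
#' here as a chromatin-condensation biomarker, not a telomere-length
#' estimate. With `total = 0` the value is undefined and returned as `NA`.
#'
#' @param telomere_like Integer vector of telomere-like read counts.
#' @param total Integer vector of total read counts.
#' @return Numeric vector of fractions in `[0, 1]` (`NA` where `total` is 0).
#' @export
#' @examples
#' compute_nta(250, 1000)
compute_nta <- function(telomere_like, total) {
  if (any(telomere_like < 0, na.rm = TRUE) || any(total < 0, na.rm = TRUE)) {
    rlang::abort("counts must be non-negative")
  }
  if (any(telomere_like > total, na.rm = TRUE)) {
    rlang::abort("telomere_like exceeds total: inconsistent counts")
  }
  ifelse(total > 0, telomere_like / total, NA_real_)
}

#' Rank transform to the unit interval
#'
#' Average ranks (ties share their mean rank) rescaled by
#' `(rank - 1) / (n - 1)` so the smallest value maps to 0 and the largest to
#' 1. A single value, or an all-tied vector, maps to 0.5. Used to display
#' per-cell nTA with maximal contrast.
#'
#' @param values Numeric vector, length >= 1; `NA`s propagate.
#' @return Numeric vector in `[0, 1]`.
#' @export
#' @examples
#' rank_transform(c(0.1, 0.2, 0.3))
rank_transform <- function(values) {
  if (length(values) == 0L) rlang::abort("rank_transform needs at least one value")
  n <- sum(!is.na(values))
  if (n == 0L) return(values)
  r <- rank(values, ties.method = "average", na.last = "keep")
  if (n == 1L) {
    out <- ifelse(is.na(values), NA_real_, 0.5)
    return(out)
  }
  out <- (r - 1) / (n - 1)
  # an all-tied vector has every average rank equal to (n+1)/2, which the
  # scaling already sends to 0.5
  out
}

#' Library-level nTA summary
#'
#' @param classified Output of [classify_reads()].
#' @return One-row tibble: `total_reads`, `telomere_like_reads`, `nta`,
#'   `rpm` (nTA x 1e6) and the counting `mode` (`"read"` or `"fragment"`).
#' @export
library_summary <- function(classified) {
  stopifnot("is_telomere_like" %in% names(classified))
  mode <- if ("mate_sequence" %in% names(classified) &&
              any(!is.na(classified$mate_sequence))) "fragment" else "read"
  total <- nrow(classified)
  tl <- sum(classified$is_telomere_like)
  nta <- compute_nta(tl, total)
  tibble::tibble(
    total_reads = total,
    telomere_like_reads = tl,
    nta = nta,
    rpm = nta * 1e6,
    mode = mode
  )
}

#' Per-cell telomere-like read counts
#'
#' Tallies total and telomere-like reads per cell barcode. Records without a
#' barcode accumulate in a reserved row (barcode `NA`) that is excluded from
#' the rank transform. `rank_nta` is computed over cells whose total reaches
#' `min_total`.
#'
#' @param classified Output of [classify_reads()] carrying a `barcode` column
#'   (may contain `NA`).
#' @param min_total Minimum total reads for a cell to receive a `rank_nta`
#'   (default 1).
#' @return Tibble with columns `barcode`, `total`, `telomere_like`, `nta`,
#'   `rank_nta`, sorted by barcode with the no-barcode row (if any) last.
#' @export
per_cell_counts <- function(classified, min_total = 1L) {
  stopifnot("is_telomere_like" %in% names(classified))
  if (!"barcode" %in% names(classified)) classified$barcode <- NA_character_
  tab <- classified |>
    dplyr::group_by(.data$barcode) |>
    dplyr::summarise(
      total = dplyr::n(),
      telomere_like = sum(.data$is_telomere_like),
      .groups = "drop"
    ) |>
    dplyr::mutate(nta = compute_nta(.data$telomere_like, .data$total))
  eligible <- !is.na(tab$barcode) & tab$total >= min_total
  tab$rank_nta <- NA_real_
  if (any(eligible)) {
    tab$rank_nta[eligible] <- rank_transform(tab$nta[eligible])
  }
  dplyr::arrange(tab, is.na(.data$barcode), .data$barcode)
}

#' Per-contig telomere-like read counts
#'
#' @param classified Output of [classify_reads()] carrying a `contig` column;
#'   records without one count under `"unmapped"`.
#' @return Tibble with `contig`, `total`, `telomere_like`, `nta`.
#' @export
per_contig_counts <- function(classified) {
  stopifnot("is_telomere_like" %in% names(classified))
  if (!"contig" %in% names(classified)) classified$contig <- NA_character_
  classified |>
    dplyr::mutate(contig = dplyr::coalesce(.data$contig, "unmapped")) |>
    dplyr::group_by(.data$contig) |>
    dplyr::summarise(
      total = dplyr::n(),
      telomere_like = sum(.data$is_telomere_like),
      .groups = "drop"
    ) |>
    dplyr::mutate(nta = compute_nta(.data$telomere_like, .data$total)) |>
    dplyr::arrange(.data$contig == "unmapped", .data$contig)
}

#' Write the per-cell count table / library summary
#'
#' The cell table is a TSV with header exactly
#' `barcode, total, telomere_like, nta, rank_nta`; nta values are written at
#' 6 significant digits and the reserved no-barcode row (barcode `NA`) is
#' written with an empty barcode field. The library summary is a flat
#' key/value file.
#'
#' @param cells Output of [per_cell_counts()].
#' @param summary One-row tibble from [library_summary()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cell_counts <- function(cells, path) {
  out <- cells |>
    dplyr::mutate(
      barcode = dplyr::coalesce(.data$barcode, ""),
      nta = signif(.data$nta, 6),
      rank_nta = signif(.data$rank_nta, 6)
    )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' @rdname write_cell_counts
#' @export
write_library_summary <- function(summary, path) {
  stopifnot(nrow(summary) == 1L)
  lines <- vapply(names(summary), function(k) {
    v <- summary[[k]]
    paste0(k, "=", if (is.numeric(v)) format(v, digits = 10) else as.character(v))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
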