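#' Read FASTQ files into a read tibble
#'
#' Reads single or paired FASTQ (optionally gzipped) into the package's
#' standard read table. Cell barcodes can come from a separate barcode read
#' file, or from the leading `barcode_length` bases of R1 or R2 (in which
#' case those bases are stripped from the sequence).
#'
#' @param path FASTQ file (R1).
#' @param mate_path Optional FASTQ file for the mate read (R2).
#' @param barcode_path Optional FASTQ file whose sequences are the cell
#'   barcodes, in the same order as `path`.
#' @param barcode_from One of `"none"`, `"file"`, `"r1"`, `"r2"`.
#' @param barcode_length Number of leading bases used as barcode when
#'   `barcode_from` is `"r1"` or `"r2"`.
#' @return Tibble with `read_id`, `sequence`, and, when applicable,
#'   `mate_sequence` and `barcode`.
#' @export
read_fastq <- function(path, mate_path = NULL, barcode_path = NULL,
                       barcode_from = c("none", "file", "r1", "r2"),
                       barcode_length = 16L) {
  barcode_from <- match.arg(barcode_from)
  if (!is.null(barcode_path) && barcode_from == "none") barcode_from <- "file"
  r1 <- read_fastq_one(path)
  out <- tibble::tibble(read_id = names(r1),
                        sequence = unname(as.character(r1)))
  # FASTQ ids may carry comments after whitespace; keep the id token only
  out$read_id <- sub("\\s.*$", "", out$read_id)
  if (!is.null(mate_path)) {
    r2 <- read_fastq_one(mate_path)
    if (length(r2) != nrow(out)) {
      rlang::abort(sprintf(
        "pairing error: %s has %d records but %s has %d",
        path, nrow(out), mate_path, length(r2)
      ))
    }
    out$mate_sequence <- unname(as.character(r2))
  }
  if (barcode_from == "file") {
    if (is.null(barcode_path)) rlang::abort("barcode_from='file' needs barcode_path")
    bc <- read_fastq_one(barcode_path)
    if (length(bc) != nrow(out)) {
      rlang::abort(sprintf(
        "pairing error: barcode file %s has %d records but %s has %d",
        barcode_path, length(bc), path, nrow(out)
      ))
    }
    out$barcode <- unname(as.character(bc))
  } else if (barcode_from == "r1") {
    out$barcode <- substr(out$sequence, 1L, barcode_length)
    out$sequence <- substr(out$sequence, barcode_length + 1L, nchar(out$sequence))
  } else if (barcode_from == "r2") {
    if (is.null(mate_path)) rlang::abort("barcode_from='r2' needs mate_path")
    out$barcode <- substr(out$mate_sequence, 1L, barcode_length)
    out$mate_sequence <- substr(out$mate_sequence, barcode_length + 1L,
                                nchar(out$mate_sequence))
  }
  out
}

read_fastq_one <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  n_lines <- length(readLines(path, warn = FALSE))
  if (n_lines %% 4L != 0L) {
    rlang::abort(sprintf(
      "FASTQ parse error in %s: %d lines is not a multiple of 4 (truncated record at line %d)",
      path, n_lines, (n_lines %/% 4L) * 4L + 1L
    ))
  }
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) {
      rlang::abort(sprintf("FASTQ parse error in %s: %s", path, conditionMessage(e)))
    }
  )
  stats::setNames(x, names(x))
}

#' Read a FASTA file into a read tibble
#'
#' @param path FASTA file (optionally gzipped).
#' @return Tibble with `read_id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  tibble::tibble(
    read_id = sub("\\s.*$", "", names(x)),
    sequence = unname(as.character(x))
  )
}

#' Read SAM/BAM alignment records, including unmapped ones
#'
#' Streams all records of a BAM (or plain-text SAM, converted on the fly)
#' into the standard read table. Telomere-like reads typically fail to align,
#' so unmapped records are always consumed. Secondary and supplementary
#' alignments are flagged so that counting can exclude them.
#'
#' @param path BAM or SAM file.
#' @param barcode_tag Cell-barcode tag (default `"CB"`); records lacking the
#'   tag get `NA` and fall back to `fallback_tag` when that is present.
#' @param fallback_tag Secondary tag tried when `barcode_tag` is absent
#'   (default `"CR"`; set `NULL` to disable).
#' @return Tibble with `read_id`, `sequence`, `barcode`, `contig`
#'   (`"unmapped"` for unaligned records), `flag`, `secondary`,
#'   `supplementary`, `duplicate`.
#' @export
read_alignment <- function(path, barcode_tag = "CB", fallback_tag = "CR") {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  tags <- unique(c(barcode_tag, fallback_tag))
  tags <- tags[!vapply(tags, is.null, logical(1))]
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "seq"),
    tag = tags
  )
  res <- Rsamtools::scanBam(path, param = param)[[1]]
  flag <- res$flag
  bc <- res$tag[[barcode_tag]]
  if (is.null(bc)) bc <- rep(NA_character_, length(flag))
  if (!is.null(fallback_tag)) {
    fb <- res$tag[[fallback_tag]]
    if (!is.null(fb)) bc <- dplyr::coalesce(bc, fb)
  }
  contig <- as.character(res$rname)
  unmapped <- bitwAnd(flag, 4L) > 0L
  contig[unmapped | is.na(contig)] <- "unmapped"
  tibble::tibble(
    read_id = res$qname,
    sequence = unname(as.character(res$seq)),
    barcode = bc,
    contig = contig,
    flag = flag,
    secondary = bitwAnd(flag, 256L) > 0L,
    supplementary = bitwAnd(flag, 2048L) > 0L,
    duplicate = bitwAnd(flag, 1024L) > 0L
  )
}

#' Drop secondary/supplementary alignment records before counting
#'
#' Totals should include unmapped and duplicate records but count each
#' fragment's primary record once; both exclusions are switchable.
#'
#' @param reads Output of [read_alignment()].
#' @param drop_secondary,drop_supplementary,drop_duplicates Which flag
#'   classes to remove (duplicates kept by default).
#' @return Filtered tibble.
#' @export
filter_alignment_records <- function(reads, drop_secondary = TRUE,
                                     drop_supplementary = TRUE,
                                     drop_duplicates = FALSE) {
  if (drop_secondary && "secondary" %in% names(reads)) {
    reads <- dplyr::filter(reads, !.data$secondary)
  }
  if (drop_supplementary && "supplementary" %in% names(reads)) {
    reads <- dplyr::filter(reads, !.data$supplementary)
  }
  if (drop_duplicates && "duplicate" %in% names(reads)) {
    reads <- dplyr::filter(reads, !.data$duplicate)
  }
  reads
}

#' Write a read tibble as FASTQ or FASTA
#'
#' @param reads Tibble with `read_id` and `sequence`.
#' @param path Output path (gzipped when it ends in `.gz`).
#' @param format `"fastq"` (constant Phred 40 qualities) or `"fasta"`.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  compress <- grepl("\\.gz$", path)
  if (format == "fastq") {
    quals <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = quals, compress = compress)
  } else {
    Biostrings::writeXStringSet(x, path, format = "fasta", compress = compress)
  }
  invisible(path)
}
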