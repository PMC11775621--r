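#' Configuration for nanopore telomere-read processing
#'
#' Nanopore telomere capture reads start at the chromosome end on the C-rich
#' strand: a ligated biotin adapter, then `TAACCC` telomere repeats, then the
#' subtelomere. Processing trims the adapter, drops short reads, and walks
#' the repeat tract to locate the subtelomere boundary.
#'
#' @param adapter Adapter ligated to the telomere (default `"CCCTCCGATA"`),
#'   trimmed only when found at position 0.
#' @param min_read_length Minimum trimmed read length in bp (default 8000;
#'   shorter reads are flagged, not dropped).
#' @param boundary_motif Repeat motif walked during the boundary scan
#'   (default `"TAACCC"`, the C-strand telomere repeat).
#' @param max_gap Maximum gap in bp tolerated between consecutive motif
#'   matches during the scan (default 18, inclusive — three degenerate
#'   hexamers).
#' @param adapter_mismatches Mismatches tolerated in the adapter match
#'   (default 0).
#' @return An object of class `nanopore_config`.
#' @export
nanopore_config <- function(adapter = "CCCTCCGATA",
                            min_read_length = 8000L,
                            boundary_motif = "TAACCC",
                            max_gap = 18L,
                            adapter_mismatches = 0L) {
  if (nchar(adapter) == 0L) rlang::abort("adapter must be non-empty")
  if (max_gap < 0L) rlang::abort("max_gap must be >= 0")
  structure(
    list(adapter = adapter,
         min_read_length = as.integer(min_read_length),
         boundary_motif = boundary_motif,
         max_gap = as.integer(max_gap),
         adapter_mismatches = as.integer(adapter_mismatches)),
    class = "nanopore_config"
  )
}

#' Preprocess nanopore telomere reads
#'
#' Trims the ligation adapter when it matches at the very start of the read
#' (within `adapter_mismatches`), applies the minimum-length filter to the
#' trimmed sequence, and locates the subtelomere boundary with
#' [find_subtelomere_start()]. Reads failing the filter are flagged rather
#' than dropped, so the caller decides.
#'
#' @param reads Tibble with `read_id` and `sequence`.
#' @param config A [nanopore_config()].
#' @return Tibble with `read_id`, `trimmed_sequence`, `adapter_found`,
#'   `passed_length_filter`, `subtelomere_start` and `telomere_length`
#'   (identical to `subtelomere_start`: bases of telomere proper before the
#'   boundary).
#' @export
preprocess_reads <- function(reads, config = nanopore_config()) {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  ad <- config$adapter
  k <- nchar(ad)
  prefix <- substr(reads$sequence, 1L, k)
  mm <- vapply(prefix, function(p) {
    if (nchar(p) < k) return(k)
    hamming(p, ad)
  }, integer(1), USE.NAMES = FALSE)
  found <- mm <= config$adapter_mismatches
  trimmed <- ifelse(found,
                    substr(reads$sequence, k + 1L, nchar(reads$sequence)),
                    reads$sequence)
  boundary <- find_subtelomere_start(trimmed, config)
  tibble::tibble(
    read_id = reads$read_id,
    trimmed_sequence = trimmed,
    adapter_found = found,
    passed_length_filter = nchar(trimmed) >= config$min_read_length,
    subtelomere_start = boundary,
    telomere_length = boundary
  )
}

#' Locate the subtelomere boundary in a telomere read
#'
#' Walks the C-strand repeat tract: starting at position 0, the sequence is
#' repeatedly scanned for the boundary motif beginning within `[0, max_gap]`
#' bases of the current position (leftmost match taken); after each match the
#' cursor jumps past the matched motif. When no further match is found within
#' the gap window, the cursor is the subtelomere start. A pure tract of `k`
#' motif copies followed by non-matching sequence therefore returns `6 * k`.
#'
#' @param seq Character vector of (trimmed) read sequences.
#' @param config A [nanopore_config()].
#' @return Integer vector of 0-based subtelomere start positions (equal to
#'   the telomere-proper length).
#' @export
#' @examples
#' find_subtelomere_start(paste0(strrep("TAACCC", 10), strrep("G", 50)))
find_subtelomere_start <- function(seq, config = nanopore_config()) {
  motif <- config$boundary_motif
  m <- nchar(motif)
  gap <- config$max_gap
  vapply(seq, function(s) {
    starts <- as.integer(gregexpr(motif, s, fixed = TRUE)[[1]])
    starts <- starts[starts > 0L] - 1L
    pos <- 0L
    i <- 1L
    n <- length(starts)
    while (i <= n) {
      # first motif start at or beyond the cursor
      while (i <= n && starts[i] < pos) i <- i + 1L
      if (i > n || starts[i] > pos + gap) break
      pos <- starts[i] + m
      i <- i + 1L
    }
    pos
  }, integer(1), USE.NAMES = FALSE)
}

#' Build a training set for the read-origin model
#'
#' Draws uniform random 50-bp windows from four compartments and labels each
#' with a log-transformed distance from the telomere: windows within the
#' telomere proper get distance 0; subtelomeric windows their distance from
#' the boundary; chromatin and centromere windows fixed artificial
#' pseudo-distances (defaults 1e7 and 5e7). Labels are `log10(1 + d)`. The
#' reverse complement of every window is appended with the same label, and
#' the draw is deterministic under `seed`.
#'
#' Telomere and subtelomere windows are drawn from processed nanopore reads
#' (boundary known); chromatin and centromere windows from labelled
#' reference regions (e.g. a [make_genome()] annotation).
#'
#' @param telomere_reads Output of [preprocess_reads()] (only reads passing
#'   the length filter are used; pass everything and let the function
#'   filter).
#' @param reference_regions Tibble with `sequence` and `region`
#'   (`"chromatin"` / `"centromere"`) columns, e.g. from
#'   [genome_compartments()].
#' @param n_per_class Windows drawn per class before reverse-complement
#'   augmentation.
#' @param seed Integer RNG seed.
#' @param window Window width in bp (default 50).
#' @param chromatin_distance,centromere_distance Fixed pseudo-distances in
#'   bp for the non-telomeric classes.
#' @param max_subtelomere_extent Subtelomeric windows are drawn within this
#'   many bases past the boundary (default 5000).
#' @return Tibble with `sequence` (length-`window` strings), `label`
#'   (`log10(1 + d)`) and `region`; `2 * n_per_class` rows per usable class.
#'   Regions shorter than `window` are skipped with a message.
#' @export
build_training_set <- function(telomere_reads, reference_regions,
                               n_per_class = 1000L, seed = 1L,
                               window = 50L,
                               chromatin_distance = 1e7,
                               centromere_distance = 5e7,
                               max_subtelomere_extent = 5000L) {
  withr::local_seed(seed)
  usable <- dplyr::filter(telomere_reads, .data$passed_length_filter)
  if (nrow(usable) == 0L) usable <- telomere_reads
  draw_from_reads <- function(region_name) {
    picks <- vector("list", n_per_class)
    for (i in seq_len(n_per_class)) {
      r <- usable[sample.int(nrow(usable), 1L), ]
      len <- nchar(r$trimmed_sequence)
      b <- r$subtelomere_start
      if (region_name == "telomere") {
        if (b < window) { picks[[i]] <- NULL; next }
        start <- sample.int(b - window + 1L, 1L) - 1L
        d <- 0
      } else {
        hi <- min(len, b + max_subtelomere_extent)
        if (hi - b < window) { picks[[i]] <- NULL; next }
        start <- b + sample.int(hi - b - window + 1L, 1L) - 1L
        d <- start - b
      }
      picks[[i]] <- tibble::tibble(
        sequence = substr0(r$trimmed_sequence, start, start + window),
        label = log10(1 + d),
        region = region_name
      )
    }
    dplyr::bind_rows(picks)
  }
  draw_from_regions <- function(region_name, d) {
    regs <- dplyr::filter(reference_regions, .data$region == region_name)
    short <- nchar(regs$sequence) < window
    if (any(short)) {
      message(sprintf("build_training_set: skipped %d %s region(s) shorter than %d bp",
                      sum(short), region_name, window))
      regs <- regs[!short, , drop = FALSE]
    }
    if (nrow(regs) == 0L) return(NULL)
    lens <- nchar(regs$sequence) - window + 1L
    idx <- sample.int(nrow(regs), n_per_class, replace = TRUE, prob = lens)
    start <- vapply(lens[idx], function(l) sample.int(l, 1L) - 1L, integer(1))
    tibble::tibble(
      sequence = substr0(regs$sequence[idx], start, start + window),
      label = log10(1 + d),
      region = region_name
    )
  }
  out <- dplyr::bind_rows(
    draw_from_reads("telomere"),
    draw_from_reads("subtelomere"),
    draw_from_regions("chromatin", chromatin_distance),
    draw_from_regions("centromere", centromere_distance)
  )
  aug <- dplyr::mutate(out, sequence = revcomp(.data$sequence))
  dplyr::bind_rows(out, aug)
}

#' Write a training set as TSV
#'
#' @param examples Output of [build_training_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_training_set <- function(examples, path) {
  utils::write.table(examples[, c("sequence", "label", "region")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
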