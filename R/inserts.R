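#' The 95-bp non-fragmenting Tn5 cargo oligo
#'
#' Sense strand of the 95-bp cargo used to mark Tn5 insertion sites without
#' fragmenting the genome: a transposon-derived body terminated on both
#' sides by the 19-bp mosaic-end (ME) recognition sequences. The antisense
#' oligo is its reverse complement.
#'
#' @return A single 95-character string.
#' @export
tn5_cargo_sequence <- function() {
  paste0(
    "CTGTCTCTTATACACATCTACGCGGTGGACAAAAAATTTCATTTGGAACT",
    "AGATTTGACCTCAGCTTCAATGCCAGAGATGTGTATAAGAGACAG"
  )
}

#' Cargo specification for insert detection
#'
#' @param sense_sequence The cargo sense strand (default
#'   [tn5_cargo_sequence()]).
#' @param seed_length Exact-match seed length taken from each cargo terminus
#'   (default 20).
#' @param max_mismatch_fraction Maximum mismatch fraction allowed over the
#'   full cargo when verifying a candidate (default 0.1).
#' @param flank_window Length of genomic flank recorded on each side of an
#'   insert (default 30).
#' @return An object of class `cargo_spec`.
#' @export
cargo_spec <- function(sense_sequence = tn5_cargo_sequence(),
                       seed_length = 20L,
                       max_mismatch_fraction = 0.1,
                       flank_window = 30L) {
  check_dna(sense_sequence, "sense_sequence", allow_n = FALSE)
  structure(
    list(
      sense_sequence = sense_sequence,
      cargo_length = nchar(sense_sequence),
      seed_length = as.integer(seed_length),
      max_mismatch_fraction = max_mismatch_fraction,
      flank_window = as.integer(flank_window)
    ),
    class = "cargo_spec"
  )
}

# Hamming mismatches between equal-length strings.
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(NA_integer_)
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Candidate insert starts in one read for one cargo orientation:
# seed-and-verify from both cargo termini. Seeds tolerate mismatches at the
# same rate as the full-length verification, so a single sequencing error in
# a terminus does not hide the insert.
candidate_inserts <- function(seq, cargo_seq, spec) {
  L <- nchar(cargo_seq)
  k <- spec$seed_length
  max_mm <- floor(spec$max_mismatch_fraction * L)
  seed_mm <- floor(spec$max_mismatch_fraction * k)
  seed5 <- substr(cargo_seq, 1L, k)
  seed3 <- substr(cargo_seq, L - k + 1L, L)
  subject <- Biostrings::DNAString(seq)
  seed_hits <- function(seed) {
    Biostrings::start(Biostrings::matchPattern(seed, subject,
                                               max.mismatch = seed_mm))
  }
  starts5 <- seed_hits(seed5) - 1L                      # 0-based insert start
  starts3 <- seed_hits(seed3) - 1L - (L - k)            # implied insert start
  cand <- sort(unique(c(starts5, starts3)))
  cand <- cand[cand >= 0L & cand + L <= nchar(seq)]
  if (length(cand) == 0L) return(NULL)
  mm <- vapply(cand, function(s) hamming(substr0(seq, s, s + L), cargo_seq),
               integer(1))
  keep <- mm <= max_mm
  if (!any(keep)) return(NULL)
  data.frame(insert_start = cand[keep], mismatches = mm[keep])
}

#' Detect non-fragmenting Tn5 cargo insertions in long reads
#'
#' Seed-and-verify search: exact `seed_length`-bp seeds from both cargo
#' termini, in both orientations, are located in each read; each candidate is
#' verified over the full cargo length at up to `max_mismatch_fraction`
#' mismatches. Overlapping candidates are resolved to the lowest-mismatch
#' (ties: leftmost) event; multiple non-overlapping inserts per read are
#' allowed.
#'
#' @param reads Tibble with `read_id` and `sequence` (long reads).
#' @param cargo A [cargo_spec()].
#' @param d_max Maximum target-site-duplication length measured on the
#'   flanks (default 15).
#' @return Tibble of events: `read_id`, `insert_start`, `insert_end`
#'   (0-based half-open), `orientation` (`"forward"`/`"reverse"`),
#'   `mismatches`, `left_flank`, `right_flank`, `duplication_length`. Flanks
#'   shorter than `flank_window` are left `NA` along with their duplication
#'   length.
#' @export
find_inserts <- function(reads, cargo = cargo_spec(), d_max = 15L) {
  stopifnot(is.data.frame(reads), all(c("read_id", "sequence") %in% names(reads)))
  L <- cargo$cargo_length
  fw <- cargo$sense_sequence
  rc <- revcomp(fw)
  events <- purrr::map2_dfr(reads$read_id, reads$sequence, function(id, seq) {
    if (nchar(seq) < L) return(NULL)
    f <- candidate_inserts(seq, fw, cargo)
    r <- candidate_inserts(seq, rc, cargo)
    if (!is.null(f)) f$orientation <- "forward"
    if (!is.null(r)) r$orientation <- "reverse"
    cand <- rbind(f, r)
    if (is.null(cand) || nrow(cand) == 0L) return(NULL)
    cand <- cand[order(cand$mismatches, cand$insert_start), , drop = FALSE]
    chosen <- cand[0, , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      s <- cand$insert_start[i]
      if (nrow(chosen) == 0L ||
          all(s + L <= chosen$insert_start | s >= chosen$insert_start + L)) {
        chosen <- rbind(chosen, cand[i, , drop = FALSE])
      }
    }
    chosen <- chosen[order(chosen$insert_start), , drop = FALSE]
    w <- cargo$flank_window
    lf <- ifelse(chosen$insert_start >= w,
                 substr0(seq, chosen$insert_start - w, chosen$insert_start),
                 NA_character_)
    rf <- ifelse(chosen$insert_start + L + w <= nchar(seq),
                 substr0(seq, chosen$insert_start + L, chosen$insert_start + L + w),
                 NA_character_)
    tibble::tibble(
      read_id = id,
      insert_start = chosen$insert_start,
      insert_end = chosen$insert_start + L,
      orientation = chosen$orientation,
      mismatches = chosen$mismatches,
      left_flank = lf,
      right_flank = rf
    )
  })
  if (nrow(events) == 0L) {
    return(tibble::tibble(
      read_id = character(0), insert_start = integer(0),
      insert_end = integer(0), orientation = character(0),
      mismatches = integer(0), left_flank = character(0),
      right_flank = character(0), duplication_length = integer(0)
    ))
  }
  ok <- !is.na(events$left_flank) & !is.na(events$right_flank)
  events$duplication_length <- NA_integer_
  events$duplication_length[ok] <- duplication_length(
    events$left_flank[ok], events$right_flank[ok], d_max = d_max)
  events
}

#' Target-site-duplication length from insert flanks
#'
#' The largest `d <= d_max` such that the last `d` bases of the left flank
#' equal the first `d` bases of the right flank — the standard definition of
#' a target-site duplication created by staggered transposase cuts
#' (wild-type Tn5 is reported to duplicate 9 bp).
#'
#' @param left_flank,right_flank Character vectors of flanking sequence,
#'   each at least `d_max` long.
#' @param d_max Maximum duplication length considered (default 15).
#' @return Integer vector of measured duplication lengths (0 when none).
#' @export
#' @examples
#' duplication_length("TTTTTTACGTACGTA", "ACGTACGTATTTTTT")
duplication_length <- function(left_flank, right_flank, d_max = 15L) {
  if (length(left_flank) == 0L) return(integer(0))
  if (any(nchar(left_flank) < d_max) || any(nchar(right_flank) < d_max)) {
    rlang::abort(sprintf("flanks must be at least d_max = %d bases long", d_max))
  }
  mapply(function(l, r) {
    nl <- nchar(l)
    for (d in d_max:1) {
      if (substr(l, nl - d + 1L, nl) == substr(r, 1L, d)) return(d)
    }
    0L
  }, left_flank, right_flank, USE.NAMES = FALSE)
}

#' Per-base motif matrix around insertion points
#'
#' Extracts the genomic sequence within `window` bases on each side of each
#' insertion point (the cargo itself removed), reverse complements the
#' context of reverse-orientation events, stacks the contexts and returns
#' their [base_frequency_matrix()]. Events too close to a read end to
#' provide a full window are skipped; a message reports how many.
#'
#' @param events Output of [find_inserts()].
#' @param reads The read tibble the events came from.
#' @param window Context half-width in bp (default 20).
#' @return A `base_freq_matrix` of dimension `2 * window` x 5.
#' @export
insertion_context_matrix <- function(events, reads, window = 20L) {
  ctx <- insertion_contexts(events, reads, window)
  skipped <- sum(is.na(ctx))
  if (skipped > 0L) {
    message(sprintf("insertion_context_matrix: skipped %d event(s) with windows outside read bounds", skipped))
  }
  ctx <- ctx[!is.na(ctx)]
  if (length(ctx) == 0L) rlang::abort("no usable insertion events for a context matrix")
  base_frequency_matrix(ctx, length = 2L * window)
}

insertion_contexts <- function(events, reads, window) {
  seqs <- stats::setNames(reads$sequence, reads$read_id)
  purrr::pmap_chr(
    list(events$read_id, events$insert_start, events$insert_end,
         events$orientation),
    function(id, s, e, ori) {
      seq <- seqs[[id]]
      if (is.null(seq) || s < window || e + window > nchar(seq)) {
        return(NA_character_)
      }
      ctx <- paste0(substr0(seq, s - window, s), substr0(seq, e, e + window))
      if (ori == "reverse") ctx <- revcomp(ctx)
      ctx
    }
  )
}

#' Telomere-motif proximity around insertion points
#'
#' For each event, the signed offset from the insertion point to the nearest
#' start of the canonical telomere motif within `range` bp (cargo bases
#' masked so motifs inside the insert never count). Events with no motif in
#' range are excluded.
#'
#' @param events Output of [find_inserts()].
#' @param reads The read tibble the events came from.
#' @param range Maximum absolute offset in bp (default 60).
#' @param motif Motif searched for (default `"TTAGGG"`); its reverse
#'   complement is searched too.
#' @return Tibble with columns `offset` and `n`, one row per observed
#'   offset; empty when no event has a motif in range.
#' @export
telomere_proximity_histogram <- function(events, reads, range = 60L,
                                         motif = "TTAGGG") {
  masked <- mask_inserts(reads, events)
  seqs <- stats::setNames(masked$sequence, masked$read_id)
  offsets <- purrr::pmap_dbl(
    list(events$read_id, events$insert_start, events$insert_end),
    function(id, s, e) {
      seq <- seqs[[id]]
      if (is.null(seq)) return(NA_real_)
      starts <- c(
        as.integer(gregexpr(motif, seq, fixed = TRUE)[[1]]),
        as.integer(gregexpr(revcomp(motif), seq, fixed = TRUE)[[1]])
      )
      starts <- starts[starts > 0L] - 1L
      if (length(starts) == 0L) return(NA_real_)
      # offsets are measured in the insert-removed (host) frame: motifs 3' of
      # the insert are shifted back by the cargo length
      starts <- starts[starts < s | starts >= e]
      starts <- ifelse(starts >= e, starts - (e - s), starts)
      d <- starts - s
      d <- d[abs(d) <= range]
      if (length(d) == 0L) return(NA_real_)
      d[which.min(abs(d))]
    })
  offsets <- offsets[!is.na(offsets)]
  if (length(offsets) == 0L) {
    return(tibble::tibble(offset = integer(0), n = integer(0)))
  }
  tibble::as_tibble(table(offset = as.integer(offsets)), .name_repair = "minimal") |>
    dplyr::mutate(offset = as.integer(as.character(.data$offset))) |>
    dplyr::arrange(.data$offset)
}

# Replace detected cargo bases by N so motif scans ignore them while
# read coordinates are preserved.
mask_inserts <- function(reads, events) {
  out <- tibble::as_tibble(reads)
  if (nrow(events) == 0L) return(out)
  by_read <- split(events, events$read_id)
  idx <- match(names(by_read), out$read_id)
  for (i in seq_along(by_read)) {
    j <- idx[i]
    if (is.na(j)) next
    seq <- out$sequence[j]
    for (r in seq_len(nrow(by_read[[i]]))) {
      s <- by_read[[i]]$insert_start[r]
      e <- by_read[[i]]$insert_end[r]
      substr(seq, s + 1L, e) <- strrep("N", e - s)
    }
    out$sequence[j] <- seq
  }
  out
}

#' nTA over all long reads versus insert-bearing reads only
#'
#' Classifies reads with the cargo bases masked, then reports the
#' telomere-like fraction over the whole read set and over the subset that
#' carries at least one detected insert. Similar values indicate that the
#' compartment producing the telomere-like signal also receives insertions;
#' a much lower insert-only nTA indicates that the telomere proper is
#' protected from transposition.
#'
#' @param reads Tibble with `read_id`, `sequence`.
#' @param cargo A [cargo_spec()].
#' @param config A [motif_scan_config()].
#' @return Tibble with rows `all` and `insert_only`: `n_reads`,
#'   `telomere_like`, `nta` (`NA` when no read carries an insert).
#' @export
nta_by_insert_status <- function(reads, cargo = cargo_spec(),
                                 config = motif_scan_config()) {
  events <- find_inserts(reads, cargo)
  masked <- mask_inserts(reads, events)
  cls <- classify_reads(masked, config)
  with_insert <- cls$read_id %in% events$read_id
  tibble::tibble(
    group = c("all", "insert_only"),
    n_reads = c(nrow(cls), sum(with_insert)),
    telomere_like = c(sum(cls$is_telomere_like),
                      sum(cls$is_telomere_like[with_insert])),
  ) |>
    dplyr::mutate(nta = compute_nta(.data$telomere_like, .data$n_reads))
}

#' Write insert events as a BED-like TSV
#'
#' @param events Output of [find_inserts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_insert_events <- function(events, path) {
  out <- events[, c("read_id", "insert_start", "insert_end", "orientation",
                    "duplication_length")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
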