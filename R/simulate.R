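#' Specification of a synthetic genome
#'
#' Each arm runs, from the chromosome end inward: a telomere proper of pure
#' tandem TTAGGG; a degenerate subtelomere made of blocks of 3-10 tandem
#' hexamers (canonical or variant, at a tunable substitution rate) separated
#' by random spacers; chromatin proper (random sequence); and a centromere
#' of tandem 171-bp monomer copies. All compartment boundaries are recorded
#' as 0-based half-open intervals.
#'
#' @param n_arms Number of arms (default 4).
#' @param telomere_repeats TTAGGG copies in the telomere proper per arm
#'   (default 300, i.e. 1800 bp).
#' @param subtelomere_length Subtelomere length in bp per arm (default 2000).
#' @param tvr_rate Probability that a subtelomeric repeat hexamer is a
#'   variant (`T**GGG`, non-canonical) rather than TTAGGG (default 0.5).
#' @param block_range Tandem hexamers per subtelomeric repeat block
#'   (default `c(3, 10)`).
#' @param spacer_range Random-spacer length range between blocks in bp
#'   (default `c(20, 50)`).
#' @param chromatin_length Chromatin-proper length in bp per arm
#'   (default 50000).
#' @param centromere_monomers Copies of the 171-bp centromeric monomer per
#'   arm (default 50).
#' @param seed Integer seed; the genome is a pure function of the spec.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(n_arms = 4L, telomere_repeats = 300L,
                        subtelomere_length = 2000L, tvr_rate = 0.5,
                        block_range = c(3L, 10L), spacer_range = c(20L, 50L),
                        chromatin_length = 50000L, centromere_monomers = 50L,
                        seed = 1L) {
  stopifnot(n_arms >= 1L, telomere_repeats >= 0L, subtelomere_length >= 0L,
            tvr_rate >= 0, tvr_rate <= 1, chromatin_length >= 0L,
            centromere_monomers >= 0L)
  structure(
    list(n_arms = as.integer(n_arms),
         telomere_repeats = as.integer(telomere_repeats),
         subtelomere_length = as.integer(subtelomere_length),
         tvr_rate = tvr_rate,
         block_range = as.integer(block_range),
         spacer_range = as.integer(spacer_range),
         chromatin_length = as.integer(chromatin_length),
         centromere_monomers = as.integer(centromere_monomers),
         seed = as.integer(seed)),
    class = "genome_spec"
  )
}

# One subtelomere: repeat blocks (mixed canonical/variant tandem hexamers)
# separated by random spacers, truncated to the requested length. Spacers
# are G-free so every T**GGG hexamer in the subtelomere is an intentional
# repeat: any GGG must sit at positions 3-5 of a block hexamer, which pins
# matching windows to the hexamer frame.
make_subtelomere <- function(length_bp, tvr_rate, block_range, spacer_range,
                             motif = "TTAGGG") {
  if (length_bp <= 0L) return("")
  variants <- variant_hexamers(motif_scan_config(canonical_motif = motif))
  parts <- character(0)
  total <- 0L
  while (total < length_bp) {
    n_hex <- sample_range(block_range[1], block_range[2])
    hexes <- ifelse(stats::runif(n_hex) < tvr_rate,
                    sample(variants, n_hex, replace = TRUE), motif)
    block <- paste0(hexes, collapse = "")
    spacer <- random_dna(1L, sample_range(spacer_range[1], spacer_range[2]),
                         alphabet = c("A", "C", "T"))
    parts <- c(parts, block, spacer)
    total <- total + nchar(block) + nchar(spacer)
  }
  substr(paste0(parts, collapse = ""), 1L, length_bp)
}

#' Generate a synthetic genome
#'
#' @param spec A [genome_spec()].
#' @return An object of class `synthetic_genome`: list with `arms` (tibble
#'   `arm`, `sequence`), `compartments` (tibble `arm`, `compartment`,
#'   `start`, `end`, 0-based half-open) and the `spec`.
#' @export
#' @examples
#' g <- make_genome(genome_spec(n_arms = 1, chromatin_length = 500,
#'                              centromere_monomers = 2, seed = 7))
#' g$compartments
make_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  withr::local_seed(spec$seed)
  monomer <- random_dna(1L, 171L)
  arms <- vector("list", spec$n_arms)
  comps <- vector("list", spec$n_arms)
  for (a in seq_len(spec$n_arms)) {
    telo <- strrep("TTAGGG", spec$telomere_repeats)
    sub <- make_subtelomere(spec$subtelomere_length, spec$tvr_rate,
                            spec$block_range, spec$spacer_range)
    chrom <- random_dna(1L, spec$chromatin_length)
    cen <- strrep(monomer, spec$centromere_monomers)
    lens <- c(telomere = nchar(telo), subtelomere = nchar(sub),
              chromatin = nchar(chrom), centromere = nchar(cen))
    ends <- cumsum(lens)
    arm_name <- paste0("arm", a)
    arms[[a]] <- tibble::tibble(arm = arm_name,
                                sequence = paste0(telo, sub, chrom, cen))
    comps[[a]] <- tibble::tibble(
      arm = arm_name,
      compartment = names(lens),
      start = as.integer(ends - lens),
      end = as.integer(ends)
    )
  }
  genome <- list(arms = dplyr::bind_rows(arms),
                 compartments = dplyr::bind_rows(comps),
                 spec = spec)
  if (sum(nchar(genome$arms$sequence)) == 0L) {
    rlang::abort("genome_spec produces a zero-length genome")
  }
  structure(genome, class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("<synthetic_genome> %d arm(s), %s bp total\n",
              nrow(x$arms), format(sum(nchar(x$arms$sequence)), big.mark = ",")))
  print(dplyr::count(x$compartments, .data$compartment,
                     wt = .data$end - .data$start, name = "bp"))
  invisible(x)
}

#' Compartment sequences of a synthetic genome
#'
#' @param genome A [make_genome()] result.
#' @return Tibble with `arm`, `region` (compartment name) and `sequence`,
#'   one row per compartment interval — the reference-region format
#'   consumed by [build_training_set()].
#' @export
genome_compartments <- function(genome) {
  seqs <- stats::setNames(genome$arms$sequence, genome$arms$arm)
  genome$compartments |>
    dplyr::mutate(
      region = .data$compartment,
      sequence = unname(substring(seqs[.data$arm], .data$start + 1L, .data$end))
    ) |>
    dplyr::select("arm", "region", "sequence")
}

#' Condensation state: per-compartment accessibility weights
#'
#' Models global chromatin condensation as relative Tn5 accessibility per
#' compartment. The telomere proper defaults to a near-zero weight,
#' encoding its protection from transposition; raising the condensation
#' parameter `condensation` scales the chromatin-proper weight down by
#' `1 / (1 + condensation)`, which raises the expected nTA — a condensed
#' genome yields relatively more reads from the repeat compartments.
#'
#' @param telomere,subtelomere,chromatin,centromere Relative per-bp
#'   sampling weights (>= 0, not all zero).
#' @param condensation Non-negative condensation parameter (default 0).
#' @return An object of class `condensation_state`.
#' @export
condensation_state <- function(telomere = 0.01, subtelomere = 1,
                               chromatin = 1, centromere = 0.3,
                               condensation = 0) {
  w <- c(telomere = telomere, subtelomere = subtelomere,
         chromatin = chromatin, centromere = centromere)
  if (any(w < 0) || all(w == 0)) {
    rlang::abort("weights must be >= 0 and not all zero")
  }
  if (condensation < 0) rlang::abort("condensation must be >= 0")
  w["chromatin"] <- w["chromatin"] / (1 + condensation)
  structure(list(weights = w, condensation = condensation),
            class = "condensation_state")
}

#' Uniform (WGS-like) sampling state
#'
#' Equal weight for every compartment — uniform coverage, as from
#' mechanically sheared whole-genome sequencing.
#'
#' @return A `condensation_state` with all weights 1.
#' @export
uniform_state <- function() {
  condensation_state(telomere = 1, subtelomere = 1, chromatin = 1,
                     centromere = 1, condensation = 0)
}

# Sample fragment start positions across compartments, weighted per bp.
# Starts leave room for at least `reserve` bases inside the compartment so
# the truth compartment label is exact for the reads derived from the
# fragment (fragments are later clipped at the compartment end).
sample_positions <- function(genome, weights, n, reserve = 0L) {
  comp <- genome$compartments
  len <- pmax(comp$end - comp$start - reserve, 0L)
  w <- unname(weights[comp$compartment]) * len
  idx <- sample.int(nrow(comp), n, replace = TRUE, prob = w)
  offset <- floor(stats::runif(n) * len[idx])
  tibble::tibble(
    arm = comp$arm[idx],
    compartment = comp$compartment[idx],
    start = comp$start[idx] + as.integer(offset),
    comp_end = comp$end[idx]
  )
}

#' Simulate ATAC-like paired reads under a condensation state
#'
#' Fragment start positions are sampled proportionally to per-compartment
#' accessibility weights; each fragment yields an R1 (5' end) and an R2
#' (reverse complement of the 3' end). With `barcodes`, each fragment is
#' assigned a cell and per-barcode condensation parameters can differ, so
#' per-cell nTA differences have a known ground truth.
#'
#' @param genome A [make_genome()] result.
#' @param state A [condensation_state()]; ignored for a barcode when
#'   `barcode_condensation` supplies one.
#' @param n_fragments Number of fragments to draw.
#' @param read_length Read length in bp (default 50).
#' @param fragment_range Fragment length range in bp (default `c(150, 350)`).
#' @param barcodes Optional character vector of cell barcodes.
#' @param barcode_condensation Optional numeric vector (same length as
#'   `barcodes`) of per-cell condensation parameters.
#' @param paired Emit mates (default `TRUE`)? With `FALSE` only R1 is kept.
#' @param seed Integer seed; output is a pure function of the arguments.
#' @return List with `reads` (tibble `read_id`, `sequence`,
#'   `mate_sequence`, `barcode`) and `truth` (tibble `read_id`, `barcode`,
#'   `arm`, `compartment`, `start`, `fragment_length`).
#' @export
simulate_atac_reads <- function(genome, state = condensation_state(),
                                n_fragments, read_length = 50L,
                                fragment_range = c(150L, 350L),
                                barcodes = NULL, barcode_condensation = NULL,
                                paired = TRUE, seed = 1L) {
  stopifnot(n_fragments >= 1L)
  withr::local_seed(seed)
  if (is.null(barcodes)) {
    pos <- sample_positions(genome, state$weights, n_fragments,
                            reserve = read_length)
    pos$barcode <- NA_character_
  } else {
    bc_idx <- sample.int(length(barcodes), n_fragments, replace = TRUE)
    if (is.null(barcode_condensation)) {
      pos <- sample_positions(genome, state$weights, n_fragments,
                              reserve = read_length)
    } else {
      stopifnot(length(barcode_condensation) == length(barcodes))
      parts <- lapply(seq_along(barcodes), function(i) {
        n_i <- sum(bc_idx == i)
        if (n_i == 0L) return(NULL)
        st <- condensation_state(
          telomere = state$weights[["telomere"]],
          subtelomere = state$weights[["subtelomere"]],
          chromatin = state$weights[["chromatin"]] * (1 + state$condensation),
          centromere = state$weights[["centromere"]],
          condensation = barcode_condensation[i]
        )
        p <- sample_positions(genome, st$weights, n_i, reserve = read_length)
        p$.bc <- i
        p
      })
      # fragments come out grouped by barcode; read ids are assigned later,
      # so within-file order is immaterial
      pos <- dplyr::bind_rows(parts)
    }
    pos$barcode <- barcodes[if (is.null(barcode_condensation)) bc_idx else pos$.bc]
    pos$.bc <- NULL
  }
  n <- nrow(pos)
  frag_len <- sample_range(fragment_range[1], fragment_range[2], n)
  arm_seq <- stats::setNames(genome$arms$sequence, genome$arms$arm)
  arm_len <- nchar(arm_seq)[pos$arm]
  # clip at the compartment end so the truth label is exact for both mates
  frag_end <- pmin(pos$start + frag_len, pos$comp_end, arm_len)
  frags <- substring(arm_seq[pos$arm], pos$start + 1L, frag_end)
  r1 <- substr(frags, 1L, read_length)
  reads <- tibble::tibble(
    read_id = sprintf("frag%07d", seq_len(n)),
    sequence = r1,
    barcode = pos$barcode
  )
  if (paired) {
    flen <- nchar(frags)
    r2 <- revcomp(substr(frags, pmax(1L, flen - read_length + 1L), flen))
    reads$mate_sequence <- r2
    reads <- reads[, c("read_id", "sequence", "mate_sequence", "barcode")]
  }
  truth <- tibble::tibble(
    read_id = reads$read_id,
    barcode = pos$barcode,
    arm = pos$arm,
    compartment = pos$compartment,
    start = pos$start,
    fragment_length = as.integer(frag_end - pos$start)
  )
  list(reads = reads, truth = truth)
}

#' Insert cargo copies into a host sequence
#'
#' Builds the sequence of a read carrying non-fragmenting Tn5 cargo
#' insertions: at each (0-based, ascending, non-overlapping) position the
#' cargo — reverse complemented for reverse orientation — is inserted, and
#' with `duplication = d > 0` the `d` host bases immediately 5' of the
#' insertion point are duplicated immediately 3' of the insert, mimicking a
#' staggered-cut target-site duplication.
#'
#' @param host Host DNA string.
#' @param positions Integer vector of 0-based insertion points, strictly
#'   increasing.
#' @param orientations Character vector (`"forward"`/`"reverse"`), recycled.
#' @param cargo_sequence Cargo sense strand (default [tn5_cargo_sequence()]).
#' @param duplication Target-site-duplication length `d` (default 0).
#' @return List with `sequence` (the built read) and `insert_start` (the
#'   0-based insert positions in the built read).
#' @export
insert_cargo_into_read <- function(host, positions, orientations = "forward",
                                   cargo_sequence = tn5_cargo_sequence(),
                                   duplication = 0L) {
  stopifnot(duplication >= 0L, all(diff(positions) > 0L),
            all(positions >= duplication), all(positions <= nchar(host)))
  orientations <- rep_len(orientations, length(positions))
  pieces <- character(0)
  starts <- integer(length(positions))
  prev <- 0L
  built <- 0L
  for (i in seq_along(positions)) {
    p <- positions[i]
    ins <- if (orientations[i] == "reverse") revcomp(cargo_sequence) else cargo_sequence
    left <- substr0(host, prev, p)
    dup <- if (duplication > 0L) substr0(host, p - duplication, p) else ""
    starts[i] <- built + nchar(left)
    pieces <- c(pieces, left, ins, dup)
    built <- built + nchar(left) + nchar(ins) + nchar(dup)
    prev <- p
  }
  pieces <- c(pieces, substr0(host, prev, nchar(host)))
  list(sequence = paste0(pieces, collapse = ""), insert_start = starts)
}

#' Simulate long reads carrying Tn5 cargo insertions
#'
#' Reads are drawn uniformly from the genome (mechanical shearing); each
#' receives a Poisson number of cargo insertions at positions accepted with
#' probability proportional to the insertion weight of the underlying
#' compartment (telomere proper defaults to 0: protected from
#' transposition). Orientation is random; a fixed target-site duplication
#' can be emitted.
#'
#' @param genome A [make_genome()] result.
#' @param cargo A [cargo_spec()].
#' @param insertion_rate Expected insertions per read (default 1).
#' @param duplication Target-site-duplication length in `[0, 15]`
#'   (default 0).
#' @param n_reads Number of reads.
#' @param read_length_range Read length range in bp (default
#'   `c(1500, 2500)`).
#' @param insert_weights Named per-compartment insertion weights.
#' @param seed Integer seed.
#' @return List with `reads` (tibble `read_id`, `sequence`) and `truth`
#'   (tibble `read_id`, `insert_start` in the final read, `orientation`,
#'   `duplication`).
#' @export
simulate_longreads_with_inserts <- function(genome, cargo = cargo_spec(),
                                            insertion_rate = 1,
                                            duplication = 0L,
                                            n_reads = 100L,
                                            read_length_range = c(1500L, 2500L),
                                            insert_weights = c(telomere = 0,
                                                               subtelomere = 1,
                                                               chromatin = 1,
                                                               centromere = 1),
                                            seed = 1L) {
  stopifnot(duplication >= 0L, duplication <= 15L)
  withr::local_seed(seed)
  arm_seq <- stats::setNames(genome$arms$sequence, genome$arms$arm)
  comp <- genome$compartments
  L_cargo <- cargo$cargo_length
  reads <- vector("list", n_reads)
  truths <- vector("list", n_reads)
  w_max <- max(insert_weights)
  for (i in seq_len(n_reads)) {
    len <- sample_range(read_length_range[1], read_length_range[2])
    arm <- sample(genome$arms$arm, 1L,
                  prob = nchar(arm_seq[genome$arms$arm]))
    alen <- nchar(arm_seq[[arm]])
    len <- min(len, alen)
    start <- sample.int(alen - len + 1L, 1L) - 1L
    host <- substr0(arm_seq[[arm]], start, start + len)
    k <- stats::rpois(1L, insertion_rate)
    pos <- integer(0)
    attempts <- 0L
    while (length(pos) < k && attempts < 50L * max(k, 1L)) {
      attempts <- attempts + 1L
      cand <- sample_range(duplication + 1L, len - 1L)
      gpos <- start + cand
      cidx <- which(comp$arm == arm & comp$start <= gpos & gpos < comp$end)
      wgt <- if (length(cidx) == 1L)
        insert_weights[[comp$compartment[cidx]]] else 0
      if (w_max > 0 && stats::runif(1L) < wgt / w_max &&
          all(abs(cand - pos) > L_cargo + duplication + 5L)) {
        pos <- c(pos, cand)
      }
    }
    pos <- sort(pos)
    ori <- sample(c("forward", "reverse"), length(pos), replace = TRUE)
    built <- insert_cargo_into_read(host, pos, ori, cargo$sense_sequence,
                                    duplication)
    id <- sprintf("longread%05d", i)
    reads[[i]] <- tibble::tibble(read_id = id, sequence = built$sequence)
    if (length(pos) > 0L) {
      truths[[i]] <- tibble::tibble(
        read_id = id,
        insert_start = built$insert_start,
        orientation = ori,
        duplication = as.integer(duplication)
      )
    }
  }
  list(reads = dplyr::bind_rows(reads), truth = dplyr::bind_rows(truths))
}

#' Simulate nanopore telomere-capture reads
#'
#' Each read models a C-strand chromosome-end read: the ligation adapter,
#' then `k` copies of `TAACCC` (the per-read telomere length, drawn
#' uniformly from `telomere_bp_range` and rounded to whole hexamers), a
#' short motif-free spacer, then the reverse complement of the arm's
#' subtelomere and enough chromatin continuation to reach the drawn read
#' length. The recorded truth boundary is exactly `6 * k`; the motif-free
#' spacer guarantees the boundary scan terminates there on noise-free
#' reads.
#'
#' @param genome A [make_genome()] result.
#' @param config A [nanopore_config()] (provides the adapter).
#' @param n_reads Number of reads.
#' @param telomere_bp_range Telomere tract length range in bp
#'   (default `c(2000, 8000)`).
#' @param read_length_range Total read length range in bp (default
#'   `c(6000, 14000)` so that some reads fail the 8-kb filter, as in real
#'   libraries).
#' @param seed Integer seed.
#' @return List with `reads` (tibble `read_id`, `sequence`) and `truth`
#'   (tibble `read_id`, `boundary` — the subtelomere start in the trimmed
#'   read — and `read_length` of the trimmed read).
#' @export
simulate_nanopore_telomere_reads <- function(genome,
                                             config = nanopore_config(),
                                             n_reads = 50L,
                                             telomere_bp_range = c(2000L, 8000L),
                                             read_length_range = c(6000L, 14000L),
                                             seed = 1L) {
  withr::local_seed(seed)
  comps <- genome_compartments(genome)
  reads <- vector("list", n_reads)
  truth <- vector("list", n_reads)
  spacer_len <- 25L
  for (i in seq_len(n_reads)) {
    arm <- sample(genome$arms$arm, 1L)
    sub_c <- revcomp(comps$sequence[comps$arm == arm &
                                      comps$region == "subtelomere"][1])
    chrom_c <- revcomp(comps$sequence[comps$arm == arm &
                                        comps$region == "chromatin"][1])
    k <- max(1L, as.integer(round(stats::runif(1L, telomere_bp_range[1],
                                               telomere_bp_range[2]) / 6)))
    total <- sample_range(read_length_range[1], read_length_range[2])
    repeat {
      spacer <- random_dna(1L, spacer_len)
      if (!grepl(config$boundary_motif, spacer, fixed = TRUE)) break
    }
    body <- paste0(strrep("TAACCC", k), spacer, sub_c, chrom_c)
    extra <- total - nchar(body)
    if (extra > 0L) body <- paste0(body, random_dna(1L, extra))
    body <- substr(body, 1L, max(total, 6L * k + spacer_len))
    id <- sprintf("nanopore%05d", i)
    reads[[i]] <- tibble::tibble(read_id = id,
                                 sequence = paste0(config$adapter, body))
    truth[[i]] <- tibble::tibble(read_id = id, boundary = 6L * k,
                                 read_length = nchar(body))
  }
  list(reads = dplyr::bind_rows(reads), truth = dplyr::bind_rows(truth))
}

#' Write the parameters of a simulation as a sidecar key/value file
#'
#' @param params Named list of scalar parameters.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_simulation_params <- function(params, path) {
  lines <- vapply(names(params), function(k) {
    paste0(k, "=", paste(format(params[[k]]), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
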