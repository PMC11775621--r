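test_that("preprocess trims the adapter only at position 0 and flags length", {
  cfg <- nanopore_config(min_read_length = 8000L)
  x <- strrep("TAACCC", 10)
  rec <- preprocess_reads(tibble::tibble(read_id = "a",
                                         sequence = paste0("CCCTCCGATA", x)),
                          cfg)
  expect_true(rec$adapter_found)
  expect_identical(rec$trimmed_sequence, x)
  # a 7999-bp trimmed read fails the filter, an 8000-bp one passes
  long <- tibble::tibble(
    read_id = c("short", "ok"),
    sequence = paste0("CCCTCCGATA",
                      c(strrep("A", 7999), strrep("A", 8000)))
  )
  rec2 <- preprocess_reads(long, cfg)
  expect_identical(rec2$passed_length_filter, c(FALSE, TRUE))
  # adapter elsewhere in the read is not trimmed
  rec3 <- preprocess_reads(tibble::tibble(read_id = "c",
                                          sequence = paste0("AA", "CCCTCCGATA")),
                           cfg)
  expect_false(rec3$adapter_found)
  expect_identical(rec3$trimmed_sequence, paste0("AA", "CCCTCCGATA"))
  # mismatch allowance
  rec4 <- preprocess_reads(
    tibble::tibble(read_id = "d", sequence = paste0("ACCTCCGATA", x)),
    nanopore_config(adapter_mismatches = 1L)
  )
  expect_true(rec4$adapter_found)
})

test_that("the boundary scan walks TAACCC with gaps up to 18 bp inclusive", {
  tail18 <- strrep("G", 100)
  expect_identical(find_subtelomere_start(paste0(strrep("TAACCC", 10), tail18)),
                   60L)
  # no motif within the first 19 positions: boundary at 0
  expect_identical(find_subtelomere_start(paste0(strrep("G", 19), "TAACCC")),
                   0L)
  # an exactly-18-bp interruption is tolerated, 19 bp is not
  expect_identical(
    find_subtelomere_start(paste0("TAACCC", strrep("G", 18), "TAACCC", tail18)),
    30L)
  expect_identical(
    find_subtelomere_start(paste0("TAACCC", strrep("G", 19), "TAACCC", tail18)),
    6L)
})

test_that("boundary scan equals 6k on pure repeat prefixes for k in 1..50", {
  withr::local_seed(89)
  for (k in 1:50) {
    seq <- paste0(strrep("TAACCC", k), strrep("G", 30))
    expect_identical(find_subtelomere_start(seq), 6L * k)
  }
  # deterministic and idempotent on already-trimmed input
  g <- test_genome()
  np <- simulate_nanopore_telomere_reads(g, n_reads = 10, seed = 97)
  r1 <- preprocess_reads(np$reads)
  r2 <- preprocess_reads(
    tibble::tibble(read_id = r1$read_id, sequence = r1$trimmed_sequence))
  expect_false(any(r2$adapter_found))
  expect_identical(r2$subtelomere_start, r1$subtelomere_start)
})

test_that("training sets label windows by log10(1 + distance) per region", {
  g <- test_genome()
  np <- simulate_nanopore_telomere_reads(g, n_reads = 20, seed = 101)
  rec <- preprocess_reads(np$reads)
  ts <- build_training_set(rec, genome_compartments(g), n_per_class = 100,
                           seed = 5)
  expect_true(all(nchar(ts$sequence) == 50L))
  expect_true(all(ts$label[ts$region == "telomere"] == 0))
  sub <- ts$label[ts$region == "subtelomere"]
  expect_true(all(sub >= 0 & sub <= log10(1 + 5000)))
  expect_true(all(ts$label[ts$region == "chromatin"] == log10(1 + 1e7)))
  expect_true(all(ts$label[ts$region == "centromere"] == log10(1 + 5e7)))
  # a window starting d bases past the boundary is labelled log10(1 + d)
  fake <- tibble::tibble(read_id = "f",
                         trimmed_sequence = strrep("A", 3000),
                         adapter_found = FALSE, passed_length_filter = TRUE,
                         subtelomere_start = 1000L, telomere_length = 1000L)
  one <- build_training_set(fake, genome_compartments(g)[0, ],
                            n_per_class = 50, seed = 6,
                            max_subtelomere_extent = 2000L)
  d <- 10^(one$label[one$region == "subtelomere"]) - 1
  expect_true(all(d >= 0 & d <= 2000 - 50 + 1))
  # revcomp augmentation doubles the set, second half mirrors the first
  n <- nrow(ts) / 2
  expect_identical(ts$sequence[n + 1], revcomp(ts$sequence[1]))
  expect_identical(ts$label[seq_len(n)], ts$label[n + seq_len(n)])
  # determinism under seed
  ts2 <- build_training_set(rec, genome_compartments(g), n_per_class = 100,
                            seed = 5)
  expect_identical(ts, ts2)
  # regions shorter than the window are skipped with a message
  tiny <- tibble::tibble(arm = "x", region = "centromere", sequence = "ACGT")
  expect_message(
    build_training_set(rec, tiny, n_per_class = 10, seed = 7),
    "skipped"
  )
})

test_that("training sets serialize as TSV", {
  g <- test_genome()
  np <- simulate_nanopore_telomere_reads(g, n_reads = 5, seed = 103)
  ts <- build_training_set(preprocess_reads(np$reads),
                           genome_compartments(g), n_per_class = 20, seed = 8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_training_set(ts, path)
  back <- utils::read.delim(path)
  expect_identical(names(back), c("sequence", "label", "region"))
  expect_identical(nrow(back), nrow(ts))
})
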