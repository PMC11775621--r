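test_that("the cargo oligo is 95 bp with mosaic-end termini", {
  cargo <- tn5_cargo_sequence()
  expect_identical(nchar(cargo), 95L)
  # both termini are the 19-bp ME recognition sequence (one reverse complemented)
  expect_identical(substr(cargo, 1, 19), revcomp(substr(cargo, 77, 95)))
})

test_that("find_inserts locates clean insertions exactly, both orientations", {
  withr::local_seed(53)
  host <- random_dna_vec(1, 2095)[1]
  fwd <- insert_cargo_into_read(substr(host, 1, 2000), 1000L, "forward")
  rev <- insert_cargo_into_read(substr(host, 1, 2000), 1000L, "reverse")
  ev_f <- find_inserts(tibble::tibble(read_id = "f", sequence = fwd$sequence))
  ev_r <- find_inserts(tibble::tibble(read_id = "r", sequence = rev$sequence))
  expect_identical(ev_f$insert_start, 1000L)
  expect_identical(ev_f$insert_end, 1095L)
  expect_identical(ev_f$orientation, "forward")
  expect_identical(ev_r$insert_start, 1000L)
  expect_identical(ev_r$orientation, "reverse")
  none <- find_inserts(tibble::tibble(read_id = "n", sequence = host))
  expect_identical(nrow(none), 0L)
})

test_that("insert recall is 1.0 clean and >= 0.95 at 5% substitution noise", {
  withr::local_seed(59)
  n <- 300L
  hosts <- random_dna_vec(n, 1000)
  pos <- sample(200:700, n, replace = TRUE)
  ori <- sample(c("forward", "reverse"), n, replace = TRUE)
  built <- mapply(function(h, p, o) {
    insert_cargo_into_read(h, p, o)$sequence
  }, hosts, pos, ori)
  ids <- sprintf("r%03d", seq_len(n))
  clean <- find_inserts(tibble::tibble(read_id = ids, sequence = unname(built)))
  hit_clean <- mapply(function(id, p, o) {
    any(clean$read_id == id & clean$insert_start == p & clean$orientation == o)
  }, ids, pos, ori)
  expect_identical(mean(hit_clean), 1)
  noisy <- vapply(unname(built), mutate_dna, character(1), rate = 0.05,
                  USE.NAMES = FALSE)
  ev <- find_inserts(tibble::tibble(read_id = ids, sequence = noisy))
  hit <- mapply(function(id, p) any(ev$read_id == id & ev$insert_start == p),
                ids, pos)
  expect_gte(mean(hit), 0.95)
})

test_that("duplication_length matches its brute-force oracle for d in 0..12", {
  withr::local_seed(61)
  for (i in 1:200) {
    d <- sample(0:12, 1)
    host <- random_dna_vec(1, 80)[1]
    built <- insert_cargo_into_read(host, 40L, "forward", duplication = d)
    left <- substr(built$sequence, 40 - 29, 40)
    right <- substr(built$sequence, 40 + 96, 40 + 96 + 29)
    expect_identical(duplication_length(left, right),
                     as.integer(oracle_duplication_length(left, right)))
    # the constructed duplication is at least recovered (chance can extend it)
    expect_gte(duplication_length(left, right), d)
  }
  # disjoint flank alphabets cannot share a duplication
  expect_identical(duplication_length(strrep("A", 20), strrep("G", 20)), 0L)
  expect_error(duplication_length("ACGT", "ACGT"), "at least")
})

test_that("insertion context matrices stack flanks, skipping edge events", {
  host <- strrep("ACGTACGTAC", 30)  # identical host for every read
  reads <- tibble::tibble(
    read_id = c("a", "b"),
    sequence = vapply(c(100L, 150L), function(p) {
      insert_cargo_into_read(host, p, "forward")$sequence
    }, character(1))
  )
  events <- find_inserts(reads, d_max = 5L)
  m <- insertion_context_matrix(events, reads, window = 20L)
  expect_identical(nrow(m), 40L)
  # periodic identical hosts give unit columns at every position
  expect_true(all(apply(m[, c("A", "C", "G", "T")], 1, max) == 1))
  # an event too close to the read end is skipped with a message
  tight <- tibble::tibble(
    read_id = "t",
    sequence = insert_cargo_into_read(substr(host, 1, 120), 5L, "forward")$sequence
  )
  ev_t <- find_inserts(tight, d_max = 5L)
  expect_message(insertion_context_matrix(dplyr::bind_rows(events, ev_t),
                                          dplyr::bind_rows(reads, tight)),
                 "skipped 1")
  expect_error(insertion_context_matrix(events[0, ], reads), "no usable")
})

test_that("telomere proximity histogram measures offsets to TTAGGG", {
  withr::local_seed(67)
  host <- paste0(gsub("G", "C", random_dna_vec(1, 300)), strrep("TTAGGG", 20),
                 gsub("G", "C", random_dna_vec(1, 300)))
  # insertion exactly at the first repeat boundary
  b <- insert_cargo_into_read(host, 300L, "forward")
  reads <- tibble::tibble(read_id = "x", sequence = b$sequence)
  ev <- find_inserts(reads, d_max = 5L)
  h <- telomere_proximity_histogram(ev, reads)
  expect_identical(h$offset, 0L)
  expect_identical(sum(h$n), 1L)
  # no motif on either strand: A/T-only host
  host2 <- paste0(sample(c("A", "T"), 400, replace = TRUE), collapse = "")
  b2 <- insert_cargo_into_read(host2, 200L, "forward")
  reads2 <- tibble::tibble(read_id = "y", sequence = b2$sequence)
  h2 <- telomere_proximity_histogram(find_inserts(reads2, d_max = 5L), reads2)
  expect_identical(nrow(h2), 0L)
})

test_that("nTA by insert status masks cargo and flags protected telomeres", {
  withr::local_seed(71)
  # no cargo anywhere: insert-only nTA undefined
  plain <- tibble::tibble(read_id = "p", sequence = random_dna_vec(1, 500))
  res <- nta_by_insert_status(plain)
  expect_true(is.na(res$nta[res$group == "insert_only"]))
  # a read whose only motifs sit inside the cargo is not telomere-like
  cargo_only <- cargo_spec(sense_sequence = paste0(
    substr(tn5_cargo_sequence(), 1, 77), strrep("TTAGGG", 3)
  ))
  read <- tibble::tibble(
    read_id = "m",
    sequence = insert_cargo_into_read(gsub("G", "C", random_dna_vec(1, 400)),
                                      200L, "forward",
                                      cargo_sequence = cargo_only$sense_sequence)$sequence
  )
  res2 <- nta_by_insert_status(read, cargo_only)
  expect_identical(res2$telomere_like, c(0L, 0L))
  # telomere-protected genome: insert-bearing reads under-sample the
  # telomere. The telomere proper must exceed the read length so that some
  # reads are entirely telomeric and can never carry an insert.
  g <- make_genome(genome_spec(n_arms = 2L, telomere_repeats = 1000L,
                               subtelomere_length = 500L,
                               chromatin_length = 20000L,
                               centromere_monomers = 20L, seed = 73))
  sim <- simulate_longreads_with_inserts(g, insertion_rate = 2, n_reads = 150,
                                         seed = 79)
  res3 <- nta_by_insert_status(sim$reads)
  expect_lt(res3$nta[res3$group == "insert_only"],
            res3$nta[res3$group == "all"])
})

test_that("insert events write a BED-like TSV", {
  withr::local_seed(83)
  host <- random_dna_vec(1, 500)[1]
  b <- insert_cargo_into_read(host, 250L, "reverse", duplication = 4L)
  ev <- find_inserts(tibble::tibble(read_id = "w", sequence = b$sequence))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_insert_events(ev, path)
  back <- utils::read.delim(path)
  expect_identical(names(back), c("read_id", "insert_start", "insert_end",
                                  "orientation", "duplication_length"))
  expect_identical(back$insert_start, 250L)
  expect_gte(back$duplication_length, 4L)
})
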