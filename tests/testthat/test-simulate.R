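test_that("synthetic genomes are deterministic with exact compartments", {
  spec <- genome_spec(n_arms = 2L, telomere_repeats = 300L,
                      subtelomere_length = 1500L, chromatin_length = 5000L,
                      centromere_monomers = 10L, seed = 21)
  g1 <- make_genome(spec)
  g2 <- make_genome(spec)
  expect_identical(g1$arms, g2$arms)
  telo <- g1$compartments[g1$compartments$compartment == "telomere", ][1, ]
  expect_identical(telo$end - telo$start, 1800L)
  arm1 <- g1$arms$sequence[1]
  expect_identical(substring(arm1, 1, 1800), strrep("TTAGGG", 300))
  cen <- g1$compartments[g1$compartments$compartment == "centromere", ][1, ]
  expect_identical(cen$end - cen$start, 1710L)
  # TVR rate 0: the subtelomere carries no non-canonical T**GGG hexamers
  g0 <- make_genome(genome_spec(n_arms = 1L, tvr_rate = 0,
                                subtelomere_length = 3000L,
                                chromatin_length = 1000L,
                                centromere_monomers = 0L, seed = 22))
  sub_seq <- genome_compartments(g0)$sequence[
    genome_compartments(g0)$region == "subtelomere"]
  v <- count_variant_repeats(sub_seq, motif_scan_config(scan_both_strands = FALSE))
  expect_identical(nrow(v), 0L)
})

test_that("ATAC simulation respects weights, barcodes and conservation", {
  g <- test_genome(seed = 23)
  # all weight on the telomere proper: every fragment is telomere-like
  telo_only <- condensation_state(telomere = 1, subtelomere = 0,
                                  chromatin = 0, centromere = 0)
  sim <- simulate_atac_reads(g, telo_only, n_fragments = 500, seed = 25)
  expect_true(all(sim$truth$compartment == "telomere"))
  cls <- classify_reads(sim$reads)
  expect_true(all(cls$is_telomere_like))
  # truth table conserves fragment counts, also per barcode
  sim2 <- simulate_atac_reads(g, condensation_state(), n_fragments = 2000,
                              barcodes = c("AAA", "BBB"), seed = 27)
  expect_identical(nrow(sim2$truth), 2000L)
  expect_identical(sort(unique(sim2$reads$barcode)), c("AAA", "BBB"))
  # bit-identical reruns under the same seed
  sim3 <- simulate_atac_reads(g, condensation_state(), n_fragments = 2000,
                              barcodes = c("AAA", "BBB"), seed = 27)
  expect_identical(sim2$reads, sim3$reads)
  expect_identical(sim2$truth, sim3$truth)
})

test_that("classification round-trips the truth table on pure fragments", {
  g <- test_genome(seed = 29)
  telo_only <- condensation_state(telomere = 1, subtelomere = 0,
                                  chromatin = 0, centromere = 0)
  chrom_only <- condensation_state(telomere = 0, subtelomere = 0,
                                   chromatin = 1, centromere = 0)
  telo <- simulate_atac_reads(g, telo_only, n_fragments = 300, seed = 31)
  chrom <- simulate_atac_reads(g, chrom_only, n_fragments = 300, seed = 33)
  # noise-free pure-repeat fragments scan positive; chromatin fragments may
  # only rarely contain a chance motif run
  expect_true(all(classify_reads(telo$reads)$is_telomere_like))
  expect_lt(mean(classify_reads(chrom$reads)$is_telomere_like), 0.01)
})

test_that("expected nTA increases with the condensation parameter", {
  g <- test_genome(seed = 37)
  n <- 20000L
  ntas <- vapply(c(0, 4), function(cond) {
    sim <- simulate_atac_reads(g, condensation_state(condensation = cond),
                               n_fragments = n, seed = 39 + as.integer(cond))
    library_summary(classify_reads(sim$reads, runs = FALSE))$nta
  }, numeric(1))
  expect_gt(ntas[2], ntas[1])
})

test_that("long-read simulation places recoverable inserts", {
  g <- test_genome(seed = 41)
  sim <- simulate_longreads_with_inserts(g, insertion_rate = 1.5,
                                         duplication = 9L, n_reads = 40,
                                         seed = 43)
  ev <- find_inserts(sim$reads)
  # every truth event is recovered at its exact position
  found <- mapply(function(id, p) any(ev$read_id == id & ev$insert_start == p),
                  sim$truth$read_id, sim$truth$insert_start)
  expect_true(all(found))
  # constructed 9-bp duplications measure exactly 9 on mismatch-free reads
  measured <- ev$duplication_length[!is.na(ev$duplication_length)]
  expect_true(all(measured >= 9L))
  expect_identical(sort(unique(measured))[1], 9L)
  # no cargo at rate 0; duplication 0 measures 0 most of the time
  none <- simulate_longreads_with_inserts(g, insertion_rate = 0, n_reads = 10,
                                          seed = 47)
  expect_identical(nrow(none$truth), 0L)
  expect_identical(nrow(find_inserts(none$reads)), 0L)
  d0 <- simulate_longreads_with_inserts(g, insertion_rate = 1, duplication = 0L,
                                        n_reads = 30, seed = 53)
  ev0 <- find_inserts(d0$reads)
  m0 <- ev0$duplication_length[!is.na(ev0$duplication_length)]
  expect_identical(sort(unique(m0))[1], 0L)
})

test_that("nanopore simulation writes recoverable boundaries and lengths", {
  g <- test_genome(seed = 59)
  sim <- simulate_nanopore_telomere_reads(g, n_reads = 30, seed = 61)
  rec <- preprocess_reads(sim$reads)
  expect_identical(rec$subtelomere_start, sim$truth$boundary)
  expect_true(all(rec$adapter_found))
  expect_identical(nchar(rec$trimmed_sequence), sim$truth$read_length)
  # the length distribution straddles the 8-kb filter
  expect_true(any(rec$passed_length_filter) && !all(rec$passed_length_filter))
  # determinism
  sim2 <- simulate_nanopore_telomere_reads(g, n_reads = 30, seed = 61)
  expect_identical(sim$reads, sim2$reads)
})

test_that("simulation parameter sidecars round-trip", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_simulation_params(list(mode = "atac", n = 100L, seed = 7L), path)
  lines <- readLines(path)
  expect_true("mode=atac" %in% lines && "seed=7" %in% lines)
})
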