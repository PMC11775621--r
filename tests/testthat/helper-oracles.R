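# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive so they share no code path with the implementation.

# Largest k with motif^k a substring of seq: try every k at every offset.
oracle_max_tandem_run <- function(seq, motif) {
  best <- 0L
  k <- 1L
  repeat {
    probe <- strrep(motif, k)
    if (nchar(probe) > nchar(seq)) break
    found <- FALSE
    for (off in 1:(nchar(seq) - nchar(probe) + 1L)) {
      if (substr(seq, off, off + nchar(probe) - 1L) == probe) {
        found <- TRUE
        break
      }
    }
    if (!found) break
    best <- k
    k <- k + 1L
  }
  best
}

# Largest d <= d_max with suffix(left, d) == prefix(right, d), by direct loop.
oracle_duplication_length <- function(left, right, d_max = 15L) {
  best <- 0L
  for (d in seq_len(d_max)) {
    if (substr(left, nchar(left) - d + 1L, nchar(left)) == substr(right, 1L, d)) {
      best <- d
    }
  }
  best
}

# Rank both vectors by hand (average ties), then plain Pearson.
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

random_dna_vec <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# Substitution noise at a fixed per-base rate.
mutate_dna <- function(s, rate) {
  ch <- strsplit(s, "")[[1]]
  idx <- which(stats::runif(length(ch)) < rate)
  if (length(idx) > 0L) {
    ch[idx] <- vapply(ch[idx], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1))
  }
  paste0(ch, collapse = "")
}

# Small genome reused across tests (kept modest so the suite stays fast).
test_genome <- function(seed = 3L, ...) {
  make_genome(genome_spec(n_arms = 2L, telomere_repeats = 300L,
                          subtelomere_length = 2000L,
                          chromatin_length = 20000L,
                          centromere_monomers = 20L, seed = seed, ...))
}
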