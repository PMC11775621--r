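test_that("spearman_cor matches independent oracles with ties", {
  expect_equal(spearman_cor(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(spearman_cor(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_true(is.na(spearman_cor(c(1, 1, 1), c(1, 2, 3))))
  expect_error(spearman_cor(1:3, 1:4), "equal length")
  withr::local_seed(131)
  for (i in 1:200) {
    x <- sample(1:5, 10, replace = TRUE)  # plenty of ties
    y <- stats::rnorm(10)
    expect_equal(spearman_cor(x, y), oracle_spearman(x, y), tolerance = 1e-12)
    expect_equal(spearman_cor(x, y),
                 stats::cor(x, y, method = "spearman"), tolerance = 1e-12)
  }
})

make_feature_fixture <- function(n_cells = 60L) {
  nta <- tibble::tibble(barcode = sprintf("c%03d", seq_len(n_cells)),
                        nta = stats::runif(n_cells))
  feats <- tibble::tibble(
    cell = nta$barcode,
    mirror = nta$nta,
    noise = stats::rnorm(n_cells),
    shuffled = sample(nta$nta),
    flat = 1
  )
  list(nta = nta, feats = feats)
}

test_that("feature correlation ranks |rho| with BH adjustment", {
  withr::local_seed(137)
  fx <- make_feature_fixture()
  res <- correlate_features(fx$nta, fx$feats)
  expect_identical(res$feature[1], "mirror")
  expect_equal(res$rho[1], 1)
  # constant feature: undefined, ranked last
  expect_identical(res$feature[nrow(res)], "flat")
  expect_true(is.na(res$rho[nrow(res)]))
  expect_true(all(res$p_adj >= res$p_value - 1e-12, na.rm = TRUE))
  # a permuted copy of nTA is not a top correlate
  expect_gt(abs(res$rho[1]) - abs(res$rho[res$feature == "shuffled"]), 0.5)
  bad <- fx$feats
  bad$cell <- paste0("x", bad$cell)
  expect_error(correlate_features(fx$nta, bad), "no overlapping")
})

test_that("null p-values are uniform (Kolmogorov-Smirnov)", {
  withr::local_seed(139)
  n_cells <- 40L
  nta <- tibble::tibble(barcode = sprintf("c%02d", seq_len(n_cells)),
                        nta = stats::runif(n_cells))
  feats <- as.data.frame(matrix(stats::rnorm(n_cells * 1000), n_cells))
  names(feats) <- sprintf("f%04d", seq_len(1000))
  feats <- cbind(cell = nta$barcode, feats)
  res <- correlate_features(nta, feats)
  ks <- suppressWarnings(stats::ks.test(res$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

grouped_fixture <- function(sizes, rho_by_group, seed = 149) {
  withr::local_seed(seed)
  groups <- rep(names(sizes), unname(sizes))
  n <- length(groups)
  barcode <- sprintf("b%05d", seq_len(n))
  nta <- stats::runif(n)
  consistent <- unlist(lapply(names(sizes), function(g) {
    sel <- groups == g
    r <- rho_by_group[[g]]
    r * nta[sel] + sqrt(1 - r^2) * stats::runif(sum(sel))
  }))
  list(
    nta = tibble::tibble(barcode = barcode, nta = nta),
    feats = tibble::tibble(cell = barcode, consistent = consistent,
                           noise = stats::rnorm(n)),
    groups = tibble::tibble(barcode = barcode, group = groups)
  )
}

test_that("grouped ranking filters small groups and aggregates rho", {
  fx <- grouped_fixture(c(g1 = 1200L, g2 = 1100L, g3 = 999L),
                        list(g1 = 0.6, g2 = 0.6, g3 = 0.6))
  res <- grouped_motif_ranking(fx$nta, fx$feats, fx$groups)
  expect_identical(sort(unique(res$by_group$group)), c("g1", "g2"))
  g3row <- res$groups[res$groups$group == "g3", ]
  expect_false(g3row$retained)
  # consistent feature outranks noise by mean/variance
  expect_identical(res$by_feature$feature[1], "consistent")
  # adding another sub-threshold group changes nothing
  extra <- grouped_fixture(c(g1 = 1200L, g2 = 1100L, g3 = 999L),
                           list(g1 = 0.6, g2 = 0.6, g3 = 0.6))
  small <- tibble::tibble(
    barcode = sprintf("z%03d", 1:500),
    nta = stats::runif(500)
  )
  nta2 <- dplyr::bind_rows(extra$nta, small)
  feats2 <- dplyr::bind_rows(
    extra$feats,
    tibble::tibble(cell = small$barcode, consistent = stats::runif(500),
                   noise = stats::rnorm(500))
  )
  groups2 <- dplyr::bind_rows(extra$groups,
                              tibble::tibble(barcode = small$barcode,
                                             group = "tiny"))
  res2 <- grouped_motif_ranking(nta2, feats2, groups2)
  expect_equal(res$by_feature, res2$by_feature)
  # fewer than 2 retained groups is an error naming the filter
  expect_error(
    grouped_motif_ranking(fx$nta, fx$feats,
                          dplyr::mutate(fx$groups, group = "all_one")),
    "min_cells"
  )
})

test_that("consistent correlation beats alternating-sign correlation", {
  fx <- grouped_fixture(c(a = 1500L, b = 1500L, c = 1500L, d = 1500L),
                        list(a = 0.5, b = 0.5, c = 0.5, d = 0.5), seed = 151)
  # alternating feature: rho +0.5 in half the groups, -0.5 in the other half
  alt_sign <- ifelse(fx$groups$group %in% c("a", "c"), 1, -1)
  withr::local_seed(157)
  fx$feats$alternating <- alt_sign *
    (0.5 * fx$nta$nta + sqrt(0.75) * stats::runif(nrow(fx$nta)))
  res <- grouped_motif_ranking(fx$nta, fx$feats, fx$groups)
  tab <- res$by_feature
  expect_gt(tab$mean_over_var[tab$feature == "consistent"],
            tab$mean_over_var[tab$feature == "alternating"])
  # group relabeling leaves the aggregates unchanged
  relab <- dplyr::mutate(fx$groups,
                         group = chartr("abcd", "wxyz", .data$group))
  res_r <- grouped_motif_ranking(fx$nta, fx$feats, relab)
  expect_equal(res$by_feature, res_r$by_feature)
})

test_that("zero across-group variance yields a signed infinite ratio", {
  # identical per-group correlations: a feature equal to nTA in every group
  fx <- grouped_fixture(c(p = 1100L, q = 1100L), list(p = 0, q = 0),
                        seed = 163)
  fx$feats$mirror <- fx$nta$nta
  res <- grouped_motif_ranking(fx$nta, fx$feats, fx$groups)
  tab <- res$by_feature
  expect_identical(tab$mean_over_var[tab$feature == "mirror"], Inf)
  # the sentinel orders above every finite ratio of the same sign
  expect_identical(tab$feature[1], "mirror")
})
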