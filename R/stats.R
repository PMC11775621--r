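#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties share their mean rank).
#' Returns `NA` when either vector is constant, where the statistic is
#' undefined.
#'
#' @param x,y Numeric vectors of equal length (>= 3); pairs with `NA` are
#'   dropped.
#' @return Correlation in `[-1, 1]`, or `NA`.
#' @export
#' @examples
#' spearman_cor(1:3, c(10, 20, 30))
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) rlang::abort("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) rlang::abort("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}

#' Correlate per-cell nTA with a feature table
#'
#' Computes a correlation (Spearman by default) and a two-sided p-value
#' between per-cell nTA and every feature, with Benjamini-Hochberg adjusted
#' p-values alongside. Features are ranked by decreasing `|rho|`; constant
#' features get `NA` and rank last.
#'
#' @param nta Data frame with columns `barcode` and `nta` (e.g. from
#'   [per_cell_counts()]).
#' @param features Data frame whose first column is the cell identifier and
#'   remaining columns are numeric features (e.g. motif activities or gene
#'   scores).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Tibble with `feature`, `rho`, `p_value`, `p_adj`, `n_cells`,
#'   sorted by `|rho|` descending.
#' @export
correlate_features <- function(nta, features,
                               method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(all(c("barcode", "nta") %in% names(nta)))
  id_col <- names(features)[1]
  merged <- dplyr::inner_join(
    dplyr::select(nta, "barcode", "nta"),
    features,
    by = stats::setNames(id_col, "barcode")
  )
  if (nrow(merged) == 0L) rlang::abort("no overlapping cells between nta and features")
  feat_names <- setdiff(names(merged), c("barcode", "nta"))
  res <- purrr::map_dfr(feat_names, function(f) {
    v <- merged[[f]]
    ok <- !is.na(v) & !is.na(merged$nta)
    if (sum(ok) < 3L || stats::sd(v[ok]) == 0 || stats::sd(merged$nta[ok]) == 0) {
      return(tibble::tibble(feature = f, rho = NA_real_,
                            p_value = NA_real_, n_cells = sum(ok)))
    }
    ct <- suppressWarnings(
      stats::cor.test(merged$nta[ok], v[ok], method = method, exact = FALSE)
    )
    tibble::tibble(feature = f, rho = unname(ct$estimate),
                   p_value = ct$p.value, n_cells = sum(ok))
  })
  res$p_adj <- stats::p.adjust(res$p_value, method = "BH")
  dplyr::arrange(res, dplyr::desc(abs(.data$rho)))[,
    c("feature", "rho", "p_value", "p_adj", "n_cells")]
}

#' Grouped motif-correlation ranking
#'
#' Within each cell group (e.g. cell type x batch), correlates every feature
#' with per-cell nTA; groups with `n_cells <= min_cells` are excluded to
#' reduce noise (default keeps groups with more than 1000 cells). Per
#' feature, the mean, variance and mean/variance ratio of the per-group
#' correlations are reported: ranking by the mean highlights strong global
#' correlates, while the mean/variance ratio de-emphasises features (such as
#' G/C-rich motifs) whose correlation is strong but inconsistent across
#' groups. A zero variance across groups yields a signed infinite ratio,
#' which sorts above every finite ratio of the same sign.
#'
#' @param nta Data frame with `barcode` and `nta`.
#' @param features Data frame: first column cell identifier, then numeric
#'   features.
#' @param groups Data frame with `barcode` and `group` columns.
#' @param min_cells Exclusion threshold: groups must have strictly more
#'   cells than this (default 1000).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return An object of class `grouped_correlation`: list with
#'   `by_feature` (tibble: `feature`, per-group mean/variance statistics),
#'   `by_group` (per-group correlations, long format) and `groups` (label,
#'   `n_cells`, `retained`).
#' @export
grouped_motif_ranking <- function(nta, features, groups, min_cells = 1000L,
                                  method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(all(c("barcode", "group") %in% names(groups)))
  id_col <- names(features)[1]
  merged <- dplyr::inner_join(
    dplyr::select(nta, "barcode", "nta"),
    features, by = stats::setNames(id_col, "barcode")
  ) |>
    dplyr::inner_join(dplyr::select(groups, "barcode", "group"), by = "barcode")
  sizes <- dplyr::count(merged, .data$group, name = "n_cells") |>
    dplyr::mutate(retained = .data$n_cells > min_cells)
  kept <- sizes$group[sizes$retained]
  if (length(kept) < 2L) {
    rlang::abort(sprintf(
      "need at least 2 groups with more than %d cells (filter min_cells = %d); %d retained",
      min_cells, min_cells, length(kept)
    ))
  }
  feat_names <- setdiff(names(merged), c("barcode", "nta", "group"))
  cor_fun <- if (method == "spearman") spearman_cor else
    function(x, y) stats::cor(x, y)
  by_group <- purrr::map_dfr(kept, function(g) {
    sub <- merged[merged$group == g, , drop = FALSE]
    rho <- vapply(feat_names, function(f) {
      v <- sub[[f]]
      ok <- !is.na(v) & !is.na(sub$nta)
      if (sum(ok) < 3L || stats::sd(v[ok]) == 0 || stats::sd(sub$nta[ok]) == 0) {
        return(NA_real_)
      }
      cor_fun(sub$nta[ok], v[ok])
    }, numeric(1))
    tibble::tibble(group = g, feature = feat_names, rho = unname(rho))
  })
  by_feature <- by_group |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(
      n_groups = sum(!is.na(.data$rho)),
      mean_rho = mean(.data$rho, na.rm = TRUE),
      var_rho = stats::var(.data$rho, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(mean_over_var = .data$mean_rho / .data$var_rho) |>
    dplyr::arrange(dplyr::desc(.data$mean_over_var))
  structure(
    list(by_feature = by_feature, by_group = by_group,
         groups = sizes, min_cells = min_cells, method = method),
    class = "grouped_correlation"
  )
}

#' @export
print.grouped_correlation <- function(x, ...) {
  cat(sprintf("<grouped_correlation> %d features x %d retained groups (of %d; min_cells > %d), %s\n",
              nrow(x$by_feature), sum(x$groups$retained), nrow(x$groups),
              x$min_cells, x$method))
  print(utils::head(x$by_feature, 5))
  invisible(x)
}

#' Write a feature-correlation table as TSV
#'
#' @param result Tibble from [correlate_features()] or the `by_feature`
#'   table of a [grouped_motif_ranking()].
#' @param path Output path.
#' @param sort_by Column to sort by before writing (default keeps order).
#' @return `path`, invisibly.
#' @export
write_correlation_table <- function(result, path, sort_by = NULL) {
  if (inherits(result, "grouped_correlation")) result <- result$by_feature
  if (!is.null(sort_by)) {
    result <- dplyr::arrange(result, dplyr::desc(.data[[sort_by]]))
  }
  utils::write.table(result, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
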