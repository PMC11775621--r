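#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the training trace of an origin model
#'
#' @param x A fitted `origin_model`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `train_mse`, `test_mse`.
#' @method tidy origin_model
#' @export
tidy.origin_model <- function(x, ...) {
  x$trace
}

#' One-row summary of a fitted origin model
#'
#' @param x A fitted `origin_model`.
#' @param ... Unused.
#' @return Tibble with architecture, data sizes and final train/test MSE.
#' @method glance origin_model
#' @export
glance.origin_model <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  tibble::tibble(
    n_parameters = sum(vapply(x$weights, length, integer(1))),
    kernel = x$kernel,
    filters = x$filters,
    epochs = x$epochs,
    n_train = x$n_train,
    n_test = x$n_test,
    train_mse = last$train_mse,
    test_mse = last$test_mse
  )
}

#' Tidy a grouped correlation result
#'
#' @param x A `grouped_correlation`.
#' @param ... Unused.
#' @return The per-feature tibble (`feature`, `n_groups`, `mean_rho`,
#'   `var_rho`, `mean_over_var`).
#' @method tidy grouped_correlation
#' @export
tidy.grouped_correlation <- function(x, ...) {
  x$by_feature
}

#' One-row summary of a grouped correlation result
#'
#' @param x A `grouped_correlation`.
#' @param ... Unused.
#' @return Tibble with feature/group counts and the cell filter used.
#' @method glance grouped_correlation
#' @export
glance.grouped_correlation <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$by_feature),
    n_groups_retained = sum(x$groups$retained),
    n_groups_total = nrow(x$groups),
    min_cells = x$min_cells,
    method = x$method
  )
}
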