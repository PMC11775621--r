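#' One-hot encode 50-bp sequences over the ATCGN alphabet
#'
#' @param sequences Character vector of sequences, each exactly `width`
#'   bases over `A`, `T`, `C`, `G`, `N`.
#' @param width Expected sequence length (default 50).
#' @return Numeric array of dimension `n x width x 5` (channel order
#'   `A, T, C, G, N`), exactly one unit per position.
#' @export
#' @examples
#' dim(encode_onehot(strrep("A", 50)))
encode_onehot <- function(sequences, width = 50L) {
  alphabet <- c("A", "T", "C", "G", "N")
  if (any(nchar(sequences) != width)) {
    rlang::abort(sprintf("all sequences must be exactly %d bases long", width))
  }
  if (any(grepl("[^ATCGN]", sequences))) {
    rlang::abort("sequences may contain only A/T/C/G/N")
  }
  n <- length(sequences)
  x <- array(0, dim = c(n, width, 5L),
             dimnames = list(NULL, NULL, alphabet))
  chars <- matrix(unlist(strsplit(sequences, "")), nrow = n, byrow = TRUE)
  ch_idx <- match(chars, alphabet)
  x[cbind(rep(seq_len(n), times = width),
          rep(seq_len(width), each = n),
          as.vector(ch_idx))] <- 1
  x
}

# im2col: (n, p, c) array -> (n * p_out, k * c) matrix of sliding windows,
# rows ordered position-major within each sample block.
im2col <- function(x, k) {
  n <- dim(x)[1]; p <- dim(x)[2]; c <- dim(x)[3]
  p_out <- p - k + 1L
  out <- matrix(0, nrow = n * p_out, ncol = k * c)
  for (j in seq_len(k)) {
    # channel-major layout: columns (j-1)*c + 1..c hold offset j
    slice <- x[, j:(j + p_out - 1L), , drop = FALSE]           # n x p_out x c
    out[, ((j - 1L) * c + 1L):(j * c)] <- matrix(aperm(slice, c(1, 2, 3)),
                                                 nrow = n * p_out)
  }
  out
}

# Scatter gradients from im2col layout back to the (n, p, c) input.
col2im <- function(g, n, p, c, k) {
  p_out <- p - k + 1L
  out <- array(0, dim = c(n, p_out, k, c))
  for (j in seq_len(k)) {
    out[, , j, ] <- array(g[, ((j - 1L) * c + 1L):(j * c)], dim = c(n, p_out, c))
  }
  dx <- array(0, dim = c(n, p, c))
  for (j in seq_len(k)) {
    dx[, j:(j + p_out - 1L), ] <- dx[, j:(j + p_out - 1L), , drop = FALSE] +
      out[, , j, ]
  }
  dx
}

new_origin_params <- function(width, channels, kernel, filters) {
  p1_out <- width - kernel + 1L
  p2_out <- p1_out - kernel + 1L
  # He initialisation for the rectified layers
  rn <- function(nr, nc, fan_in) {
    matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  }
  list(
    W1 = rn(kernel * channels, filters, kernel * channels),
    b1 = rep(0, filters),
    W2 = rn(kernel * filters, filters, kernel * filters),
    b2 = rep(0, filters),
    W3 = rn(p2_out * filters, 1L, p2_out * filters),
    b3 = 0
  )
}

origin_forward <- function(x, par, kernel, filters) {
  n <- dim(x)[1]; width <- dim(x)[2]; channels <- dim(x)[3]
  p1 <- width - kernel + 1L
  p2 <- p1 - kernel + 1L
  A1 <- im2col(x, kernel)                                     # (n*p1, k*c)
  Z1 <- sweep(A1 %*% par$W1, 2, par$b1, "+")
  H1 <- pmax(Z1, 0)
  H1a <- array(H1, dim = c(n, p1, filters))
  A2 <- im2col(H1a, kernel)                                   # (n*p2, k*f)
  Z2 <- sweep(A2 %*% par$W2, 2, par$b2, "+")
  H2 <- pmax(Z2, 0)
  Fm <- matrix(array(H2, dim = c(n, p2, filters)), nrow = n)  # (n, p2*f)
  yhat <- as.numeric(Fm %*% par$W3 + par$b3)
  list(yhat = yhat, A1 = A1, Z1 = Z1, A2 = A2, Z2 = Z2, Fm = Fm,
       n = n, p1 = p1, p2 = p2, width = width, channels = channels)
}

origin_backward <- function(fw, par, y, kernel, filters) {
  n <- fw$n
  dy <- 2 * (fw$yhat - y) / n                                 # d(MSE)/d(yhat)
  gW3 <- crossprod(fw$Fm, dy)
  gb3 <- sum(dy)
  dF <- matrix(dy, ncol = 1L) %*% t(par$W3)                   # (n, p2*f)
  dH2 <- matrix(array(dF, dim = c(n, fw$p2, filters)), nrow = n * fw$p2)
  dZ2 <- dH2 * (fw$Z2 > 0)
  gW2 <- crossprod(fw$A2, dZ2)
  gb2 <- colSums(dZ2)
  dA2 <- dZ2 %*% t(par$W2)
  dH1a <- col2im(dA2, n, fw$p1, filters, kernel)
  dZ1 <- matrix(dH1a, nrow = n * fw$p1) * (fw$Z1 > 0)
  gW1 <- crossprod(fw$A1, dZ1)
  gb1 <- colSums(dZ1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
}

#' Train the convolutional read-origin regressor
#'
#' A deliberately small convolutional network regressing `log10(1 + d)`
#' distance-from-telomere from a 50-bp one-hot (ATCGN) sequence: two
#' unpadded convolutional layers (kernel width 6, 20 filters each, ReLU)
#' and a dense layer to a single scalar; mean-squared-error loss. The
#' 6-wide kernels match the telomere hexamer; the parameter count is kept
#' small to limit overfitting. Optimised with Adam on mini-batches; fully
#' deterministic under `seed`.
#'
#' @param examples Tibble with `sequence` (fixed-width strings) and `label`
#'   columns, e.g. from [build_training_set()].
#' @param epochs Training epochs (default 200; ~100 usually suffices).
#' @param train_fraction Fraction of examples in the training split
#'   (default 0.8); the remainder is the held-out test set.
#' @param seed Integer seed controlling initialisation, the split and
#'   batch shuffling.
#' @param batch_size Mini-batch size (default 64).
#' @param learning_rate Adam step size (default 1e-3).
#' @param kernel,filters Architecture knobs (defaults 6 and 20).
#' @return An object of class `origin_model`: weights, the architecture and
#'   optimiser settings, and a per-epoch `trace` tibble with `train_mse`
#'   and `test_mse`.
#' @export
train_origin_model <- function(examples, epochs = 200L, train_fraction = 0.8,
                               seed = 1L, batch_size = 64L,
                               learning_rate = 1e-3,
                               kernel = 6L, filters = 20L) {
  stopifnot(all(c("sequence", "label") %in% names(examples)))
  withr::local_seed(seed)
  width <- nchar(examples$sequence[1])
  x <- encode_onehot(examples$sequence, width = width)
  y <- examples$label
  if (length(unique(y)) == 1L) {
    rlang::warn("all labels identical: the model will fit a constant")
  }
  n <- length(y)
  idx <- sample.int(n)
  n_train <- max(1L, floor(train_fraction * n))
  tr <- idx[seq_len(n_train)]
  te <- idx[-seq_len(n_train)]
  xtr <- x[tr, , , drop = FALSE]; ytr <- y[tr]
  xte <- x[te, , , drop = FALSE]; yte <- y[te]

  par <- new_origin_params(width, dim(x)[3], kernel, filters)
  m <- lapply(par, function(p) p * 0)
  v <- lapply(par, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  trace <- vector("list", epochs)
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n_train)
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    for (b in batches) {
      fw <- origin_forward(xtr[b, , , drop = FALSE], par, kernel, filters)
      gr <- origin_backward(fw, par, ytr[b], kernel, filters)
      t_step <- t_step + 1L
      for (k in names(par)) {
        m[[k]] <- beta1 * m[[k]] + (1 - beta1) * gr[[k]]
        v[[k]] <- beta2 * v[[k]] + (1 - beta2) * gr[[k]]^2
        mhat <- m[[k]] / (1 - beta1^t_step)
        vhat <- v[[k]] / (1 - beta2^t_step)
        par[[k]] <- par[[k]] - learning_rate * mhat / (sqrt(vhat) + eps)
      }
    }
    train_mse <- mean((origin_forward(xtr, par, kernel, filters)$yhat - ytr)^2)
    test_mse <- if (length(te) > 0L) {
      mean((origin_forward(xte, par, kernel, filters)$yhat - yte)^2)
    } else NA_real_
    trace[[epoch]] <- tibble::tibble(epoch = epoch, train_mse = train_mse,
                                     test_mse = test_mse)
  }
  structure(
    list(
      weights = par,
      width = width, kernel = kernel, filters = filters,
      optimizer = list(name = "adam", batch_size = batch_size,
                       learning_rate = learning_rate,
                       beta1 = beta1, beta2 = beta2, epsilon = eps),
      epochs = epochs, train_fraction = train_fraction, seed = seed,
      n_train = n_train, n_test = length(te),
      trace = dplyr::bind_rows(trace)
    ),
    class = "origin_model"
  )
}

#' @export
print.origin_model <- function(x, ...) {
  np <- sum(vapply(x$weights, length, integer(1)))
  cat(sprintf("<origin_model> conv(%d,%d)-ReLU-conv(%d,%d)-ReLU-dense | %d parameters\n",
              x$kernel, x$filters, x$kernel, x$filters, np))
  last <- x$trace[nrow(x$trace), ]
  cat(sprintf("  %d epochs; final train MSE %.4g, test MSE %.4g\n",
              x$epochs, last$train_mse, last$test_mse))
  invisible(x)
}

#' Predict log-distances for new sequences
#'
#' @param object A fitted `origin_model`.
#' @param newdata Character vector of sequences, or a data frame with a
#'   `sequence` column.
#' @param ... Unused.
#' @return Numeric vector of predicted `log10(1 + distance)` values.
#' @export
predict.origin_model <- function(object, newdata, ...) {
  seqs <- if (is.data.frame(newdata)) newdata$sequence else newdata
  x <- encode_onehot(seqs, width = object$width)
  origin_forward(x, object$weights, object$kernel, object$filters)$yhat
}

#' Binned class prediction from the origin model
#'
#' Maps scalar log-distance predictions to the nearest class pseudo-distance,
#' with boundaries at the midpoints between class label values on the log
#' scale. Telomere-proper predictions (distance 0) are merged with the
#' subtelomere into a single `"telomere+subtelomere"` class.
#'
#' @param model A fitted `origin_model`.
#' @param sequences Character vector of sequences (or data frame with a
#'   `sequence` column).
#' @param class_distances Named numeric vector of representative distances
#'   (bp) per class.
#' @return Factor with levels `telomere+subtelomere`, `chromatin`,
#'   `centromere`.
#' @export
predict_binned <- function(model, sequences,
                           class_distances = c(`telomere+subtelomere` = 0,
                                               chromatin = 1e7,
                                               centromere = 5e7)) {
  pred <- predict(model, sequences)
  lab <- log10(1 + sort(class_distances))
  classes <- names(sort(class_distances))
  cuts <- (lab[-1] + lab[-length(lab)]) / 2
  idx <- findInterval(pred, cuts) + 1L
  factor(classes[idx], levels = classes)
}

#' Save / load an origin model as a self-describing JSON file
#'
#' The file records the architecture, optimiser settings, seed and all
#' weights, so a saved model reloads bit-exactly and documents how it was
#' trained.
#'
#' @param model A fitted `origin_model`.
#' @param path File path.
#' @return `save_origin_model()` returns `path` invisibly;
#'   `load_origin_model()` returns the model.
#' @export
save_origin_model <- function(model, path) {
  payload <- list(
    format = "teloatac-origin-model-v1",
    width = model$width, kernel = model$kernel, filters = model$filters,
    optimizer = model$optimizer, epochs = model$epochs,
    train_fraction = model$train_fraction, seed = model$seed,
    n_train = model$n_train, n_test = model$n_test,
    weights = lapply(model$weights, function(w) {
      if (is.matrix(w)) list(dim = dim(w), data = as.numeric(w))
      else list(dim = length(w), data = as.numeric(w))
    }),
    trace = as.list(model$trace)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_origin_model
#' @export
load_origin_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "teloatac-origin-model-v1")) {
    rlang::abort("not a teloatac origin-model file")
  }
  weights <- lapply(p$weights, function(w) {
    if (length(w$dim) == 2L) matrix(w$data, w$dim[1], w$dim[2])
    else if (w$dim == 1L) as.numeric(w$data) else as.numeric(w$data)
  })
  structure(
    list(weights = weights, width = p$width, kernel = p$kernel,
         filters = p$filters, optimizer = as.list(p$optimizer),
         epochs = p$epochs, train_fraction = p$train_fraction, seed = p$seed,
         n_train = p$n_train, n_test = p$n_test,
         trace = tibble::as_tibble(p$trace)),
    class = "origin_model"
  )
}
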