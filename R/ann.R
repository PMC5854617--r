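#' Training configuration for a three-layer network
#'
#' @param n_hidden number of hidden neurons (the architecture sweep explores
#'   1 to 15).
#' @param loss `"cross-entropy"` (default; the likelihood loss for binary
#'   targets with a logistic output) or `"squared-error"`.
#' @param weight_decay ridge penalty coefficient on the sum of squared
#'   weights (default 0).
#' @param max_iterations optimizer iteration budget (default 2000).
#' @param tolerance relative convergence tolerance (default 1e-8).
#' @param init_range weights are initialized uniformly on
#'   \[-init_range, init_range\] (default 0.5).
#' @param restarts number of seeded re-initializations; the best final loss
#'   wins (default 5).
#' @param seed integer master seed for initialization.
#' @return An object of class `train_config`.
#' @export
train_config <- function(n_hidden = 5,
                         loss = c("cross-entropy", "squared-error"),
                         weight_decay = 0,
                         max_iterations = 2000,
                         tolerance = 1e-8,
                         init_range = 0.5,
                         restarts = 5,
                         seed = 1) {
  loss <- match.arg(loss)
  stopifnot(n_hidden >= 1, weight_decay >= 0, max_iterations >= 1,
            tolerance > 0, init_range >= 0, restarts >= 1)
  structure(list(n_hidden = as.integer(n_hidden), loss = loss,
                 weight_decay = weight_decay,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, init_range = init_range,
                 restarts = as.integer(restarts), seed = as.integer(seed)),
            class = "train_config")
}

#' Initialize network weights
#'
#' Weights of a three-layer feed-forward network with bias: an
#' `(n_inputs + 1) x n_hidden` input-to-hidden table (last row the hidden
#' biases) and an `(n_hidden + 1)`-vector of hidden-to-output weights (last
#' entry the output bias), drawn uniformly from
#' \[-init_range, init_range\].
#'
#' @param n_inputs,n_hidden layer sizes (both at least 1).
#' @param init_range uniform initialization half-width.
#' @param seed integer seed; identical seeds give identical weights.
#' @return An object of class `network_weights`.
#' @export
init_network <- function(n_inputs, n_hidden, init_range = 0.5, seed = 1) {
  if (n_inputs < 1 || n_hidden < 1) {
    stop("n_inputs and n_hidden must be at least 1", call. = FALSE)
  }
  with_seed(seed, {
    w1 <- matrix(stats::runif((n_inputs + 1) * n_hidden,
                              -init_range, init_range),
                 nrow = n_inputs + 1, ncol = n_hidden)
    w2 <- stats::runif(n_hidden + 1, -init_range, init_range)
    network_weights(w1, w2)
  })
}

network_weights <- function(input_to_hidden, hidden_to_output) {
  n_hidden <- ncol(input_to_hidden)
  n_inputs <- nrow(input_to_hidden) - 1L
  stopifnot(length(hidden_to_output) == n_hidden + 1L,
            all(is.finite(input_to_hidden)),
            all(is.finite(hidden_to_output)))
  structure(list(n_inputs = n_inputs, n_hidden = n_hidden,
                 input_to_hidden = input_to_hidden,
                 hidden_to_output = as.numeric(hidden_to_output)),
            class = "network_weights")
}

#' @export
print.network_weights <- function(x, ...) {
  cat("network_weights:", x$n_inputs, "inputs ->", x$n_hidden,
      "hidden (sigmoid) -> 1 output (sigmoid), with biases\n")
  invisible(x)
}

nw_flatten <- function(w) c(as.numeric(w$input_to_hidden), w$hidden_to_output)

nw_unflatten <- function(par, n_inputs, n_hidden) {
  k <- (n_inputs + 1L) * n_hidden
  network_weights(matrix(par[seq_len(k)], n_inputs + 1L, n_hidden),
                  par[(k + 1L):(k + n_hidden + 1L)])
}

#' Forward pass through the network
#'
#' Computes `sigmoid(w2 . [sigmoid(W1' . [x, 1]), 1])`, the occurrence
#' probability for each input row.
#'
#' @param weights a `network_weights` object.
#' @param x input vector (length `n_inputs`) or matrix with `n_inputs`
#'   columns; entries must be finite.
#' @return Numeric vector of probabilities, strictly inside (0, 1).
#' @export
nn_forward <- function(weights, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != weights$n_inputs) {
    stop("input has ", ncol(x), " columns; network expects ",
         weights$n_inputs, call. = FALSE)
  }
  if (!all(is.finite(x))) stop("non-finite input value", call. = FALSE)
  h <- stats::plogis(cbind(x, 1) %*% weights$input_to_hidden)
  as.numeric(stats::plogis(cbind(h, 1) %*% weights$hidden_to_output))
}

# Penalized loss and its analytic gradient for optim(). `x1` carries the
# appended bias column.
nn_loss <- function(par, x1, y, n_inputs, n_hidden, loss, decay) {
  k <- (n_inputs + 1L) * n_hidden
  w1 <- matrix(par[seq_len(k)], n_inputs + 1L, n_hidden)
  w2 <- par[(k + 1L):(k + n_hidden + 1L)]
  h <- stats::plogis(x1 %*% w1)
  p <- as.numeric(stats::plogis(cbind(h, 1) %*% w2))
  n <- length(y)
  eps <- 1e-12
  fit <- if (loss == "cross-entropy") {
    pc <- pmin(pmax(p, eps), 1 - eps)
    -mean(y * log(pc) + (1 - y) * log(1 - pc))
  } else {
    mean((p - y)^2)
  }
  fit + decay * sum(par^2)
}

nn_grad <- function(par, x1, y, n_inputs, n_hidden, loss, decay) {
  k <- (n_inputs + 1L) * n_hidden
  w1 <- matrix(par[seq_len(k)], n_inputs + 1L, n_hidden)
  w2 <- par[(k + 1L):(k + n_hidden + 1L)]
  h <- stats::plogis(x1 %*% w1)
  h1 <- cbind(h, 1)
  p <- as.numeric(stats::plogis(h1 %*% w2))
  n <- length(y)
  dz2 <- if (loss == "cross-entropy") {
    (p - y) / n
  } else {
    2 * (p - y) * p * (1 - p) / n
  }
  g2 <- as.numeric(crossprod(h1, dz2))
  dh <- tcrossprod(dz2, w2[seq_len(n_hidden)])
  dz1 <- dh * h * (1 - h)
  g1 <- crossprod(x1, dz1)
  c(as.numeric(g1), g2) + 2 * decay * par
}

#' Train a network on binary occurrence data
#'
#' Full-batch quasi-Newton (BFGS) minimization of the configured loss plus
#' the weight-decay penalty, repeated over `restarts` seeded uniform
#' initializations; the restart with the best final penalized loss is
#' returned. Training is deterministic given the configuration seed.
#'
#' @param x sites-by-inputs numeric matrix (normalized inputs).
#' @param y binary target vector; both classes must be present.
#' @param config a [train_config()].
#' @return The best `network_weights`, with attributes `loss` (final
#'   penalized loss) and `restart` (which restart won).
#' @export
train_network <- function(x, y, config = train_config()) {
  x <- as.matrix(x)
  if (nrow(x) != length(y)) {
    stop("x rows (", nrow(x), ") must match y length (", length(y), ")",
         call. = FALSE)
  }
  if (!is_binary_vector(y)) stop("y must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("degenerate target: y contains a single class", call. = FALSE)
  }
  n_inputs <- ncol(x)
  n_hidden <- config$n_hidden
  x1 <- cbind(x, 1)
  best <- NULL
  best_val <- Inf
  best_restart <- NA_integer_
  for (r in seq_len(config$restarts)) {
    w0 <- init_network(n_inputs, n_hidden, config$init_range,
                       seed = derive_seed(config$seed, r))
    fit <- stats::optim(nw_flatten(w0), fn = nn_loss, gr = nn_grad,
                        x1 = x1, y = y, n_inputs = n_inputs,
                        n_hidden = n_hidden, loss = config$loss,
                        decay = config$weight_decay,
                        method = "BFGS",
                        control = list(maxit = config$max_iterations,
                                       reltol = config$tolerance))
    if (fit$value < best_val) {
      best_val <- fit$value
      best <- fit$par
      best_restart <- r
    }
  }
  out <- nw_unflatten(best, n_inputs, n_hidden)
  attr(out, "loss") <- best_val
  attr(out, "restart") <- best_restart
  out
}

#' Sweep hidden-layer sizes by cross-validated kappa
#'
#' Each candidate hidden size is scored by the median kappa of a stratified
#' k-fold cross-validation of an environment-plus-extras network for the
#' target species; the size with the highest median kappa wins, ties broken
#' toward fewer hidden neurons.
#'
#' @param data a normalized [survey_dataset()].
#' @param target target species name.
#' @param sizes candidate hidden sizes (default `1:15`).
#' @param config base [train_config()]; its `n_hidden` is overridden.
#' @param extra_inputs species whose observed occurrence joins the inputs.
#' @param folds number of CV folds (default 5).
#' @param seed integer seed for fold assignment and training.
#' @param cutoff_mode see [cross_validate()].
#' @return A list with `best_config` (a [train_config()] at the winning
#'   size) and `table` (data frame `n_hidden`, `median_kappa`).
#' @export
sweep_hidden_sizes <- function(data, target, sizes = 1:15,
                               config = train_config(),
                               extra_inputs = character(0),
                               folds = 5, seed = 1,
                               cutoff_mode = c("test", "train")) {
  cutoff_mode <- match.arg(cutoff_mode)
  stopifnot(length(sizes) >= 1, all(sizes >= 1))
  meds <- vapply(sizes, function(s) {
    cfg <- config
    cfg$n_hidden <- as.integer(s)
    cv <- cross_validate(data, target,
                         factory = species_net_factory(cfg, extra_inputs),
                         k = folds, seed = seed, cutoff_mode = cutoff_mode)
    cv$median_k
  }, numeric(1))
  best_size <- sizes[order(-meds, sizes)][1]
  best <- config
  best$n_hidden <- as.integer(best_size)
  list(best_config = best,
       table = data.frame(n_hidden = as.integer(sizes), median_kappa = meds))
}
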