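#' Autoencoder configuration
#'
#' The network compresses each drug's binary feature row to a dense
#' `code_dim`-dimensional code.  The encoder is a stack of "building layers"
#' (fully connected + dropout, ReLU activation); the last building layer is
#' the encoding layer.  The decoder mirrors the encoder with the layer sizes
#' reversed, ending in a sigmoid output layer because the inputs are binary.
#' Training minimizes mean squared reconstruction error with Adagrad;
#' parameters are Xavier-initialized.
#'
#' Reference-scale defaults follow the published setup: hidden widths
#' 1024/640, a 400-unit code, dropout 0.5, batch size 16, Adagrad learning
#' rate 0.01.  The stopping rule (early stopping on training loss) is this
#' package's choice; the original work states no epoch budget.
#'
#' @param input_dim number of binary feature columns
#' @param hidden_dims widths of the building layers between input and code
#'   (may be empty)
#' @param code_dim width of the encoding layer; must be `< input_dim`
#' @param dropout_rate dropout probability on every building layer including
#'   the code layer, active only during training
#' @param batch_size minibatch size
#' @param learning_rate Adagrad learning rate
#' @param max_epochs,patience early-stopping budget: training stops at
#'   `max_epochs` or after `patience` epochs without loss improvement
#' @param seed integer; fixes initialization, shuffling and dropout masks
#' @return a list of class `encoder_config`
#' @export
encoder_config <- function(input_dim, hidden_dims = c(1024L, 640L),
                           code_dim = 400L, dropout_rate = 0.5,
                           batch_size = 16L, learning_rate = 0.01,
                           max_epochs = 200L, patience = 20L, seed = 1L) {
  cfg <- list(input_dim = as.integer(input_dim),
              hidden_dims = as.integer(hidden_dims),
              code_dim = as.integer(code_dim), dropout_rate = dropout_rate,
              batch_size = as.integer(batch_size),
              learning_rate = learning_rate,
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience), seed = as.integer(seed))
  if (cfg$code_dim >= cfg$input_dim)
    stop("code_dim must be smaller than input_dim", call. = FALSE)
  if (any(c(cfg$input_dim, cfg$hidden_dims, cfg$code_dim, cfg$batch_size,
            cfg$max_epochs, cfg$patience) < 1))
    stop("all dimensions and counts must be positive", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be positive", call. = FALSE)
  structure(cfg, class = "encoder_config")
}

xavier_init <- function(fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -limit, limit), fan_in, fan_out)
}

#' Build an (untrained) autoencoder
#'
#' Constructs the mirrored layer stack
#' `input -> hidden_dims... -> code_dim -> rev(hidden_dims)... -> input`
#' with Xavier-initialized weights.  All layers use ReLU and carry dropout
#' except the final output layer, which uses sigmoid and no dropout.
#'
#' @param config an [encoder_config()]
#' @return a list of class `autoencoder` with elements `layers` (each a list
#'   `W`, `b`, `activation`, `dropout`), `n_encoder_layers`, `config`, and an
#'   empty `loss_history`
#' @export
build_autoencoder <- function(config) {
  stopifnot(inherits(config, "encoder_config"))
  dims <- c(config$input_dim, config$hidden_dims, config$code_dim,
            rev(config$hidden_dims), config$input_dim)
  n_layers <- length(dims) - 1L
  with_rng(config$seed, {
    layers <- vector("list", n_layers)
    for (l in seq_len(n_layers)) {
      layers[[l]] <- list(
        W = xavier_init(dims[l], dims[l + 1L]),
        b = numeric(dims[l + 1L]),
        activation = if (l == n_layers) "sigmoid" else "relu",
        dropout = l < n_layers)
    }
    structure(list(layers = layers,
                   n_encoder_layers = length(config$hidden_dims) + 1L,
                   config = config, loss_history = numeric(0)),
              class = "autoencoder")
  })
}

activate <- function(z, kind) {
  switch(kind, relu = pmax(z, 0), sigmoid = 1 / (1 + exp(-z)))
}

# Forward pass without dropout; returns final activation.
ae_forward <- function(model, x, upto = length(model$layers)) {
  a <- x
  for (l in seq_len(upto)) {
    lay <- model$layers[[l]]
    a <- activate(sweep(a %*% lay$W, 2, lay$b, `+`), lay$activation)
  }
  a
}

#' Reconstruct inputs through the full autoencoder
#'
#' @param model an [build_autoencoder()] model (trained or not)
#' @param features drug x feature matrix with `ncol == input_dim`
#' @return matrix of reconstructed values in (0, 1)
#' @export
reconstruct <- function(model, features) {
  stopifnot(inherits(model, "autoencoder"))
  if (ncol(features) != model$config$input_dim)
    stop("feature dimension mismatch: got ", ncol(features), ", expected ",
         model$config$input_dim, call. = FALSE)
  ae_forward(model, features)
}

#' Mean squared reconstruction error
#'
#' @inheritParams reconstruct
#' @return mean over all cells of the squared reconstruction residual
#' @export
reconstruction_mse <- function(model, features) {
  mean((reconstruct(model, features) - features)^2)
}

#' Train the autoencoder
#'
#' Minibatch Adagrad on the mean squared reconstruction error, with inverted
#' dropout on every building layer (training only) and early stopping on the
#' per-epoch mean training loss.  Deterministic given `config$seed`.
#'
#' @param model an untrained [build_autoencoder()] model
#' @param features binary drug x feature matrix; a warning is raised if
#'   values outside \{0, 1\} are present (the sigmoid output assumes binary
#'   targets); `nrow` must be at least the batch size
#' @return the model with trained `layers` and a non-empty `loss_history`
#'   (one mean MSE per epoch), class `c("trained_encoder", "autoencoder")`
#' @export
fit_autoencoder <- function(model, features) {
  stopifnot(inherits(model, "autoencoder"))
  cfg <- model$config
  x <- as.matrix(features)
  if (ncol(x) != cfg$input_dim)
    stop("feature dimension mismatch: got ", ncol(x), ", expected ",
         cfg$input_dim, call. = FALSE)
  if (!all(x %in% c(0, 1)))
    warning("features are not binary; sigmoid reconstruction assumes 0/1 targets",
            call. = FALSE)
  if (nrow(x) < cfg$batch_size)
    stop("need at least batch_size (", cfg$batch_size, ") rows, got ",
         nrow(x), call. = FALSE)

  layers <- model$layers
  n_layers <- length(layers)
  grad_acc <- lapply(layers, function(l)
    list(W = matrix(0, nrow(l$W), ncol(l$W)), b = numeric(length(l$b))))
  keep <- 1 - cfg$dropout_rate

  with_rng(cfg$seed, {
    history <- numeric(0)
    best <- Inf
    stall <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      idx <- sample.int(nrow(x))
      batch_starts <- seq(1L, nrow(x), by = cfg$batch_size)
      epoch_loss <- 0
      for (s in batch_starts) {
        rows <- idx[s:min(s + cfg$batch_size - 1L, nrow(x))]
        xb <- x[rows, , drop = FALSE]

        # forward with dropout masks
        a <- vector("list", n_layers + 1L)
        z <- vector("list", n_layers)
        masks <- vector("list", n_layers)
        a[[1L]] <- xb
        for (l in seq_len(n_layers)) {
          lay <- layers[[l]]
          z[[l]] <- sweep(a[[l]] %*% lay$W, 2, lay$b, `+`)
          h <- activate(z[[l]], lay$activation)
          if (lay$dropout && cfg$dropout_rate > 0) {
            m <- matrix(stats::runif(length(h)) >= cfg$dropout_rate,
                        nrow(h), ncol(h))
            h <- h * m / keep
            masks[[l]] <- m
          }
          a[[l + 1L]] <- h
        }
        out <- a[[n_layers + 1L]]
        loss <- mean((out - xb)^2)
        if (!is.finite(loss))
          stop("training loss is not finite at epoch ", epoch, call. = FALSE)
        epoch_loss <- epoch_loss + loss * nrow(xb)

        # backward
        delta <- 2 * (out - xb) / length(xb)     # dL/d(a_L)
        for (l in rev(seq_len(n_layers))) {
          lay <- layers[[l]]
          if (lay$dropout && cfg$dropout_rate > 0)
            delta <- delta * masks[[l]] / keep
          dz <- if (lay$activation == "sigmoid") {
            sig <- activate(z[[l]], "sigmoid")
            delta * sig * (1 - sig)
          } else {
            delta * (z[[l]] > 0)
          }
          gW <- crossprod(a[[l]], dz)
          gb <- colSums(dz)
          if (l > 1L) delta <- dz %*% t(lay$W)

          # Adagrad update
          grad_acc[[l]]$W <- grad_acc[[l]]$W + gW^2
          grad_acc[[l]]$b <- grad_acc[[l]]$b + gb^2
          layers[[l]]$W <- lay$W -
            cfg$learning_rate * gW / (sqrt(grad_acc[[l]]$W) + 1e-8)
          layers[[l]]$b <- lay$b -
            cfg$learning_rate * gb / (sqrt(grad_acc[[l]]$b) + 1e-8)
        }
      }
      epoch_loss <- epoch_loss / nrow(x)
      history <- c(history, epoch_loss)
      if (epoch_loss < best - 1e-8) {
        best <- epoch_loss
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    }
    model$layers <- layers
    model$loss_history <- history
    class(model) <- c("trained_encoder", "autoencoder")
    model
  })
}

#' Encode drug features to the low-dimensional code
#'
#' Runs the encoder half of the network (through the encoding layer) without
#' dropout.  Codes are non-negative (ReLU) and deterministic: identical input
#' rows map to identical code rows.
#'
#' @param model a (preferably trained) autoencoder
#' @param features drug x feature matrix; row labels are carried over
#' @return a drugs x `code_dim` real matrix of encoding-layer activations
#' @export
encode <- function(model, features) {
  stopifnot(inherits(model, "autoencoder"))
  x <- as.matrix(features)
  if (ncol(x) != model$config$input_dim)
    stop("feature dimension mismatch: got ", ncol(x), ", expected ",
         model$config$input_dim, call. = FALSE)
  code <- ae_forward(model, x, upto = model$n_encoder_layers)
  rownames(code) <- rownames(features)
  colnames(code) <- sprintf("code%0*d", nchar(ncol(code)), seq_len(ncol(code)))
  code
}
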