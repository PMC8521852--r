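# Minimal fully-connected network for the classifier ensemble: dense layers
# with ReLU activations, softmax cross-entropy loss, Adam updates. Written in
# plain matrix algebra; the problem (18 inputs, a few thousand rows) needs
# nothing heavier.

mlp_init <- function(n_in, hidden, n_out) {
  dims <- c(n_in, hidden, n_out)
  layers <- vector("list", length(dims) - 1)
  for (l in seq_along(layers)) {
    fan_in <- dims[l]
    layers[[l]] <- list(
      W = matrix(rnorm(fan_in * dims[l + 1], 0, sqrt(2 / fan_in)),
                 fan_in, dims[l + 1]),
      b = rep(0, dims[l + 1])
    )
  }
  layers
}

mlp_forward <- function(layers, x) {
  acts <- list(x)
  n_layers <- length(layers)
  for (l in seq_len(n_layers)) {
    z <- acts[[l]] %*% layers[[l]]$W +
      matrix(layers[[l]]$b, nrow(x), ncol(layers[[l]]$W), byrow = TRUE)
    acts[[l + 1]] <- if (l < n_layers) pmax(z, 0) else z
  }
  acts
}

softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Train a small feedforward classification network
#'
#' Architecture: input - 128 - 64 - 32 - (number of classes), ReLU hidden
#' activations, softmax output, cross-entropy loss, Adam optimizer,
#' mini-batches of 32, 25 epochs. Deterministic given `seed`.
#'
#' @param x Numeric feature matrix (callers should standardize).
#' @param y Factor of class labels.
#' @param hidden Hidden layer widths.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param lr Adam learning rate.
#' @param seed Integer seed for initialization and shuffling.
#' @return An `mlp_model` usable with [mlp_predict()].
#' @export
mlp_train <- function(x, y, hidden = c(128, 64, 32), epochs = 25L,
                      batch_size = 32L, lr = 1e-3, seed = 1L) {
  stopifnot(is.factor(y), nrow(x) == length(y))
  set.seed(seed)
  n <- nrow(x)
  k <- nlevels(y)
  yid <- as.integer(y)
  onehot <- matrix(0, n, k)
  onehot[cbind(seq_len(n), yid)] <- 1
  layers <- mlp_init(ncol(x), hidden, k)
  mom <- lapply(layers, function(l) {
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      xb <- x[idx, , drop = FALSE]
      yb <- onehot[idx, , drop = FALSE]
      acts <- mlp_forward(layers, xb)
      probs <- softmax(acts[[length(acts)]])
      delta <- (probs - yb) / length(idx)
      step <- step + 1
      for (l in rev(seq_along(layers))) {
        gW <- t(acts[[l]]) %*% delta
        gb <- colSums(delta)
        if (l > 1) {
          delta <- (delta %*% t(layers[[l]]$W)) * (acts[[l]] > 0)
        }
        mom[[l]]$mW <- b1 * mom[[l]]$mW + (1 - b1) * gW
        mom[[l]]$vW <- b2 * mom[[l]]$vW + (1 - b2) * gW^2
        mom[[l]]$mb <- b1 * mom[[l]]$mb + (1 - b1) * gb
        mom[[l]]$vb <- b2 * mom[[l]]$vb + (1 - b2) * gb^2
        mhW <- mom[[l]]$mW / (1 - b1^step)
        vhW <- mom[[l]]$vW / (1 - b2^step)
        mhb <- mom[[l]]$mb / (1 - b1^step)
        vhb <- mom[[l]]$vb / (1 - b2^step)
        layers[[l]]$W <- layers[[l]]$W - lr * mhW / (sqrt(vhW) + eps)
        layers[[l]]$b <- layers[[l]]$b - lr * mhb / (sqrt(vhb) + eps)
      }
    }
  }
  structure(list(layers = layers, levels = levels(y)), class = "mlp_model")
}

#' Class probabilities from a trained network
#'
#' @param model An `mlp_model`.
#' @param x Feature matrix on the same scale as training.
#' @return Probability matrix, columns named by class.
#' @export
mlp_predict <- function(model, x) {
  acts <- mlp_forward(model$layers, x)
  p <- softmax(acts[[length(acts)]])
  colnames(p) <- model$levels
  p
}
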