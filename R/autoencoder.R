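#' Fit the embedding autoencoder
#'
#' Compresses the classifier's 256-dimensional identity embeddings to
#' 64-dimensional codes with a single-hidden-layer autoencoder
#' (256 -> 64 -> 256, linear code and output) trained with Adam on mean
#' squared reconstruction error. Inputs are scaled by their largest
#' absolute training value; the factor is stored and reapplied.
#'
#' @param x numeric matrix n x 256 of embeddings.
#' @param code_dim code width (fixed at 64).
#' @param learning_rate,epochs,batch_size Adam step size and schedule.
#' @param seed integer seed (initialization and shuffling).
#' @return object of class \code{gait_ae}: weights, input scale, per-epoch
#'   reconstruction-loss \code{trace}, configuration.
#' @seealso \code{\link{encode}}, \code{\link{predict.gait_ae}}
#' @export
gait_ae <- function(x, code_dim = 64, learning_rate = 0.001, epochs = 30,
                    batch_size = 16, seed = 1) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == 256, code_dim == 64, epochs >= 0, batch_size >= 1)
  n <- nrow(x)
  scale <- max(abs(x))
  if (scale <= 0) scale <- 1
  X <- x / scale

  with_local_seed(derive_seed(seed, 23L), {
    W1 <- matrix(rnorm(256 * code_dim, 0, sqrt(1 / 256)), 256, code_dim)
    b1 <- rep(0, code_dim)
    W2 <- matrix(rnorm(code_dim * 256, 0, sqrt(1 / code_dim)), code_dim, 256)
    b2 <- rep(0, 256)

    adam <- lapply(list(W1, b1, W2, b2),
                   function(p) list(m = p * 0, v = p * 0))
    t_step <- 0
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- function(p, g, s) {
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g^2
      mh <- s$m / (1 - beta1^t_step)
      vh <- s$v / (1 - beta2^t_step)
      list(p = p - learning_rate * mh / (sqrt(vh) + eps), s = s)
    }

    trace <- numeric(0)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = batch_size)) {
        ix <- ord[start:min(start + batch_size - 1, n)]
        Xb <- X[ix, , drop = FALSE]
        H <- sweep(Xb %*% W1, 2, b1, "+")
        R <- sweep(H %*% W2, 2, b2, "+")
        E <- R - Xb
        dR <- 2 * E / length(E)
        gW2 <- crossprod(H, dR); gb2 <- colSums(dR)
        dH <- dR %*% t(W2)
        gW1 <- crossprod(Xb, dH); gb1 <- colSums(dH)
        t_step <- t_step + 1
        u <- step(W1, gW1, adam[[1]]); W1 <- u$p; adam[[1]] <- u$s
        u <- step(b1, gb1, adam[[2]]); b1 <- u$p; adam[[2]] <- u$s
        u <- step(W2, gW2, adam[[3]]); W2 <- u$p; adam[[3]] <- u$s
        u <- step(b2, gb2, adam[[4]]); b2 <- u$p; adam[[4]] <- u$s
      }
      H <- sweep(X %*% W1, 2, b1, "+")
      R <- sweep(H %*% W2, 2, b2, "+")
      trace <- c(trace, mean((R - X)^2))
    }

    structure(list(
      W1 = W1, b1 = b1, W2 = W2, b2 = b2, scale = scale,
      trace = data.frame(epoch = seq_len(epochs),
                         reconstruction_loss = trace),
      config = list(code_dim = code_dim, learning_rate = learning_rate,
                    epochs = epochs, batch_size = batch_size, seed = seed)),
      class = "gait_ae")
  })
}

#' Encode embeddings to 64-dimensional feature vectors
#'
#' @param object a fitted \code{gait_ae}.
#' @param x matrix n x 256.
#' @param ... unused.
#' @return matrix n x 64.
#' @export
encode <- function(object, x, ...) UseMethod("encode")

#' @rdname encode
#' @export
encode.gait_ae <- function(object, x, ...) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == 256)
  sweep((x / object$scale) %*% object$W1, 2, object$b1, "+")
}

#' Reconstruct embeddings from a fitted autoencoder
#' @param object a \code{gait_ae}.
#' @param x matrix n x 256.
#' @param ... unused.
#' @return matrix n x 256 (original embedding scale).
#' @export
predict.gait_ae <- function(object, x, ...) {
  H <- encode(object, x)
  sweep(H %*% object$W2, 2, object$b2, "+") * object$scale
}

#' @export
residuals.gait_ae <- function(object, x, ...) {
  as.matrix(x) - predict(object, x)
}

#' @export
print.gait_ae <- function(x, ...) {
  cat(sprintf("Embedding autoencoder: 256 -> %d -> 256, %d epoch(s)\n",
              x$config$code_dim, nrow(x$trace)))
  if (nrow(x$trace) > 0)
    cat(sprintf("  final reconstruction MSE %.3g\n",
                x$trace$reconstruction_loss[nrow(x$trace)]))
  invisible(x)
}

#' @export
plot.gait_ae <- function(x, ...) {
  tr <- x$trace
  if (nrow(tr) == 0) {
    warning("no training trace to plot")
    return(invisible(x))
  }
  plot(tr$epoch, tr$reconstruction_loss, type = "l", xlab = "epoch",
       ylab = "MSE", main = "Reconstruction loss", ...)
  invisible(x)
}
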