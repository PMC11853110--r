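#' Fit the convolutional gait classifier
#'
#' Trains a small convolutional network on 32 x 32 average bilateral
#' pressure maps: three 3 x 3 convolution + 2 x 2 max-pooling blocks
#' (filter progression 32-64-128 by default, rectified-linear activations),
#' a 256-unit fully connected layer, and a softmax output over the cohort's
#' identities, optimized with Adam on cross-entropy. The 256-unit
#' penultimate activations serve as identity embeddings for the open-set
#' stage (\code{\link{extract_embeddings}}).
#'
#' Inputs are scaled by the global training-set maximum into [0, 1]; the
#' factor is stored and reapplied at prediction time. A fraction
#' \code{validation_split} of the training maps (stratified over
#' \code{strata}, by default the labels) is held out for per-epoch
#' validation metrics.
#'
#' @param x maps: a list of \code{pressure_map} or an array n x 32 x 32.
#' @param y subject labels, one per map.
#' @param n_classes optional expected class count; a mismatch with the
#'   labels present in \code{y} is an error.
#' @param conv_filters filters per conv block (length 3).
#' @param fc_hidden width of the penultimate layer (fixed at 256).
#' @param learning_rate,epochs,batch_size,validation_split Adam step size
#'   and training schedule.
#' @param strata stratification variable for the validation split.
#' @param seed integer seed controlling initialization, the split and
#'   shuffling; fixed seed and data give bit-identical models.
#' @return object of class \code{gait_cnn}: weights, class dictionary,
#'   input scale, per-epoch \code{trace} (train/validation loss and
#'   accuracy) and the configuration.
#' @seealso \code{\link{predict.gait_cnn}}, \code{\link{gait_ae}}
#' @export
gait_cnn <- function(x, y, n_classes = NULL,
                     conv_filters = c(32, 64, 128), fc_hidden = 256,
                     learning_rate = 0.001, epochs = 50, batch_size = 16,
                     validation_split = 0.1, strata = NULL, seed = 1) {
  if (is.list(x)) x <- maps_to_array(x)
  stopifnot(length(dim(x)) == 3, dim(x)[2] == 32, dim(x)[3] == 32,
            length(y) == dim(x)[1], length(conv_filters) == 3,
            fc_hidden == 256, epochs >= 0, batch_size >= 1,
            validation_split >= 0, validation_split < 1)
  classes <- sort(unique(y))
  if (!is.null(n_classes) && n_classes != length(classes))
    stop("class count mismatch: labels contain ", length(classes),
         " classes, expected ", n_classes)
  yi <- match(y, classes) - 1L
  x_max <- max(x)
  if (x_max <= 0) x_max <- 1
  X <- matrix(x / x_max, nrow = dim(x)[1])  # rows = col-major flattened maps

  if (is.null(strata)) strata <- y
  val_idx <- integer(0)
  if (validation_split > 0 && epochs > 0) {
    val_idx <- with_local_seed(derive_seed(seed, 17L), {
      unlist(lapply(split(seq_along(y), strata), function(ix) {
        k <- floor(validation_split * length(ix))
        if (k > 0) sample(ix, k) else integer(0)
      }), use.names = FALSE)
    })
  }
  tr_idx <- setdiff(seq_along(y), val_idx)

  if (epochs == 0) {
    weights <- cnn_init_cpp(as.integer(conv_filters),
                            length(classes), as.integer(seed))
    trace <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        train_accuracy = numeric(0), val_loss = numeric(0),
                        val_accuracy = numeric(0))
  } else {
    fit <- cnn_train_cpp(X[tr_idx, , drop = FALSE], yi[tr_idx],
                         X[val_idx, , drop = FALSE], yi[val_idx],
                         as.integer(conv_filters), length(classes),
                         as.integer(epochs), as.integer(batch_size),
                         learning_rate, as.integer(seed))
    weights <- fit$weights
    trace <- fit$trace
  }
  structure(list(
    weights = weights, classes = classes, x_max = x_max, trace = trace,
    config = list(conv_filters = conv_filters, fc_hidden = fc_hidden,
                  learning_rate = learning_rate, epochs = epochs,
                  batch_size = batch_size,
                  validation_split = validation_split, seed = seed),
    n_train = length(tr_idx), n_val = length(val_idx)),
    class = "gait_cnn")
}

prep_x <- function(object, x) {
  if (is.list(x) && !is.matrix(x)) x <- maps_to_array(x)
  if (length(dim(x)) == 3) x <- matrix(x, nrow = dim(x)[1])
  stopifnot(ncol(x) == 1024)
  x / object$x_max
}

#' Predict from a fitted gait classifier
#'
#' @param object a \code{gait_cnn}.
#' @param x maps (list or n x 32 x 32 array).
#' @param type \code{"class"} (predicted labels), \code{"prob"}
#'   (n x K softmax scores), or \code{"embedding"} (n x 256 penultimate
#'   activations).
#' @param ... unused.
#' @export
predict.gait_cnn <- function(object, x,
                             type = c("class", "prob", "embedding"), ...) {
  type <- match.arg(type)
  X <- prep_x(object, x)
  out <- cnn_forward_cpp(object$weights, X,
                         if (type == "embedding") "embedding" else "prob")
  if (type == "class") {
    object$classes[max.col(out, ties.method = "first")]
  } else if (type == "prob") {
    colnames(out) <- as.character(object$classes)
    out
  } else out
}

#' Extract 256-dimensional identity embeddings
#'
#' The penultimate (256-unit) activations of the classifier for each map;
#' the feature vectors compressed by \code{\link{gait_ae}}.
#'
#' @param model a \code{gait_cnn}.
#' @param x maps (list or array).
#' @return matrix n x 256.
#' @export
extract_embeddings <- function(model, x) {
  stopifnot(inherits(model, "gait_cnn"))
  predict(model, x, type = "embedding")
}

#' @export
print.gait_cnn <- function(x, ...) {
  cat(sprintf(
    "Convolutional gait classifier: %d classes, filters %s, %d epoch(s)\n",
    length(x$classes), paste(x$config$conv_filters, collapse = "-"),
    nrow(x$trace)))
  if (nrow(x$trace) > 0) {
    last <- x$trace[nrow(x$trace), ]
    cat(sprintf("  final train accuracy %.3f%s\n", last$train_accuracy,
                if (!is.na(last$val_accuracy))
                  sprintf(", validation accuracy %.3f", last$val_accuracy)
                else ""))
  }
  invisible(x)
}

#' @export
summary.gait_cnn <- function(object, ...) {
  print(object)
  f <- object$config$conv_filters
  cat(sprintf(
    "  architecture: 32x32x1 -> [conv3x3 %d, pool2] -> [conv3x3 %d, pool2] -> [conv3x3 %d, pool2] -> fc 256 -> softmax %d\n",
    f[1], f[2], f[3], length(object$classes)))
  cat(sprintf("  trained on %d maps (%d held out for validation), input scale %.3f\n",
              object$n_train, object$n_val, object$x_max))
  invisible(object)
}

#' @export
coef.gait_cnn <- function(object, ...) object$weights

#' @export
plot.gait_cnn <- function(x, ...) {
  tr <- x$trace
  if (nrow(tr) == 0) {
    warning("no training trace to plot")
    return(invisible(x))
  }
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  plot(tr$epoch, tr$train_loss, type = "l", xlab = "epoch", ylab = "loss",
       main = "Cross-entropy loss", ...)
  if (any(!is.na(tr$val_loss)))
    graphics::lines(tr$epoch, tr$val_loss, lty = 2)
  plot(tr$epoch, tr$train_accuracy, type = "l", ylim = c(0, 1),
       xlab = "epoch", ylab = "accuracy", main = "Accuracy", ...)
  if (any(!is.na(tr$val_accuracy)))
    graphics::lines(tr$epoch, tr$val_accuracy, lty = 2)
  invisible(x)
}
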