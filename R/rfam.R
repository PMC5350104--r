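#' Initialize network parameters (Nguyen-Widrow)
#'
#' Two recurrent hidden layers between a 256-unit input layer and the output
#' layer. Each unit's incoming weights (feedforward and recurrent together)
#' are drawn as a random direction and rescaled so the incoming-weight vector
#' has norm `0.7 * n_units^(1 / fan_in)`; biases are spread uniformly over
#' `[-beta, beta]`.
#'
#' @param n_in Input dimension (number of checks; default 256).
#' @param n1,n2 Hidden layer sizes.
#' @param n_out Number of output units.
#' @param seed Integer seed.
#' @return List of class `"rfam_params"` with `w_in` (n1 x n_in), `w_h1h1`
#'   (n1 x n1), `b1`, `w_h1h2` (n2 x n1), `w_h2h2` (n2 x n2), `b2`, `w_out`
#'   (n_out x n2), `b_out`.
#' @examples
#' p <- rfam_init(n_out = 123, seed = 1)
#' n_params(p) # 68,223 for the 256-100-100-123 architecture
#' @export
rfam_init <- function(n_in = 256, n1 = 100, n2 = 100, n_out = 1, seed = 1) {
  stopifnot(n_in >= 1, n1 >= 1, n2 >= 1, n_out >= 1)
  nw_layer <- function(n_units, fan_in) {
    beta <- 0.7 * n_units^(1 / fan_in)
    W <- matrix(stats::runif(n_units * fan_in, -0.5, 0.5), n_units, fan_in)
    W <- W * (beta / sqrt(rowSums(W^2)))
    b <- if (n_units > 1) beta * seq(-1, 1, length.out = n_units) else 0
    list(W = W, b = b)
  }
  with_seed(seed, {
    l1 <- nw_layer(n1, n_in + n1)
    l2 <- nw_layer(n2, n1 + n2)
    lo <- nw_layer(n_out, n2)
    structure(list(
      w_in = l1$W[, seq_len(n_in), drop = FALSE],
      w_h1h1 = l1$W[, n_in + seq_len(n1), drop = FALSE],
      b1 = l1$b,
      w_h1h2 = l2$W[, seq_len(n1), drop = FALSE],
      w_h2h2 = l2$W[, n1 + seq_len(n2), drop = FALSE],
      b2 = l2$b,
      w_out = lo$W,
      b_out = lo$b), class = "rfam_params")
  })
}

#' Count trainable parameters
#'
#' Walks every weight matrix and bias vector of a parameter set.
#'
#' @param params An `rfam_params` list (or fitted `rfam` object).
#' @return Integer total.
#' @export
n_params <- function(params) {
  if (inherits(params, "rfam")) params <- params$params
  sum(vapply(params, length, numeric(1)))
}

#' @export
print.rfam_params <- function(x, ...) {
  cat("Recurrent network parameters:",
      ncol(x$w_in), "->", nrow(x$w_in), "(rec) ->", nrow(x$w_h1h2),
      "(rec) ->", nrow(x$w_out), "|", n_params(x), "trainable parameters\n")
  invisible(x)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# affine map of stimulus values onto [-1, 1] given a global (min, max) range
apply_input_map <- function(x, map) {
  map <- unname(map)
  if (map[2] <= map[1]) return(x)
  2 * (x - map[1]) / (map[2] - map[1]) - 1
}

# coerce stimuli to a list of 5 matrices (n x n_in), one per time step
as_step_list <- function(stimulus, n_in = NULL) {
  if (inherits(stimulus, "stim_sequence")) {
    d <- dim(stimulus$frames)
    return(lapply(1:5, function(t) matrix(stimulus$frames[, , t], 1, d[1] * d[2])))
  }
  if (inherits(stimulus, "texture_set")) {
    stimulus <- stimulus_matrix(stimulus$grids)
  }
  if (is.numeric(stimulus) && is.null(dim(stimulus))) {
    stimulus <- matrix(stimulus, 1)
  }
  if (is.matrix(stimulus)) return(rep(list(stimulus), 5))
  if (is.array(stimulus) && length(dim(stimulus)) == 3 && dim(stimulus)[3] == 5) {
    return(lapply(1:5, function(t) stimulus[, , t, drop = TRUE]))
  }
  if (is.list(stimulus) && length(stimulus) == 5) return(stimulus)
  stop("unsupported stimulus representation")
}

#' Forward pass of the recurrent network
#'
#' Elman dynamics: at step t each hidden layer receives feedforward input
#' from the current step and recurrent input from its own output at step
#' t - 1; the recurrent state before step 1 is zero ("reset between trials").
#' All units are sigmoidal.
#'
#' @param params `rfam_params` (or fitted `rfam` object).
#' @param stimulus A `stim_sequence`, a `texture_set`, an `n x n_in` matrix
#'   of static inputs, an `n x n_in x 5` array, or a list of five `n x n_in`
#'   step matrices.
#' @return List with arrays `h1` (n x n1 x 5), `h2`, `out` (n x n_out x 5).
#' @export
rfam_forward <- function(params, stimulus) {
  if (inherits(params, "rfam")) params <- params$params
  steps <- as_step_list(stimulus)
  n <- nrow(steps[[1]])
  n1 <- nrow(params$w_in); n2 <- nrow(params$w_h1h2); no <- nrow(params$w_out)
  h1 <- array(0, c(n, n1, 5)); h2 <- array(0, c(n, n2, 5))
  out <- array(0, c(n, no, 5))
  h1p <- matrix(0, n, n1); h2p <- matrix(0, n, n2)
  for (t in 1:5) {
    a1 <- steps[[t]] %*% t(params$w_in) + h1p %*% t(params$w_h1h1)
    h1p <- sigmoid(sweep(a1, 2, params$b1, "+"))
    a2 <- h1p %*% t(params$w_h1h2) + h2p %*% t(params$w_h2h2)
    h2p <- sigmoid(sweep(a2, 2, params$b2, "+"))
    o <- sigmoid(sweep(h2p %*% t(params$w_out), 2, params$b_out, "+"))
    if (!all(is.finite(o))) stop("non-finite activations in forward pass")
    h1[, , t] <- h1p; h2[, , t] <- h2p; out[, , t] <- o
  }
  list(h1 = h1, h2 = h2, out = out)
}

#' Exact BPTT gradient for one stimulus
#'
#' Gradient of the summed squared error over the five steps with respect to
#' every weight and bias, unrolled through time. Reference implementation
#' (the training loop uses a compiled equivalent); useful for gradient
#' checking.
#'
#' @param params `rfam_params`.
#' @param stimulus One stimulus (vector of length `n_in`, `stim_sequence`, or
#'   list of five 1-row matrices).
#' @param target `n_out x 5` matrix of target outputs in `[0, 1]`.
#' @return List shaped like `params` holding the gradients, with attribute
#'   `"error"` (the summed squared error).
#' @export
bptt_gradients <- function(params, stimulus, target) {
  if (inherits(params, "rfam")) params <- params$params
  no <- nrow(params$w_out)
  target <- matrix(target, no, 5)
  steps <- as_step_list(stimulus)
  stopifnot(nrow(steps[[1]]) == 1)
  fw <- rfam_forward(params, stimulus)
  n1 <- nrow(params$w_in); n2 <- nrow(params$w_h1h2)
  h1 <- matrix(fw$h1[1, , ], n1, 5); h2 <- matrix(fw$h2[1, , ], n2, 5)
  out <- matrix(fw$out[1, , ], no, 5)
  err <- sum((out - target)^2)
  dpre1 <- matrix(0, n1, 5); dpre2 <- matrix(0, n2, 5); dout <- matrix(0, no, 5)
  carry1 <- numeric(n1); carry2 <- numeric(n2)
  for (t in 5:1) {
    o <- out[, t]
    dout[, t] <- 2 * (o - target[, t]) * o * (1 - o)
    g2 <- drop(t(params$w_out) %*% dout[, t]) + carry2
    dpre2[, t] <- g2 * h2[, t] * (1 - h2[, t])
    carry2 <- drop(t(params$w_h2h2) %*% dpre2[, t])
    g1 <- drop(t(params$w_h1h2) %*% dpre2[, t]) + carry1
    dpre1[, t] <- g1 * h1[, t] * (1 - h1[, t])
    carry1 <- drop(t(params$w_h1h1) %*% dpre1[, t])
  }
  h1prev <- cbind(0 * h1[, 1], h1[, 1:4])
  h2prev <- cbind(0 * h2[, 1], h2[, 1:4])
  gr <- list(
    w_in = Reduce(`+`, lapply(1:5, function(t)
      dpre1[, t, drop = FALSE] %*% steps[[t]])),
    w_h1h1 = dpre1 %*% t(h1prev),
    b1 = rowSums(dpre1),
    w_h1h2 = dpre2 %*% t(h1),
    w_h2h2 = dpre2 %*% t(h2prev),
    b2 = rowSums(dpre2),
    w_out = dout %*% t(h2),
    b_out = rowSums(dout))
  attr(gr, "error") <- err
  gr
}

# expand user-supplied targets to an n x (n_out*5) matrix (row p reshapes to
# n_out x 5 column-major)
expand_targets <- function(targets, classes, n, n_out = NULL) {
  if (inherits(targets, "target_patterns")) {
    if (is.null(classes)) classes <- targets$classes
    targets <- targets$values
  }
  if (is.matrix(targets) && !is.null(rownames(targets)) &&
      !is.null(classes) && all(levels(as.factor(classes)) %in% rownames(targets))) {
    # class-mean curves (K x 5): every example gets its class's curve
    stopifnot(ncol(targets) == 5)
    return(targets[as.character(classes), , drop = FALSE])
  }
  if (is.matrix(targets)) {
    stopifnot(nrow(targets) == n, ncol(targets) %% 5 == 0)
    return(targets)
  }
  if (is.array(targets) && length(dim(targets)) == 3) {
    d <- dim(targets)  # n_out x 5 x n
    stopifnot(d[2] == 5, d[3] == n)
    return(t(matrix(targets, d[1] * d[2], d[3])))
  }
  stop("unsupported target representation")
}

#' Fit a recurrent form analysis model
#'
#' Trains a two-stage locally recurrent sigmoid network (Elman-type: full
#' within-layer recurrence in both hidden layers, feedforward everywhere
#' else) to reproduce 5-bin response sequences evoked by static textures,
#' by stochastic gradient descent with exact backpropagation-through-time:
#' each epoch presents one uniformly sampled training pattern, resets the
#' recurrent state to zero, and takes one gradient step on the summed squared
#' error.
#'
#' @param x Training stimuli: a `texture_set` (blurred/flattened internally)
#'   or an `n x n_in` numeric matrix of static inputs in `[0, 1]`.
#' @param targets Target output sequences, one of: `K x 5` matrix of
#'   class-mean curves with class rownames (single output unit; requires
#'   `classes`), an `n x (n_out*5)` matrix, an `n_out x 5 x n` array, or a
#'   `target_patterns` object carrying per-example values.
#' @param classes Factor of per-example class labels (taken from `x` when it
#'   is a `texture_set`).
#' @param n1,n2 Hidden layer sizes. The published architecture uses 100/100;
#'   the scaled desk default is 30/30.
#' @param epochs Number of training epochs (one pattern presentation each).
#' @param learning_rate SGD learning rate.
#' @param momentum Classical momentum coefficient in `[0, 1)` (0 disables).
#' @param weight_decay L2 penalty coefficient on the weights (biases are not
#'   penalized; 0 disables). A small penalty discourages memorization of
#'   individual training textures in favor of class-generic structure.
#' @param clip Gradient-norm clip (0 disables).
#' @param seed Integer seed (initialization and pattern order).
#' @param trace_every Record the probe error every this many epochs.
#' @param n_probe Number of fixed probe patterns for the error trace.
#' @return Object of class `"rfam"`.
#' @examples
#' ts <- make_texture_set(10, seed = 1)
#' tgt <- matrix(seq(0, 1, length.out = 35), 7, 5,
#'               dimnames = list(texture_classes(), NULL))
#' fit <- rfam(ts, tgt, epochs = 200, n1 = 5, n2 = 5, seed = 1)
#' @export
rfam <- function(x, targets, classes = NULL, n1 = 30, n2 = 30, epochs = 1e5,
                 learning_rate = 0.05, momentum = 0.9, weight_decay = 0,
                 clip = 10, seed = 1,
                 trace_every = max(1, floor(epochs / 100)), n_probe = 64) {
  if (inherits(x, "texture_set")) {
    if (is.null(classes)) classes <- x$classes
    x <- stimulus_matrix(x$grids)
  }
  stopifnot(is.matrix(x), epochs >= 1)
  n <- nrow(x)
  # map network inputs to [-1, 1] using the global training-ensemble range
  # (standard min-max input preprocessing; stored and reapplied to probes)
  input_map <- c(min = min(x), max = max(x))
  x <- apply_input_map(x, input_map)
  tg <- expand_targets(targets, classes, n)
  n_out <- ncol(tg) / 5
  params <- rfam_init(ncol(x), n1, n2, n_out, seed = derive_seed(seed, "init"))
  ord <- with_seed(derive_seed(seed, "order"),
                   sample.int(n, epochs, replace = TRUE))
  probe <- with_seed(derive_seed(seed, "probe"),
                     sample.int(n, min(n_probe, n)))
  res <- cpp_rfam_sgd(unclass(params), x, tg, ord - 1L, learning_rate, clip,
                      probe - 1L, as.integer(trace_every), momentum,
                      weight_decay)
  trained <- structure(res[c("w_in", "w_h1h1", "b1", "w_h1h2", "w_h2h2",
                             "b2", "w_out", "b_out")], class = "rfam_params")
  trained$b1 <- drop(trained$b1); trained$b2 <- drop(trained$b2)
  trained$b_out <- drop(trained$b_out)
  structure(list(
    params = trained, init = params,
    trace = data.frame(epoch = res$trace_epoch, error = res$trace_error),
    x = x, targets = tg, classes = classes, input_map = input_map,
    call = match.call(),
    config = list(n1 = n1, n2 = n2, n_out = n_out, epochs = epochs,
                  learning_rate = learning_rate, momentum = momentum,
                  weight_decay = weight_decay, clip = clip, seed = seed)),
    class = "rfam")
}

#' @export
print.rfam <- function(x, ...) {
  cfg <- x$config
  cat("Recurrent form analysis model\n")
  cat("  architecture:", ncol(x$params$w_in), "->", cfg$n1, "(rec) ->",
      cfg$n2, "(rec) ->", cfg$n_out, "|", n_params(x$params), "parameters\n")
  cat("  training:", cfg$epochs, "epochs, lr", cfg$learning_rate,
      "| final probe error", signif(utils::tail(x$trace$error, 1), 4), "\n")
  invisible(x)
}

#' @export
summary.rfam <- function(object, ...) {
  tr <- object$trace
  out <- list(config = object$config, n_params = n_params(object$params),
              initial_error = tr$error[1],
              final_error = utils::tail(tr$error, 1))
  if (!is.null(object$classes)) {
    pred <- predict(object, object$x, average_time = TRUE)
    tgt <- rowMeans(matrix(object$targets[, seq_len(5 * object$config$n_out)],
                           nrow(object$x)))
    out$train_tuning <- evaluate_tuning(rowMeans(pred), tgt, object$classes,
                                        method = "pearson")
  }
  structure(out, class = "summary.rfam")
}

#' @export
print.summary.rfam <- function(x, ...) {
  cat("RFAM fit:", x$n_params, "parameters,", x$config$epochs, "epochs\n")
  cat("  probe error:", signif(x$initial_error, 4), "->",
      signif(x$final_error, 4), "\n")
  if (!is.null(x$train_tuning)) {
    cat("  train-set tuning correlation:", round(x$train_tuning, 3), "\n")
  }
  invisible(x)
}

#' @export
coef.rfam <- function(object, ...) object$params

#' Predict responses of a fitted recurrent model
#'
#' @param object Fitted `rfam`.
#' @param newdata Stimuli (see [rfam_forward()]); default: training stimuli.
#' @param type `"response"` (output units), `"hidden1"` or `"hidden2"`.
#' @param average_time Average over the five steps? If `TRUE` returns an
#'   `n x units` matrix, otherwise an `n x units x 5` array.
#' @param ... Unused.
#' @export
predict.rfam <- function(object, newdata = NULL,
                         type = c("response", "hidden1", "hidden2"),
                         average_time = FALSE, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    steps <- as_step_list(object$x)   # training inputs are stored mapped
  } else {
    steps <- as_step_list(newdata)
    if (!is.null(object$input_map)) {
      steps <- lapply(steps, apply_input_map, map = object$input_map)
    }
  }
  fw <- rfam_forward(object$params, steps)
  y <- switch(type, response = fw$out, hidden1 = fw$h1, hidden2 = fw$h2)
  if (average_time) apply(y, c(1, 2), mean) else y
}

#' @export
fitted.rfam <- function(object, ...) predict(object, object$x)

#' @export
residuals.rfam <- function(object, ...) {
  fw <- predict(object, object$x)
  n <- dim(fw)[1]; no <- dim(fw)[2]
  tgt <- array(NA_real_, dim(fw))
  for (i in seq_len(n)) tgt[i, , ] <- matrix(object$targets[i, ], no, 5)
  fw - tgt
}

#' @export
plot.rfam <- function(x, ...) {
  graphics::plot(x$trace$epoch, x$trace$error, type = "l", log = "y",
                 xlab = "epoch", ylab = "probe error (summed squared)",
                 main = "Training error", ...)
  invisible(x)
}

#' Tuning-curve performance of predicted responses
#'
#' Collapses predicted and target responses to class-mean tuning curves and
#' returns their rank (Spearman) or Pearson correlation.
#'
#' @param predicted,target Numeric vectors, one value per example.
#' @param classes Factor of class labels per example.
#' @param method `"spearman"` or `"pearson"`.
#' @return Correlation between the two class-mean tuning curves.
#' @export
evaluate_tuning <- function(predicted, target, classes,
                            method = c("spearman", "pearson")) {
  method <- match.arg(method)
  classes <- as.factor(classes)
  a <- tapply(predicted, classes, mean)
  b <- tapply(target, classes, mean)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant tuning curve: correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b, method = method)
}
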