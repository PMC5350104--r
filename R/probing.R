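#' Condition-mean tuning curve
#'
#' Mean response per condition (averaged over the five time steps and over
#' examples), with standard errors over examples.
#'
#' @param responses Numeric vector (one responder) or `n x units` matrix of
#'   time-averaged responses, one row per example.
#' @param conditions Factor of condition labels, one per example.
#' @return For a vector: data frame with `condition`, `mean`, `se`,
#'   `n_examples`. For a matrix: list of `mean` and `se` matrices
#'   (conditions x units).
#' @export
tuning_curve <- function(responses, conditions) {
  conditions <- as.factor(conditions)
  if (length(conditions) == 0) stop("no examples")
  if (is.null(dim(responses))) {
    stopifnot(length(responses) == length(conditions))
    m <- tapply(responses, conditions, mean)
    s <- tapply(responses, conditions, stats::sd) /
      sqrt(tapply(responses, conditions, length))
    return(data.frame(condition = names(m), mean = as.numeric(m),
                      se = as.numeric(s),
                      n_examples = as.integer(table(conditions))))
  }
  stopifnot(nrow(responses) == length(conditions))
  lv <- levels(conditions)
  mean_mat <- t(vapply(lv, function(l)
    colMeans(responses[conditions == l, , drop = FALSE]),
    numeric(ncol(responses))))
  se_mat <- t(vapply(lv, function(l) {
    r <- responses[conditions == l, , drop = FALSE]
    apply(r, 2, stats::sd) / sqrt(nrow(r))
  }, numeric(ncol(responses))))
  list(mean = mean_mat, se = se_mat, n_examples = as.integer(table(conditions)))
}

#' Texture tuning index (absolute Michelson contrast)
#'
#' `TTI = |(x - r) / (x + r)|` for a class-mean response `x` against the
#' mean response `r` to unstructured (random) textures. 0 means no
#' selectivity; 1 is the maximum.
#'
#' @param mean_class Mean response to the class.
#' @param mean_random Mean response to random textures.
#' @export
tti <- function(mean_class, mean_random) {
  s <- mean_class + mean_random
  if (any(s == 0)) stop("undefined index: class + random response is zero")
  abs((mean_class - mean_random) / s)
}

#' Texture selectivity index (signed difference)
#'
#' `TSI = x - r`: positive when the unit responds more to the class than to
#' random textures.
#'
#' @inheritParams tti
#' @export
tsi <- function(mean_class, mean_random) mean_class - mean_random

#' Orientation selectivity index
#'
#' The deviation of one orientation's mean response from the average over
#' all orientations, taking the deviation with the largest magnitude and
#' keeping its sign.
#'
#' @param means Numeric vector of mean responses, one per orientation (18).
#' @export
osi <- function(means) {
  dev <- means - mean(means)
  dev[which.max(abs(dev))]
}

#' Speed selectivity index
#'
#' The deviation of one speed's mean response from the stationary-condition
#' response, taking the largest-magnitude deviation with its sign. Ties are
#' broken toward the lower speed (the input order).
#'
#' @param means Mean responses by speed, ordered by increasing speed and
#'   including the stationary condition (speed 0) unless `stationary` is
#'   given separately.
#' @param stationary Mean response to the stationary condition; defaults to
#'   the first entry of `means`.
#' @export
ssi <- function(means, stationary = means[1]) {
  dev <- means - stationary
  dev[which.max(abs(dev))]
}

#' Direction selectivity index
#'
#' The preferred (anti-preferred) speed is the speed with the largest
#' (smallest) mean response across directions; the index is the largest
#' range of direction responses at either of those two speeds. Speed ties
#' break toward the lower speed.
#'
#' @param means `speeds x directions` matrix of mean responses, rows ordered
#'   by increasing speed.
#' @export
dsi <- function(means) {
  sp <- rowMeans(means)
  pref <- which.max(sp); anti <- which.min(sp)
  max(diff(range(means[pref, ])), diff(range(means[anti, ])))
}

#' Selectivity indices of hidden units under simulated experiments
#'
#' Probes every unit of a hidden layer of a fitted recurrent model with
#' static texture ensembles (TSI and TTI per class), oriented noise (OSI),
#' translating noise (SSIt, DSIt) and rotating noise (SSIr, DSIr). Each
#' condition uses `n_examples` examples; responses are sigmoid outputs
#' averaged over the five time steps and over examples. Noise carriers and
#' motion canvases are shared across conditions of the same experiment
#' (paired design).
#'
#' @param model Fitted [rfam()] model.
#' @param layer `"hidden1"` or `"hidden2"`.
#' @param n_examples Examples per condition.
#' @param seed Integer seed.
#' @param experiments Which probe experiments to run.
#' @return Data frame, one row per unit: `tsi_<class>`, `tti_<class>`,
#'   `osi`, `ssi_t`, `dsi_t`, `ssi_r`, `dsi_r` (columns present for the
#'   experiments run), plus `unit` and `layer`.
#' @export
selectivity_indices <- function(model, layer = c("hidden1", "hidden2"),
                                n_examples = 1000, seed = 1,
                                experiments = c("texture", "orientation",
                                                "translation", "rotation")) {
  layer <- match.arg(layer)
  resp <- function(stim) {
    colMeans(predict(model, stim, type = layer, average_time = TRUE))
  }
  n_units <- if (layer == "hidden1") model$config$n1 else model$config$n2
  out <- data.frame(unit = seq_len(n_units), layer = layer)

  if ("texture" %in% experiments) {
    cls <- texture_classes()
    m <- vapply(cls, function(cn)
      resp(texture_probe_batch(cn, n_examples,
                               seed = derive_seed(seed, "tex", cn))),
      numeric(n_units))
    for (cn in setdiff(cls, "random")) {
      out[[paste0("tsi_", cn)]] <- tsi(m[, cn], m[, "random"])
      out[[paste0("tti_", cn)]] <- tti(m[, cn], m[, "random"])
    }
  }
  if ("orientation" %in% experiments) {
    m <- vapply(orientation_grid(), function(a)
      resp(oriented_probe_batch(a, n_examples, seed = derive_seed(seed, "ori"))),
      numeric(n_units))
    out$osi <- apply(m, 1, osi)
  }
  if ("translation" %in% experiments) {
    canv <- motion_canvases(n_examples, derive_seed(seed, "trans"))
    speeds <- speed_grid("translation")
    dirs <- c("up", "right", "down", "left")
    m <- array(0, c(n_units, length(speeds), length(dirs)))
    for (si in seq_along(speeds)) for (di in seq_along(dirs)) {
      m[, si, di] <- resp(translation_probe_batch(canv, speeds[si], dirs[di]))
    }
    sp_means <- apply(m, c(1, 2), mean)
    out$ssi_t <- apply(sp_means, 1, function(v) ssi(v))
    out$dsi_t <- vapply(seq_len(n_units), function(u) dsi(m[u, , ]), numeric(1))
  }
  if ("rotation" %in% experiments) {
    canv <- motion_canvases(n_examples, derive_seed(seed, "rot"))
    speeds <- speed_grid("rotation")
    dirs <- c("cw", "ccw")
    m <- array(0, c(n_units, length(speeds), length(dirs)))
    for (si in seq_along(speeds)) for (di in seq_along(dirs)) {
      m[, si, di] <- resp(rotation_probe_batch(canv, speeds[si], dirs[di]))
    }
    sp_means <- apply(m, c(1, 2), mean)
    out$ssi_r <- apply(sp_means, 1, function(v) ssi(v))
    out$dsi_r <- vapply(seq_len(n_units), function(u) dsi(m[u, , ]), numeric(1))
  }
  out
}
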