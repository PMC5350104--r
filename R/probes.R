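# Batched probe-stimulus generation. Probing a trained network requires
# thousands of examples per condition; these builders generate whole batches
# as n x 256 step matrices so the forward pass runs as matrix products.

# cache of kron(Bc, Br) flat blur operators and rotation gather tables
.probe_cache <- new.env(parent = emptyenv())

flat_blur_operator <- function(size = 16, sigma = 2) {
  key <- sprintf("blur_%d_%g", size, sigma)
  if (is.null(.probe_cache[[key]])) {
    B <- blur_matrix(size, sigma)
    .probe_cache[[key]] <- kronecker(B, B)  # vec(Br X Bc') = (Bc x Br) vec(X)
  }
  .probe_cache[[key]]
}

# gather table for rotating size x size patterns by `angle` about the center:
# 4 source indices + weights per target pixel (NA index = out of support)
rotation_gather <- function(angle, size = 16) {
  key <- sprintf("rot_%d_%g", size, angle)
  if (!is.null(.probe_cache[[key]])) return(.probe_cache[[key]])
  th <- angle * pi / 180
  ctr <- (size + 1) / 2
  g <- expand.grid(r = seq_len(size), col = seq_len(size))
  dr <- g$r - ctr; dc <- g$col - ctr
  sr <- ctr + cos(th) * dr + sin(th) * dc
  sc <- ctr - sin(th) * dr + cos(th) * dc
  r0 <- floor(sr); c0 <- floor(sc); fr <- sr - r0; fc <- sc - c0
  idx <- function(r, c) ifelse(r >= 1 & r <= size & c >= 1 & c <= size,
                               r + size * (c - 1), NA_integer_)
  out <- list(
    i = cbind(idx(r0, c0), idx(r0 + 1, c0), idx(r0, c0 + 1), idx(r0 + 1, c0 + 1)),
    w = cbind((1 - fr) * (1 - fc), fr * (1 - fc), (1 - fr) * fc, fr * fc))
  .probe_cache[[key]] <- out
  out
}

# apply a gather table to rows of flat patterns (n x size^2), fill for NA
gather_apply <- function(flat, gather, fill = 0) {
  out <- matrix(0, nrow(flat), nrow(gather$i))
  for (k in 1:4) {
    idx <- gather$i[, k]
    ok <- !is.na(idx)
    src <- matrix(fill, nrow(flat), length(idx))
    src[, ok] <- flat[, idx[ok], drop = FALSE]
    out <- out + sweep(src, 2, gather$w[, k], "*")
  }
  out
}

#' Batch of static texture probe inputs
#'
#' @param class_name Texture class.
#' @param n Number of examples.
#' @param seed Integer seed.
#' @param sigma Blur width.
#' @return `n x 256` matrix of blurred inputs in `[0, 1]`.
#' @export
texture_probe_batch <- function(class_name, n, seed = 1, sigma = 2) {
  stimulus_matrix(generate_textures(class_name, n, seed = seed), sigma = sigma)
}

#' Batch of oriented-noise probe inputs
#'
#' The same `n` one-dimensional noise carriers rotated to the given angle
#' (paired across angles when the same seed is reused), blurred, static.
#'
#' @param angle Angle on the 18-angle grid (degrees).
#' @param n Number of examples.
#' @param seed Integer seed for the carriers.
#' @param sigma Blur width.
#' @param size Grid side.
#' @return `n x size^2` matrix in `[0, 1]`.
#' @export
oriented_probe_batch <- function(angle, n, seed = 1, sigma = 2, size = 16) {
  v <- with_seed(derive_seed(seed, "oriented"), {
    matrix(sample(c(-1, 1), n * size, replace = TRUE), n, size)
  })
  colpat <- v[, rep(seq_len(size), each = size), drop = FALSE] # value varies along x
  rot <- gather_apply(colpat, rotation_gather(angle, size), fill = 0)
  (rot %*% t(flat_blur_operator(size, sigma)) + 1) / 2
}

# shared blurred canvases for moving probes: size^2c x n matrix (flat) in [0,1]
motion_canvases <- function(n, seed, sigma = 2, canvas_size = 80) {
  arr <- with_seed(derive_seed(seed, "canvas"), {
    array(sample(c(-1, 1), canvas_size^2 * n, replace = TRUE),
          c(canvas_size, canvas_size, n))
  })
  (gaussian_blur(arr, sigma) + 1) / 2
}

#' Batch of translating-noise probe sequences
#'
#' A 16 x 16 window slides across each canvas at `speed` checks per bin in
#' the given direction; canvases can be shared across conditions for a
#' paired design.
#'
#' @param canvases `80 x 80 x n` blurred canvas array (see the `seed`
#'   shortcut) or `NULL` to generate `n` canvases from `seed`.
#' @param speed Speed on the translation grid (checks/bin).
#' @param direction `"up"`, `"right"`, `"down"` or `"left"`.
#' @param n,seed Used when `canvases` is `NULL`.
#' @param size Window side.
#' @return List of five `n x size^2` step matrices.
#' @export
translation_probe_batch <- function(canvases = NULL, speed, direction,
                                    n = 100, seed = 1, size = 16) {
  if (is.null(canvases)) canvases <- motion_canvases(n, seed)
  cs <- dim(canvases)[1]
  n <- dim(canvases)[3]
  total <- 4 * speed
  base <- (cs - size) / 2 + 1
  vertical <- direction %in% c("up", "down")
  step_sign <- if (direction %in% c("down", "right")) 1 else -1
  lapply(1:5, function(t) {
    o <- base - step_sign * total / 2 + step_sign * (t - 1) * speed
    r0 <- if (vertical) o else base
    c0 <- if (vertical) base else o
    ri <- floor(r0); ci <- floor(c0); fr <- r0 - ri; fc <- c0 - ci
    w <- function(dr, dc)
      canvases[ri + dr + 0:(size - 1), ci + dc + 0:(size - 1), , drop = FALSE]
    out <- (1 - fr) * (1 - fc) * w(0, 0)
    if (fr > 0) out <- out + fr * (1 - fc) * w(1, 0)
    if (fc > 0) out <- out + (1 - fr) * fc * w(0, 1)
    if (fr > 0 && fc > 0) out <- out + fr * fc * w(1, 1)
    t(matrix(out, size * size, n))
  })
}

#' Batch of rotating-noise probe sequences
#'
#' The canvas rotates about the window center by `speed` degrees per bin;
#' bilinear resampling, out-of-canvas fill 0.5.
#'
#' @inheritParams translation_probe_batch
#' @param speed Speed on the rotation grid (degrees/bin).
#' @param direction `"cw"` or `"ccw"`.
#' @return List of five `n x size^2` step matrices.
#' @export
rotation_probe_batch <- function(canvases = NULL, speed, direction,
                                 n = 100, seed = 1, size = 16) {
  if (is.null(canvases)) canvases <- motion_canvases(n, seed)
  cs <- dim(canvases)[1]
  n <- dim(canvases)[3]
  flat <- t(matrix(canvases, cs * cs, n))
  sgn <- if (direction == "ccw") 1 else -1
  ctr <- (cs + 1) / 2
  g <- expand.grid(r = seq_len(size), col = seq_len(size))
  wr <- g$r - (size + 1) / 2
  wc <- g$col - (size + 1) / 2
  lapply(1:5, function(t) {
    th <- sgn * speed * (t - 1) * pi / 180
    sr <- ctr + cos(th) * wr + sin(th) * wc
    sc <- ctr - sin(th) * wr + cos(th) * wc
    r0 <- floor(sr); c0 <- floor(sc); fr <- sr - r0; fc <- sc - c0
    idx <- function(r, c) ifelse(r >= 1 & r <= cs & c >= 1 & c <= cs,
                                 r + cs * (c - 1), NA_integer_)
    gth <- list(i = cbind(idx(r0, c0), idx(r0 + 1, c0),
                          idx(r0, c0 + 1), idx(r0 + 1, c0 + 1)),
                w = cbind((1 - fr) * (1 - fc), fr * (1 - fc),
                          (1 - fr) * fc, fr * fc))
    gather_apply(flat, gth, fill = 0.5)
  })
}
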