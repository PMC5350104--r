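#' Glider specifications for multipoint spatial correlation textures
#'
#' A glider is a small set of check offsets over which a texture class imposes
#' a parity constraint: in \eqn{\pm 1} check coding, the product of the checks
#' covered by every complete placement of the glider equals the target parity.
#' Seven named classes are provided: `random` (no constraint), the three-point
#' `white_triangle` / `black_triangle` classes, and the four-point `even`,
#' `odd`, `wye` and `foot` classes. Only the defining correlation is non-zero;
#' all lower-order statistics average to zero over the ensemble.
#'
#' @param name Class name, one of `"random"`, `"white_triangle"`,
#'   `"black_triangle"`, `"even"`, `"odd"`, `"wye"`, `"foot"`, or a custom
#'   label when `offsets` are supplied explicitly.
#' @param offsets Integer matrix with two columns (row, col) of check offsets;
#'   must contain `(0, 0)` and be distinct. `NULL` for the random class.
#' @param parity Target product, `+1` or `-1`. Ignored for the random class.
#' @return An object of class `"glider_spec"`.
#' @examples
#' glider_spec("even")
#' glider_spec("my_glider", offsets = rbind(c(0, 0), c(1, 1)), parity = -1)
#' @export
glider_spec <- function(name, offsets = NULL, parity = NULL) {
  if (is.null(offsets)) {
    lib <- glider_library()
    if (!name %in% names(lib)) {
      stop("unknown texture class '", name, "'; known classes: ",
           paste(names(lib), collapse = ", "), call. = FALSE)
    }
    return(lib[[name]])
  }
  offsets <- matrix(as.integer(offsets), ncol = 2)
  if (anyDuplicated(offsets) > 0) stop("glider offsets must be distinct")
  if (!any(offsets[, 1] == 0 & offsets[, 2] == 0)) {
    stop("glider offsets must include (0, 0)")
  }
  if (!is.null(parity) && !parity %in% c(-1, 1)) stop("parity must be +1 or -1")
  structure(list(name = name, offsets = offsets,
                 parity = if (is.null(parity)) NA_real_ else parity),
            class = "glider_spec")
}

#' The seven standard texture classes
#'
#' @return Named list of [glider_spec()] objects.
#' @export
glider_library <- function() {
  mk <- function(name, off, par) {
    structure(list(name = name, offsets = matrix(as.integer(off), ncol = 2, byrow = TRUE),
                   parity = par), class = "glider_spec")
  }
  list(
    random = structure(list(name = "random", offsets = NULL, parity = NA_real_),
                       class = "glider_spec"),
    white_triangle = mk("white_triangle", c(0, 0, 0, 1, 1, 0), +1),
    black_triangle = mk("black_triangle", c(0, 0, 0, 1, 1, 0), -1),
    even = mk("even", c(0, 0, 0, 1, 1, 0, 1, 1), +1),
    odd  = mk("odd",  c(0, 0, 0, 1, 1, 0, 1, 1), -1),
    wye  = mk("wye",  c(0, 0, 0, 2, 1, 1, 2, 1), +1),
    foot = mk("foot", c(0, 0, 0, 1, 0, 2, 1, 0), +1)
  )
}

#' @export
print.glider_spec <- function(x, ...) {
  if (is.null(x$offsets)) {
    cat("Glider spec:", x$name, "(unconstrained / random)\n")
  } else {
    cat("Glider spec:", x$name, "| parity", sprintf("%+d", x$parity),
        "| offsets:", paste(apply(x$offsets, 1, function(o)
          sprintf("(%d,%d)", o[1], o[2])), collapse = " "), "\n")
  }
  invisible(x)
}

#' Class names of the standard texture library
#' @param include_random Include the unconstrained class?
#' @return Character vector of class names.
#' @export
texture_classes <- function(include_random = TRUE) {
  cls <- names(glider_library())
  if (!include_random) cls <- setdiff(cls, "random")
  cls
}

# Run expr with a private RNG state; restores the caller's .Random.seed.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a reproducible sub-seed from a master seed and a stream label.
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(lapply(list(...), function(x) {
    if (is.character(x)) sum(utf8ToInt(paste(x, collapse = ""))) else as.numeric(x)
  })))
  s <- 0
  for (p in parts) s <- (s * 69069 + round(p) + 1) %% 2147483563
  as.integer(s) + 1L
}

#' Generate binary textures by the Markov recurrence rule
#'
#' Seeds the checks that no complete glider placement determines with
#' independent fair coin flips, then fills the remaining checks in raster
#' order so that the product over every complete glider placement equals the
#' class parity. This realizes the maximum-entropy ensemble whose only
#' non-zero correlation is the glider's.
#'
#' @param spec A [glider_spec()] or a class name.
#' @param n Number of textures to generate.
#' @param seed Integer seed; the same `(spec, n, seed)` reproduces the
#'   identical ensemble.
#' @param size Grid side length in checks (default 16).
#' @return A `size x size x n` array with values in `{-1, +1}` and attributes
#'   `class_name` and `seed`; class `"binary_textures"`.
#' @examples
#' tx <- generate_textures("even", n = 3, seed = 1)
#' all(tx[1:15, 1:15, 1] * tx[1:15, 2:16, 1] *
#'     tx[2:16, 1:15, 1] * tx[2:16, 2:16, 1] == 1)
#' @export
generate_textures <- function(spec, n = 1, seed = 1, size = 16) {
  if (is.character(spec)) spec <- glider_spec(spec)
  stopifnot(inherits(spec, "glider_spec"), n >= 1, size >= 2)
  g <- with_seed(seed, {
    arr <- array(sample(c(-1, 1), size * size * n, replace = TRUE),
                 dim = c(size, size, n))
    if (!is.null(spec$offsets)) {
      off <- spec$offsets
      # dependent offset: last in raster order, so all other glider checks of
      # a placement are already assigned when its dependent check is filled
      ord <- order(off[, 1], off[, 2])
      off <- off[ord, , drop = FALSE]
      d <- off[nrow(off), ]
      rest <- off[-nrow(off), , drop = FALSE]
      flat <- matrix(arr, size * size, n)
      for (i in 0:(size - 1)) {
        for (j in 0:(size - 1)) {
          a <- c(i, j) - d                      # anchor of determining placement
          if (a[1] < 0 || a[2] < 0) next
          src <- sweep(rest, 2, a, "+")
          if (any(src[, 1] >= size | src[, 2] >= size | src[, 2] < 0)) next
          idx <- src[, 1] + 1L + size * src[, 2]
          v <- flat[idx[1], ]
          for (k in seq_len(nrow(src))[-1]) v <- v * flat[idx[k], ]
          flat[i + 1L + size * j, ] <- spec$parity * v
        }
      }
      arr <- array(flat, dim = c(size, size, n))
    }
    arr
  })
  structure(g, class_name = spec$name, seed = seed, class = "binary_textures")
}

#' Generate a single texture
#'
#' @inheritParams generate_textures
#' @return A `size x size` matrix in `{-1, +1}` with attribute `class_name`.
#' @export
generate_texture <- function(spec, seed = 1, size = 16) {
  g <- generate_textures(spec, n = 1, seed = seed, size = size)
  structure(g[, , 1],
            class_name = attr(g, "class_name"), seed = seed,
            class = "binary_texture")
}

#' Average glider product of a texture ensemble
#'
#' Mean over all complete placements (and textures) of the product of checks
#' covered by the glider; per-texture values are returned when
#' `per_texture = TRUE`. A constrained ensemble attains its parity exactly.
#'
#' @param textures A `binary_textures` array (or a single matrix).
#' @param spec A [glider_spec()] or class name (must be a constrained class).
#' @param window Optional `c(row0, col0, rows, cols)` restricting placements
#'   to a subgrid (1-based top-left corner).
#' @param per_texture Return one value per texture instead of the grand mean.
#' @return Scalar mean product, or a vector of length `n`.
#' @export
glider_statistic <- function(textures, spec, window = NULL, per_texture = FALSE) {
  if (is.character(spec)) spec <- glider_spec(spec)
  if (is.null(spec$offsets)) stop("the random class has no defining glider")
  if (length(dim(textures)) == 2) textures <- array(textures, c(dim(textures), 1))
  size_r <- dim(textures)[1]; size_c <- dim(textures)[2]; n <- dim(textures)[3]
  off <- spec$offsets
  r0 <- 1L; c0 <- 1L; nr <- size_r; nc <- size_c
  if (!is.null(window)) { r0 <- window[1]; c0 <- window[2]; nr <- window[3]; nc <- window[4] }
  rows <- (r0 + max(0, -min(off[, 1]))):(r0 + nr - 1 - max(0, max(off[, 1])))
  cols <- (c0 + max(0, -min(off[, 2]))):(c0 + nc - 1 - max(0, max(off[, 2])))
  prod_arr <- array(1, dim = c(length(rows), length(cols), n))
  for (k in seq_len(nrow(off))) {
    prod_arr <- prod_arr *
      textures[rows + off[k, 1], cols + off[k, 2], , drop = FALSE]
  }
  if (per_texture) apply(prod_arr, 3, mean) else mean(prod_arr)
}

# Blur operator for one axis of length n: row-stochastic matrix applying a
# normalized Gaussian kernel with symmetric (reflect) boundary handling.
blur_matrix <- function(n, sigma) {
  stopifnot(sigma > 0)
  r <- ceiling(4 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    src <- (i - r):(i + r)
    # reflect with edge repeat: ..., 2, 1, | 1, 2, ..., n | n, n-1, ...
    src <- ifelse(src < 1, 1 - src, src)
    src <- ifelse(src > n, 2 * n + 1 - src, src)
    for (t in seq_along(src)) B[i, src[t]] <- B[i, src[t]] + k[t]
  }
  B
}

#' Separable Gaussian smoothing of a matrix (linear, no range remapping)
#'
#' Reflect-padded, shift-invariant Gaussian filter applied along rows and
#' columns. Linear: `gaussian_blur(a) + gaussian_blur(b) == gaussian_blur(a + b)`.
#'
#' @param mat Numeric matrix (or `size x size x n` array, blurred slice-wise).
#' @param sigma Gaussian standard deviation in checks.
#' @return Object of the same shape.
#' @export
gaussian_blur <- function(mat, sigma = 2) {
  if (sigma <= 0) stop("sigma must be > 0")
  d <- dim(mat)
  if (length(d) == 2) {
    return(blur_matrix(d[1], sigma) %*% mat %*% t(blur_matrix(d[2], sigma)))
  }
  Br <- blur_matrix(d[1], sigma); Bc <- blur_matrix(d[2], sigma)
  y <- array(Br %*% matrix(mat, d[1], d[2] * d[3]), d)
  z <- aperm(y, c(2, 1, 3))                    # transpose each slice
  z <- Bc %*% matrix(z, d[2], d[1] * d[3])     # = Bc %*% t(slice)
  aperm(array(z, c(d[2], d[1], d[3])), c(2, 1, 3))
}

#' Low-pass filter a binary texture into a contrast frame in [0, 1]
#'
#' Applies [gaussian_blur()] to the \eqn{\pm 1} check grid and remaps linearly
#' to `[0, 1]` (black 0, white 1), emulating optical/retinal blur of the
#' stimulus as seen by cortical neurons.
#'
#' @param texture A `binary_texture` matrix, `binary_textures` array, or any
#'   numeric matrix/array in \eqn{\pm 1} coding.
#' @param sigma Blur standard deviation in checks (default 2).
#' @return Same shape as input, values in `[0, 1]`.
#' @export
lowpass <- function(texture, sigma = 2) {
  if (sigma <= 0) stop("sigma must be > 0")
  x <- unclass(texture)
  attributes(x) <- list(dim = dim(x))
  (gaussian_blur(x, sigma) + 1) / 2
}

# Rotate a matrix about its center by angle (degrees, CCW) with bilinear
# resampling; out-of-support samples get `fill`.
rotate_pattern <- function(mat, angle, fill = 0) {
  n <- nrow(mat); m <- ncol(mat)
  th <- angle * pi / 180
  cr <- (n + 1) / 2; cc <- (m + 1) / 2
  g <- expand.grid(r = seq_len(n), col = seq_len(m))
  # inverse map: target -> source
  dr <- g$r - cr; dc <- g$col - cc
  sr <- cr + cos(th) * dr + sin(th) * dc
  sc <- cc - sin(th) * dr + cos(th) * dc
  bilinear_sample(mat, sr, sc, fill) |> matrix(n, m)
}

bilinear_sample <- function(mat, sr, sc, fill) {
  n <- nrow(mat); m <- ncol(mat)
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  val <- function(r, c) {
    ok <- r >= 1 & r <= n & c >= 1 & c <= m
    out <- rep(fill, length(r))
    out[ok] <- mat[cbind(r[ok], c[ok])]
    out
  }
  val(r0, c0) * (1 - fr) * (1 - fc) + val(r0 + 1, c0) * fr * (1 - fc) +
    val(r0, c0 + 1) * (1 - fr) * fc + val(r0 + 1, c0 + 1) * fr * fc
}

new_stim_sequence <- function(frames, kind, speed = NA_real_,
                              direction = NA_character_, angle = NA_real_,
                              blur_sigma = NA_real_, class_name = NA_character_) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] == 5)
  structure(list(frames = frames, kind = kind, speed = speed,
                 direction = direction, angle = angle,
                 blur_sigma = blur_sigma, class_name = class_name),
            class = "stim_sequence")
}

#' @export
print.stim_sequence <- function(x, ...) {
  cat("Stimulus sequence:", x$kind,
      if (!is.na(x$class_name)) paste0("(", x$class_name, ")") else "",
      "| 5 frames", dim(x$frames)[1], "x", dim(x$frames)[2],
      if (!is.na(x$speed)) paste("| speed", x$speed) else "",
      if (!is.na(x$direction)) paste("| dir", x$direction) else "",
      if (!is.na(x$angle)) paste("| angle", x$angle) else "", "\n")
  invisible(x)
}

#' Static texture stimulus sequence
#'
#' Blurs a binary texture and repeats it over the five 40 ms bins of a trial.
#'
#' @param texture A `binary_texture` matrix (\eqn{\pm 1}).
#' @param sigma Blur width in checks.
#' @return A `stim_sequence` (kind `"static"`).
#' @export
static_sequence <- function(texture, sigma = 2) {
  fr <- lowpass(texture, sigma)
  new_stim_sequence(array(fr, c(dim(fr), 5)), "static", speed = 0,
                    blur_sigma = sigma,
                    class_name = attr(texture, "class_name") %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Oriented binary-noise probe
#'
#' One-dimensional binary noise (16 values) replicated along y, rotated by one
#' of 18 angles on a 10 degree grid spanning `[0, 180)`, blurred, and
#' presented statically for five bins.
#'
#' @param angle Rotation angle in degrees; must lie on the 18-angle grid.
#' @param seed Integer seed for the noise carrier.
#' @param sigma Blur width in checks.
#' @param size Grid side length.
#' @return A `stim_sequence` (kind `"oriented"`).
#' @export
oriented_noise <- function(angle, seed = 1, sigma = 2, size = 16) {
  grid <- orientation_grid()
  if (!isTRUE(any(abs(grid - angle) < 1e-9))) {
    stop("angle must lie on the 18-angle grid: ", paste(grid, collapse = ", "))
  }
  pat <- with_seed(seed, {
    v <- sample(c(-1, 1), size, replace = TRUE)
    matrix(v, size, size, byrow = TRUE)   # value varies along x, constant along y
  })
  rot <- rotate_pattern(pat, angle, fill = 0)
  fr <- (gaussian_blur(rot, sigma) + 1) / 2
  new_stim_sequence(array(fr, c(size, size, 5)), "oriented", angle = angle,
                    blur_sigma = sigma)
}

#' The 18-angle orientation grid (degrees)
#' @export
orientation_grid <- function() seq(0, 170, by = 10)

#' Speed grids for moving-noise probes
#'
#' Translation speeds are in checks per 40 ms bin; rotation speeds in degrees
#' per bin. On a receptive field of 1 degree (16 checks) the translation grid
#' corresponds to 0-25 degrees/s.
#'
#' @param kind `"translation"` or `"rotation"`.
#' @export
speed_grid <- function(kind = c("translation", "rotation")) {
  kind <- match.arg(kind)
  if (kind == "translation") c(0, 0.5, 1, 2, 4, 8, 16)
  else c(0, 0.5, 1, 2, 4, 8, 16, 32, 64, 128)
}

#' Convert a translation speed to degrees per second
#'
#' @param checks_per_bin Speed on the stimulus grid (checks per 40 ms bin).
#' @param rf_deg Receptive-field size in degrees covered by the grid.
#' @param n_checks Number of checks across the receptive field.
#' @param bin_s Bin duration in seconds.
#' @return Speed in degrees of visual angle per second.
#' @examples
#' speed_deg_per_s(16) # fastest probe speed on a 1-degree RF: 25 deg/s
#' @export
speed_deg_per_s <- function(checks_per_bin, rf_deg = 1, n_checks = 16,
                            bin_s = 0.04) {
  checks_per_bin * (rf_deg / n_checks) / bin_s
}

#' Moving-noise probe sequence
#'
#' A 16 x 16 window into a larger blurred binary-noise canvas. For
#' translation the window slides at the stated speed (checks/bin) in one of
#' four cardinal directions, with half-check offsets realized by linear
#' interpolation of the canvas. For rotation the canvas rotates about the
#' window center by `speed` degrees per bin (bilinear resampling,
#' out-of-canvas fill 0.5). Speed 0 gives five identical frames.
#'
#' @param kind `"translation"` or `"rotation"`.
#' @param speed Speed on the corresponding grid (see [speed_grid()]).
#' @param direction `"up"`, `"right"`, `"down"`, `"left"` (translation) or
#'   `"cw"`, `"ccw"` (rotation).
#' @param seed Integer seed for the noise canvas.
#' @param sigma Blur width in checks.
#' @param size Window side length.
#' @param canvas_size Canvas side length.
#' @return A `stim_sequence`.
#' @export
motion_sequence <- function(kind = c("translation", "rotation"), speed,
                            direction, seed = 1, sigma = 2, size = 16,
                            canvas_size = 80) {
  kind <- match.arg(kind)
  grid <- speed_grid(kind)
  if (!isTRUE(any(abs(grid - speed) < 1e-9))) {
    stop("speed ", speed, " not on the ", kind, " grid: ",
         paste(grid, collapse = ", "))
  }
  dirs <- if (kind == "translation") c("up", "right", "down", "left")
          else c("cw", "ccw")
  direction <- match.arg(direction, dirs)
  canvas <- noise_canvas(seed, sigma, canvas_size)
  frames <- array(0, c(size, size, 5))
  if (kind == "translation") {
    total <- 4 * speed
    base <- (canvas_size - size) / 2 + 1     # centered window (1-based, fractional)
    start <- base - total / 2
    step <- c(up = -1, down = 1, right = 1, left = -1)[[direction]]
    vertical <- direction %in% c("up", "down")
    for (t in 1:5) {
      o <- start + (t - 1) * speed
      if (step < 0) o <- base + total / 2 - (t - 1) * speed
      r0 <- if (vertical) o else base
      c0 <- if (vertical) base else o
      frames[, , t] <- crop_linear(canvas, r0, c0, size)
    }
  } else {
    sign <- if (direction == "ccw") 1 else -1
    ctr <- (canvas_size + 1) / 2
    g <- expand.grid(r = seq_len(size), col = seq_len(size))
    wr <- g$r - (size + 1) / 2
    wc <- g$col - (size + 1) / 2
    for (t in 1:5) {
      th <- sign * speed * (t - 1) * pi / 180
      sr <- ctr + cos(th) * wr + sin(th) * wc
      sc <- ctr - sin(th) * wr + cos(th) * wc
      frames[, , t] <- matrix(bilinear_sample(canvas, sr, sc, 0.5), size, size)
    }
  }
  new_stim_sequence(frames, kind, speed = speed, direction = direction,
                    blur_sigma = sigma)
}

noise_canvas <- function(seed, sigma = 2, canvas_size = 80) {
  with_seed(seed, {
    b <- matrix(sample(c(-1, 1), canvas_size^2, replace = TRUE),
                canvas_size, canvas_size)
    (gaussian_blur(b, sigma) + 1) / 2
  })
}

# Crop a size x size window whose top-left corner is at (possibly fractional)
# 1-based position (r0, c0); fractional offsets by linear interpolation.
crop_linear <- function(canvas, r0, c0, size) {
  ri <- floor(r0); ci <- floor(c0)
  fr <- r0 - ri; fc <- c0 - ci
  w <- function(dr, dc) canvas[ri + dr + 0:(size - 1), ci + dc + 0:(size - 1)]
  out <- (1 - fr) * (1 - fc) * w(0, 0)
  if (fr > 0) out <- out + fr * (1 - fc) * w(1, 0)
  if (fc > 0) out <- out + (1 - fr) * fc * w(0, 1)
  if (fr > 0 && fc > 0) out <- out + fr * fc * w(1, 1)
  out
}

#' Empirical correlation statistics of a texture ensemble
#'
#' Reports the mean check value, two-point correlations at a set of small
#' offsets, and the average glider product for each requested glider, all
#' with standard errors over textures. For a constrained class the defining
#' glider statistic equals the class parity exactly, while all lower-order
#' statistics are zero on average.
#'
#' @param textures A `binary_textures` array (single class).
#' @param specs List of [glider_spec()]s (or class names) whose glider
#'   statistics to report; defaults to all constrained classes.
#' @param pair_offsets Matrix of (row, col) offsets for two-point statistics.
#' @return A list of class `"stat_report"` with components `mean_stat`,
#'   `pair_stats`, `glider_stats`, each value accompanied by its SE, and
#'   `n_textures`.
#' @export
verify_statistics <- function(textures, specs = NULL, pair_offsets = NULL) {
  stopifnot(length(dim(textures)) == 3)
  n <- dim(textures)[3]
  if (is.null(specs)) specs <- glider_library()[texture_classes(FALSE)]
  specs <- lapply(specs, function(s) if (is.character(s)) glider_spec(s) else s)
  if (is.null(pair_offsets)) {
    pair_offsets <- rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1), c(0, 2), c(2, 0))
  }
  per_tx_mean <- apply(textures, 3, mean)
  pair <- apply(pair_offsets, 1, function(o) {
    s <- glider_spec("pair", offsets = rbind(c(0, 0), o), parity = NULL)
    v <- glider_statistic(textures, s, per_texture = TRUE)
    c(mean(v), stats::sd(v) / sqrt(n))
  })
  colnames(pair) <- apply(pair_offsets, 1, function(o)
    sprintf("(%d,%d)", o[1], o[2]))
  gl <- vapply(specs, function(s) {
    v <- glider_statistic(textures, s, per_texture = TRUE)
    c(mean(v), stats::sd(v) / sqrt(n))
  }, numeric(2))
  # use glider names; avoid white/black duplication collapsing
  colnames(gl) <- vapply(specs, function(s) s$name, character(1))
  structure(list(
    mean_stat = c(mean = mean(per_tx_mean),
                  se = stats::sd(per_tx_mean) / sqrt(n)),
    pair_stats = t(pair), glider_stats = t(gl), n_textures = n,
    class_name = attr(textures, "class_name")), class = "stat_report")
}

#' @export
print.stat_report <- function(x, digits = 3, ...) {
  cat("Texture ensemble statistics (", x$n_textures, " textures",
      if (!is.null(x$class_name)) paste0(", class ", x$class_name), ")\n", sep = "")
  cat(sprintf("  mean check value: %+.*f (SE %.1e)\n", digits,
              x$mean_stat[1], x$mean_stat[2]))
  cat("  two-point correlations:\n")
  for (i in seq_len(nrow(x$pair_stats))) {
    cat(sprintf("    %-8s %+.*f (SE %.1e)\n", rownames(x$pair_stats)[i],
                digits, x$pair_stats[i, 1], x$pair_stats[i, 2]))
  }
  cat("  glider statistics:\n")
  for (i in seq_len(nrow(x$glider_stats))) {
    cat(sprintf("    %-15s %+.*f (SE %.1e)\n", rownames(x$glider_stats)[i],
                digits, x$glider_stats[i, 1], x$glider_stats[i, 2]))
  }
  invisible(x)
}

#' Flatten blurred static textures into a stimulus matrix
#'
#' Convenience for model fitting: blurs each texture and flattens the frame
#' to a 256-vector (column-major), returning an `n x (size^2)` matrix.
#'
#' @param textures `binary_textures` array.
#' @param sigma Blur width in checks.
#' @return Numeric matrix, one row per texture, values in `[0, 1]`.
#' @export
stimulus_matrix <- function(textures, sigma = 2) {
  fr <- lowpass(textures, sigma)
  d <- dim(fr)
  t(matrix(fr, d[1] * d[2], d[3]))
}
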