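#' Mixed-class texture set
#'
#' Generates `n_per_class` textures for each requested class and concatenates
#' them with class labels, mirroring the interleaved stimulus set of a
#' texture experiment (1024 examples per class in the recordings the
#' surrogate emulates).
#'
#' @param n_per_class Examples per class.
#' @param seed Master seed; per-class streams are derived from it.
#' @param classes Character vector of class names.
#' @param size Grid side length.
#' @return List of class `"texture_set"` with `grids` (`size x size x N`
#'   array), `classes` (factor of length N) and `seed`.
#' @export
make_texture_set <- function(n_per_class, seed = 1,
                             classes = texture_classes(), size = 16) {
  grids <- array(0, c(size, size, n_per_class * length(classes)))
  lab <- character(0)
  for (i in seq_along(classes)) {
    g <- generate_textures(classes[i], n_per_class,
                           seed = derive_seed(seed, "textures", classes[i]),
                           size = size)
    grids[, , (i - 1) * n_per_class + seq_len(n_per_class)] <- g
    lab <- c(lab, rep(classes[i], n_per_class))
  }
  structure(list(grids = grids, classes = factor(lab, levels = classes),
                 seed = seed), class = "texture_set")
}

#' @export
print.texture_set <- function(x, ...) {
  cat("Texture set:", dim(x$grids)[3], "textures,",
      nlevels(x$classes), "classes (",
      paste(levels(x$classes), collapse = ", "), ")\n")
  invisible(x)
}

#' Construct a surrogate neuron
#'
#' A generative stand-in for a recorded V1/V2 cell. The expected firing rate
#' in bin t (40 ms bins, five bins) for a texture is
#' \deqn{r(t) = b \, k(t) \, \max(0,\; 1 + \sum_c g_c \psi_c)}
#' where `b` is the baseline rate, `k(t) = a e^{-(t-1)/\tau} + (1-a)` a
#' transient/sustained temporal kernel, `g_c` the gain for texture class `c`,
#' and `\psi_c` a convex mix (weight `example_sensitivity`) of the class
#' indicator and the per-example glider statistic of class `c` computed on
#' the neuron's receptive-field window. Spike counts are Poisson.
#'
#' @param baseline_rate Baseline firing rate, spikes/s (> 0).
#' @param class_gains Named numeric vector of gains for the six constrained
#'   classes (missing classes default to 0).
#' @param example_sensitivity Weight in `[0, 1]` on per-example statistics
#'   versus the pure class label.
#' @param transient_amp Transient fraction `a` in `[0, 1]`.
#' @param tau Decay constant of the transient, in bins (> 0).
#' @param area `"V1"` or `"V2"`.
#' @param layer `"supra"`, `"gran"` or `"infra"`.
#' @param rf_window `c(row, col)` of the top-left corner of the 8 x 8
#'   receptive-field window used for example statistics.
#' @param rf_filter Optional 8 x 8 numeric matrix: a linear receptive-field
#'   weighting of the checks in the window, adding example-specific drive
#'   (`sum(rf_filter * window) / 8`). Creates within-class response variance.
#' @param id Neuron identifier.
#' @return Object of class `"surrogate_neuron"`.
#' @export
surrogate_neuron <- function(baseline_rate = 30, class_gains = c(even = 0.5),
                             example_sensitivity = 0.3, transient_amp = 0.5,
                             tau = 1, area = "V2", layer = "supra",
                             rf_window = c(5, 5), rf_filter = NULL,
                             id = "sn1") {
  stopifnot(baseline_rate > 0, tau > 0,
            transient_amp >= 0, transient_amp <= 1,
            example_sensitivity >= 0, example_sensitivity <= 1)
  gains <- stats::setNames(numeric(6), texture_classes(FALSE))
  gains[names(class_gains)] <- class_gains
  structure(list(baseline_rate = baseline_rate, class_gains = gains,
                 example_sensitivity = example_sensitivity,
                 transient_amp = transient_amp, tau = tau,
                 area = area, layer = layer, rf_window = rf_window,
                 rf_filter = rf_filter, id = id),
            class = "surrogate_neuron")
}

#' @export
print.surrogate_neuron <- function(x, ...) {
  cat("Surrogate neuron", x$id, sprintf("(%s %s)", x$area, x$layer),
      "| baseline", x$baseline_rate, "sp/s | transient", round(x$transient_amp, 2),
      "tau", round(x$tau, 2), "\n  gains:",
      paste(sprintf("%s %+0.2f", names(x$class_gains), x$class_gains),
            collapse = ", "), "\n")
  invisible(x)
}

# temporal kernel over the five 40 ms bins
temporal_kernel <- function(neuron, n_bins = 5) {
  t <- seq_len(n_bins)
  neuron$transient_amp * exp(-(t - 1) / neuron$tau) + (1 - neuron$transient_amp)
}

#' Per-example glider statistics within a window
#'
#' For each texture, the average glider product of each constrained class's
#' glider over complete placements inside the given window.
#'
#' @param grids `size x size x N` array in \eqn{\pm 1}.
#' @param rf_window `c(row, col)` top-left corner of the window.
#' @param window_size Window side length.
#' @return `N x 6` matrix, columns named by class.
#' @export
example_statistics <- function(grids, rf_window = c(5, 5), window_size = 8) {
  cls <- texture_classes(FALSE)
  win <- c(rf_window[1], rf_window[2], window_size, window_size)
  n <- dim(grids)[3]
  out <- matrix(0, n, length(cls), dimnames = list(NULL, cls))
  for (cn in cls) {
    out[, cn] <- glider_statistic(grids, cn, window = win, per_texture = TRUE)
  }
  out
}

# expected rate (sp/s) per bin for one neuron across a texture set:
# returns N x 5 matrix
expected_rates <- function(neuron, tset, stats = NULL) {
  cls <- texture_classes(FALSE)
  if (is.null(stats)) stats <- example_statistics(tset$grids, neuron$rf_window)
  ind <- outer(as.character(tset$classes), cls, "==") * 1
  s <- neuron$example_sensitivity
  psi <- (1 - s) * ind + s * stats
  drive <- 1 + drop(psi %*% neuron$class_gains[cls])
  if (!is.null(neuron$rf_filter)) {
    f <- neuron$rf_filter
    w <- neuron$rf_window
    rows <- w[1] + seq_len(nrow(f)) - 1
    colsw <- w[2] + seq_len(ncol(f)) - 1
    patch <- matrix(tset$grids[rows, colsw, ], nrow(f) * ncol(f),
                    dim(tset$grids)[3])
    drive <- drive + drop(crossprod(c(f), patch)) / nrow(f)
  }
  outer(pmax(0, drive), temporal_kernel(neuron)) * neuron$baseline_rate
}

#' Simulate one response record
#'
#' Poisson spike counts in five 40 ms bins for one neuron and one texture.
#' Deterministic given `(neuron, texture, repeat_seed)`.
#'
#' @param neuron A [surrogate_neuron()].
#' @param texture A `binary_texture` matrix with a `class_name` attribute.
#' @param repeat_seed Integer seed for the count noise.
#' @param expected Return the expected counts (no noise) instead.
#' @param bin_s Bin width in seconds.
#' @return Numeric vector of 5 counts (or expected counts).
#' @export
simulate_response <- function(neuron, texture, repeat_seed = 1,
                              expected = FALSE, bin_s = 0.04) {
  cn <- attr(texture, "class_name")
  if (is.null(cn)) stop("texture must carry a class_name attribute")
  tset <- list(grids = array(unclass(texture), c(dim(texture), 1)),
               classes = factor(cn, levels = texture_classes()))
  mu <- expected_rates(neuron, tset)[1, ] * bin_s
  if (expected) return(mu)
  with_seed(derive_seed(repeat_seed, neuron$id), stats::rpois(length(mu), mu))
}

#' Generate a surrogate population
#'
#' Draws neurons with area/layer-dependent gain scales: multipoint
#' selectivity is weakest in V1, intermediate in V2 granular/infragranular,
#' and strongest in V2 supragranular, where the mean gain for the `even`
#' class is positive so that the supragranular population average is
#' even-preferring. Temporal kernels span transient, sustained and mixed
#' dynamics.
#'
#' @param n Named integer vector of counts per `area.layer` group, e.g.
#'   `c(V1.supra = 32, V2.supra = 32)`. The default mirrors the laminar
#'   composition of the recorded sample (269 V1 / 153 V2 cells with certain
#'   laminar assignment: 32/153/71 and 32/34/57).
#' @param seed Integer seed.
#' @param gain_sd Named vector of gain scales per group.
#' @param gain_mean_even Mean `even` gain for the V2 supragranular group.
#' @param example_sensitivity Shared mixing weight (see [surrogate_neuron()]).
#' @param rf_filter_sd Standard deviation of the example-specific
#'   receptive-field drive (see [surrogate_neuron()]); 0 disables it.
#' @param size Stimulus grid side (for placing receptive-field windows).
#' @return List of `surrogate_neuron` objects, class `"surrogate_population"`.
#' @export
make_population <- function(n = c(V1.supra = 32, V1.gran = 153, V1.infra = 71,
                                  V2.supra = 32, V2.gran = 34, V2.infra = 57),
                            seed = 1,
                            gain_sd = c(V1.supra = 0.08, V1.gran = 0.05,
                                        V1.infra = 0.05, V2.supra = 0.35,
                                        V2.gran = 0.15, V2.infra = 0.12),
                            gain_mean_even = 0.45,
                            example_sensitivity = 0.3, rf_filter_sd = 0.2,
                            size = 16) {
  stopifnot(all(n >= 0), all(names(n) %in% names(gain_sd)))
  cls <- texture_classes(FALSE)
  pop <- with_seed(seed, {
    out <- list()
    for (grp in names(n)) {
      if (n[[grp]] == 0) next
      al <- strsplit(grp, ".", fixed = TRUE)[[1]]
      for (i in seq_len(n[[grp]])) {
        mu <- stats::setNames(numeric(6), cls)
        if (grp == "V2.supra") {
          # even-preferring on average; salient classes get modest means
          mu[c("even", "odd", "black_triangle", "white_triangle")] <-
            c(gain_mean_even, 0.10, 0.08, -0.06)
        }
        gains <- stats::rnorm(6, mu, gain_sd[[grp]])
        names(gains) <- cls
        filt <- if (rf_filter_sd > 0) {
          matrix(stats::rnorm(64, 0, rf_filter_sd), 8, 8)
        } else NULL
        # the supragranular V2 population average responds to its preferred
        # (even) class with a transient-sustained time course: strongly
        # selective neurons are drawn with a substantial transient riding on
        # a sustained pedestal, so the population-average class difference
        # carries an onset transient without vanishing late in the window
        amp <- stats::runif(1)
        if (grp == "V2.supra") {
          w <- stats::plogis(4 * (gains[["even"]] - 0.2))
          amp <- (1 - w) * amp + w * stats::runif(1, 0.4, 0.8)
        }
        out[[length(out) + 1L]] <- surrogate_neuron(
          baseline_rate = stats::rlnorm(1, log(30), 0.35),
          class_gains = gains,
          example_sensitivity = example_sensitivity,
          transient_amp = amp,
          tau = stats::runif(1, 0.5, 2.5),
          area = al[1], layer = al[2],
          rf_window = c(sample.int(size - 7, 1), sample.int(size - 7, 1)),
          rf_filter = filt,
          id = sprintf("%s_%s_%03d", al[1], al[2], i))
      }
    }
    out
  })
  class(pop) <- "surrogate_population"
  pop
}

#' @export
print.surrogate_population <- function(x, ...) {
  tab <- table(vapply(x, function(nn) paste(nn$area, nn$layer), character(1)))
  cat("Surrogate population:", length(x), "neurons\n")
  print(tab)
  invisible(x)
}

#' Simulate a population's responses to a texture set
#'
#' @param population A `surrogate_population` (or list of neurons).
#' @param tset A [make_texture_set()] result.
#' @param n_repeats Repeats per texture.
#' @param seed Integer seed for the noise.
#' @param shared_gain_sd Log-scale SD of a multiplicative gain fluctuation
#'   shared by all neurons within a trial (one draw per example x repeat;
#'   lognormal with mean 1). Emulates the correlated trial-to-trial
#'   variability of cortical populations, which a population average cannot
#'   average away. 0 disables it.
#' @param bin_s Bin width in seconds.
#' @return Object of class `"response_set"`: `counts` array
#'   (neurons x examples x 5 bins x repeats), `rates` (trial-averaged rates,
#'   sp/s, neurons x examples x 5), `classes`, `neurons`, `bin_s`.
#' @export
simulate_responses <- function(population, tset, n_repeats = 2, seed = 1,
                               shared_gain_sd = 0.3, bin_s = 0.04) {
  nn <- length(population)
  N <- dim(tset$grids)[3]
  mu <- array(0, c(nn, N, 5))
  stat_cache <- new.env()
  for (i in seq_len(nn)) {
    neuron <- population[[i]]
    key <- paste(neuron$rf_window, collapse = "_")
    if (is.null(stat_cache[[key]])) {
      stat_cache[[key]] <- example_statistics(tset$grids, neuron$rf_window)
    }
    mu[i, , ] <- expected_rates(neuron, tset, stats = stat_cache[[key]])
  }
  counts <- with_seed(derive_seed(seed, "poisson"), {
    lam <- rep(c(mu * bin_s), n_repeats)
    if (shared_gain_sd > 0) {
      g <- stats::rlnorm(N * n_repeats, -shared_gain_sd^2 / 2, shared_gain_sd)
      gfull <- array(rep(g, each = nn), c(nn, N, n_repeats))
      lam <- lam * c(aperm(array(gfull, c(nn, N, n_repeats, 5)),
                           c(1, 2, 4, 3)))
    }
    array(stats::rpois(nn * N * 5 * n_repeats, lam), c(nn, N, 5, n_repeats))
  })
  rates <- apply(counts, c(1, 2, 3), mean) / bin_s
  structure(list(counts = counts, rates = rates, classes = tset$classes,
                 neurons = population, bin_s = bin_s, expected = mu),
            class = "response_set")
}

#' @export
print.response_set <- function(x, ...) {
  d <- dim(x$counts)
  cat("Response set:", d[1], "neurons x", d[2], "examples x", d[3],
      "bins x", d[4], "repeats\n")
  invisible(x)
}

#' Normalize firing rates to training targets in [0, 1]
#'
#' One affine map shared by every neuron, condition and bin: subtract the
#' global minimum rate, then divide by the maximum of the shifted rates, so
#' that the global minimum maps to 0 and the global maximum to 1.
#'
#' @param rates Numeric array/matrix of (trial-averaged) firing rates.
#' @return Object of class `"target_patterns"`: `values` (same shape, in
#'   `[0, 1]`), `min_rate`, `max_rate`.
#' @export
normalize_targets <- function(rates) {
  rng <- range(rates)
  if (diff(rng) == 0) stop("degenerate normalization: all rates are equal")
  structure(list(values = (rates - rng[1]) / (rng[2] - rng[1]),
                 min_rate = rng[1], max_rate = rng[2]),
            class = "target_patterns")
}

#' Population-average response
#'
#' Mean response across a subset of neurons, per condition and bin, then
#' normalized to `[0, 1]`. With the default subset selector this produces a
#' supragranular V2 population average (V2pa), the single-output training
#' target of the population-average recurrent model.
#'
#' @param responses A [simulate_responses()] result.
#' @param subset Logical/integer index of neurons, or a predicate taking a
#'   neuron. Default: V2 supragranular neurons.
#' @return A `target_patterns` object whose `values` is an
#'   `examples x 5 bins` matrix; also carries the `classes` factor.
#' @export
population_average <- function(responses, subset = NULL) {
  if (is.null(subset)) {
    subset <- function(nn) nn$area == "V2" && nn$layer == "supra"
  }
  if (is.function(subset)) {
    subset <- which(vapply(responses$neurons, subset, logical(1)))
  }
  if (length(subset) == 0) stop("empty neuron subset")
  avg <- apply(responses$rates[subset, , , drop = FALSE], c(2, 3), mean)
  tp <- normalize_targets(avg)
  tp$classes <- responses$classes
  tp$n_neurons <- length(subset)
  tp
}

#' Split-half consistency of a class tuning curve
#'
#' For each of `n_splits` random 50/50 splits of the examples within every
#' class, compute the class-mean tuning curve on each half and their Pearson
#' correlation; return the mean correlation over splits. A noiseless
#' class-deterministic responder has consistency 1.
#'
#' @param response Numeric vector: one (time-averaged) response per example.
#' @param classes Factor of class labels, one per example (>= 2 per class).
#' @param n_splits Number of random splits.
#' @param seed Integer seed for the splits.
#' @return Mean split-half correlation (scalar).
#' @export
consistency <- function(response, classes, n_splits = 5000, seed = 1) {
  classes <- droplevels(as.factor(classes))
  tab <- table(classes)
  if (any(tab < 2)) stop("every class needs at least 2 examples")
  K <- nlevels(classes)
  with_seed(derive_seed(seed, "splits"), {
    curve1 <- matrix(0, K, n_splits)
    curve2 <- matrix(0, K, n_splits)
    for (k in seq_len(K)) {
      idx <- which(classes == levels(classes)[k])
      nh <- floor(length(idx) / 2)
      x <- response[idx]
      # one permutation per split; first nh entries form half A
      sel <- replicate(n_splits, sample.int(length(idx)))
      xa <- matrix(x[sel[seq_len(nh), ]], nh, n_splits)
      xb <- matrix(x[sel[(nh + 1):length(idx), ]],
                   length(idx) - nh, n_splits)
      curve1[k, ] <- colMeans(xa)
      curve2[k, ] <- colMeans(xb)
    }
    mean(vapply(seq_len(n_splits),
                function(s) stats::cor(curve1[, s], curve2[, s]),
                numeric(1)))
  })
}

#' Class-mean target curves
#'
#' Collapses per-example target values to one 5-bin curve per class; used as
#' the learning target, where every example of a class shares the class-mean
#' curve.
#'
#' @param targets A `target_patterns` from [population_average()] (values:
#'   examples x bins; must carry `classes`), or a matrix plus `classes`.
#' @param classes Factor of per-example classes (if `targets` is a matrix).
#' @param renormalize Rescale the class-mean curves so the global minimum
#'   and maximum over classes and bins are exactly 0 and 1 (the target
#'   convention of the learning rule). `FALSE` keeps the raw means.
#' @return `n_classes x 5` matrix with class rownames.
#' @export
class_mean_targets <- function(targets, classes = NULL, renormalize = TRUE) {
  if (inherits(targets, "target_patterns")) {
    classes <- targets$classes
    targets <- targets$values
  }
  stopifnot(!is.null(classes), nrow(targets) == length(classes))
  out <- apply(targets, 2, function(col) tapply(col, classes, mean))
  out <- out[levels(as.factor(classes)), , drop = FALSE]
  if (renormalize) out <- normalize_targets(out)$values
  out
}
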