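#' Spike-triggered moments of a stimulus ensemble
#'
#' Rate-weighted mean (STA) and covariance (STC) of the stimuli, together
#' with the unweighted raw ensemble moments. Stimuli are weighted by the
#' mean response they evoked, so doubling all rates leaves the moments
#' unchanged.
#'
#' @param stimuli `n x d` matrix of flattened (blurred) stimulus frames.
#' @param rates Numeric vector of n non-negative mean responses.
#' @return List of class `"st_moments"`: `sta`, `stc`, `raw_mean`,
#'   `raw_cov`, `n_samples`, `mean_rate`.
#' @export
spike_triggered_moments <- function(stimuli, rates) {
  stimuli <- as.matrix(stimuli)
  stopifnot(nrow(stimuli) == length(rates))
  if (any(rates < 0)) stop("rates must be non-negative")
  if (sum(rates) == 0) stop("degenerate ensemble: all rates are zero")
  w <- rates / sum(rates)
  sta <- drop(crossprod(stimuli, w))
  ctr <- sweep(stimuli, 2, sta)
  stc <- crossprod(ctr * sqrt(w), ctr * sqrt(w))
  raw_mean <- colMeans(stimuli)
  rctr <- sweep(stimuli, 2, raw_mean)
  raw_cov <- crossprod(rctr) / nrow(stimuli)
  structure(list(sta = sta, stc = stc, raw_mean = raw_mean,
                 raw_cov = raw_cov, n_samples = nrow(stimuli),
                 mean_rate = mean(rates)),
            class = "st_moments")
}

# truncated whitener: d x r matrix M with cov(M'(s - m)) = I on the retained
# subspace; dimensions with eigenvalue below tol * max are dropped (blurred
# stimulus ensembles are strongly low-pass, leaving near-null directions
# where whitening would only amplify sampling noise)
whitening_basis <- function(C, tol = 1e-6) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  keep <- e$values >= tol * e$values[1]
  e$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e$values[keep]), sum(keep))
}

# Gaussian KL divergence objective of a whitened subspace B:
# 0.5 * (tr(B'(L + mu mu')B) - logdet(B'LB) - k)
istac_kl <- function(B, L, mu) {
  M <- crossprod(B, L %*% B)
  k <- ncol(B)
  0.5 * (sum(diag(M)) + sum(crossprod(B, mu)^2) -
           determinant(M, logarithm = TRUE)$modulus[1] - k)
}

#' Maximally informative filters (iSTAC)
#'
#' Greedy selection of an orthonormal stimulus subspace maximizing the
#' Kullback-Leibler divergence between Gaussian approximations of the
#' spike-triggered and raw stimulus ensembles, evaluated in whitened
#' coordinates. The candidate pool is the whitened STC eigenvectors plus the
#' whitened STA direction.
#'
#' @param moments A [spike_triggered_moments()] result.
#' @param n_filters Number of filters to select (at most the stimulus
#'   dimension).
#' @param whiten_tol Relative eigenvalue cutoff of the raw covariance below
#'   which stimulus dimensions are excluded from the whitened search space.
#'   Blurred texture ensembles are strongly low-pass: dimensions carrying
#'   less than ~0.1% of the leading variance hold no usable stimulus power,
#'   and whitening them would only amplify sampling noise.
#' @return List of class `"istac_filters"`: `filters` (`d x n_filters`,
#'   orthonormal in stimulus space, ranked), `info` (KL increment per
#'   filter, nats), `whitened_basis`, `raw_mean`.
#' @export
istac_filters <- function(moments, n_filters = 15, whiten_tol = 1e-3) {
  d <- length(moments$sta)
  if (n_filters > d) stop("n_filters exceeds the stimulus dimension")
  M <- whitening_basis(moments$raw_cov, whiten_tol)
  r <- ncol(M)
  if (n_filters > r) {
    warning("n_filters reduced to the rank of the whitened space (", r, ")")
    n_filters <- r
  }
  mu <- drop(crossprod(M, moments$sta - moments$raw_mean))
  L <- crossprod(M, moments$stc %*% M)
  L <- (L + t(L)) / 2
  eg <- eigen(L, symmetric = TRUE)
  cand <- cbind(eg$vectors, mu / max(sqrt(sum(mu^2)), 1e-12))
  B <- matrix(0, r, 0)
  info <- numeric(0)
  kl_prev <- 0
  avail <- rep(TRUE, ncol(cand))
  for (k in seq_len(n_filters)) {
    best <- -Inf; best_j <- NA; best_vec <- NULL
    for (j in which(avail)) {
      v <- cand[, j]
      if (k > 1) v <- v - B %*% crossprod(B, v)
      nv <- sqrt(sum(v^2))
      if (nv < 1e-8) { avail[j] <- FALSE; next }
      v <- v / nv
      kl <- istac_kl(cbind(B, v), L, mu)
      if (kl > best) { best <- kl; best_j <- j; best_vec <- v }
    }
    if (is.na(best_j)) break
    B <- cbind(B, best_vec)
    avail[best_j] <- FALSE
    info <- c(info, best - kl_prev)
    kl_prev <- best
  }
  # map back to stimulus space and re-orthonormalize sequentially (the span
  # and ordering are preserved; projections are taken about the raw mean)
  Fs <- M %*% B
  for (k in seq_len(ncol(Fs))) {
    v <- Fs[, k]
    if (k > 1) v <- v - Fs[, 1:(k - 1), drop = FALSE] %*%
        crossprod(Fs[, 1:(k - 1), drop = FALSE], v)
    Fs[, k] <- v / sqrt(sum(v^2))
  }
  structure(list(filters = Fs, info = info, whitened_basis = B,
                 raw_mean = moments$raw_mean),
            class = "istac_filters")
}

#' @export
print.istac_filters <- function(x, ...) {
  cat("iSTAC filters:", ncol(x$filters), "filters; information (nats):",
      paste(signif(x$info, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Histogram-ratio estimate of a static nonlinearity
#'
#' Ratio of the rate-weighted (spike-triggered) histogram to the raw
#' histogram of stimulus projections onto one filter, over 25 equal-width
#' bins spanning four standard deviations either side of the mean
#' projection; the result is in units of response rate. Empty raw bins are
#' linearly interpolated; projections beyond the range are clamped to the
#' edge bins.
#'
#' @param filter Length-d filter vector.
#' @param stimuli `n x d` stimulus matrix.
#' @param rates Length-n non-negative responses.
#' @param n_bins Number of bins (default 25).
#' @param center Value subtracted from stimuli before projecting (default
#'   the raw ensemble mean).
#' @return List of class `"ln_nonlinearity"`: `centers`, `values`,
#'   `breaks`, `mean_rate`.
#' @export
estimate_nonlinearity <- function(filter, stimuli, rates, n_bins = 25,
                                  center = colMeans(stimuli)) {
  if (all(filter == 0)) stop("filter must be non-zero")
  if (sum(rates) == 0) stop("degenerate ensemble: all rates are zero")
  proj <- drop(sweep(as.matrix(stimuli), 2, center) %*% filter)
  m <- mean(proj); s <- stats::sd(proj)
  breaks <- seq(m - 4 * s, m + 4 * s, length.out = n_bins + 1)
  bin <- findInterval(proj, breaks, all.inside = TRUE)
  cnt <- tabulate(bin, n_bins)
  tot <- vapply(seq_len(n_bins), function(b) sum(rates[bin == b]), numeric(1))
  vals <- ifelse(cnt > 0, tot / cnt, NA_real_)
  centers <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  if (anyNA(vals)) {
    ok <- !is.na(vals)
    vals <- stats::approx(centers[ok], vals[ok], xout = centers,
                          rule = 2)$y
  }
  structure(list(centers = centers, values = vals, breaks = breaks,
                 mean_rate = mean(rates), center = center, filter = filter),
            class = "ln_nonlinearity")
}

#' Fit a linear-nonlinear model by spike-triggered analysis
#'
#' The feedforward baseline: maximally informative filters from the
#' spike-triggered moments (iSTAC), each followed by a histogram-ratio
#' static nonlinearity; the model output is the sum of the per-filter
#' nonlinearity outputs (separability across filter dimensions is assumed).
#'
#' @param stimuli `n x d` matrix of flattened blurred stimulus frames.
#' @param rates Length-n mean responses (e.g. mean rate over the 40-200 ms
#'   analysis window).
#' @param n_filters Number of informative filters.
#' @param n_bins Histogram bins for each nonlinearity.
#' @return Object of class `"ln_model"`.
#' @examples
#' ts <- make_texture_set(30, seed = 1)
#' X <- stimulus_matrix(ts$grids)
#' rates <- pmax(0, 5 + 40 * (X[, 120] - 0.5))
#' fit <- ln_istac(X, rates, n_filters = 2)
#' cor(predict(fit, X), rates)
#' @export
ln_istac <- function(stimuli, rates, n_filters = 15, n_bins = 25) {
  stimuli <- as.matrix(stimuli)
  mom <- spike_triggered_moments(stimuli, rates)
  fl <- istac_filters(mom, n_filters)
  nls <- lapply(seq_len(ncol(fl$filters)), function(k) {
    estimate_nonlinearity(fl$filters[, k], stimuli, rates, n_bins,
                          center = mom$raw_mean)
  })
  structure(list(moments = mom, filters = fl$filters, info = fl$info,
                 nonlinearities = nls, mean_rate = mom$mean_rate,
                 call = match.call()),
            class = "ln_model")
}

#' @export
print.ln_model <- function(x, ...) {
  cat("Linear-nonlinear model:", ncol(x$filters), "iSTAC filters,",
      "mean rate", signif(x$mean_rate, 4), "\n")
  cat("  information (nats):", paste(signif(x$info, 3), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.ln_model <- function(object, ...) object$filters

#' Predict responses of a fitted LN model
#'
#' Sum over filters of each nonlinearity evaluated at the stimulus
#' projection; projections beyond the histogram support use the edge values.
#'
#' @param object Fitted `ln_model`.
#' @param newdata `n x d` stimulus matrix (or `texture_set`).
#' @param n_filters Use only the first `n_filters` filters.
#' @param ... Unused.
#' @return Numeric vector of predicted rates.
#' @export
predict.ln_model <- function(object, newdata, n_filters = NULL, ...) {
  if (inherits(newdata, "texture_set")) {
    newdata <- stimulus_matrix(newdata$grids)
  }
  newdata <- as.matrix(newdata)
  kk <- if (is.null(n_filters)) seq_along(object$nonlinearities)
        else seq_len(n_filters)
  ctr <- sweep(newdata, 2, object$moments$raw_mean)
  out <- numeric(nrow(newdata))
  for (k in kk) {
    nl <- object$nonlinearities[[k]]
    p <- drop(ctr %*% object$filters[, k])
    out <- out + stats::approx(nl$centers, nl$values, xout = p, rule = 2)$y
  }
  out
}

#' @export
plot.ln_model <- function(x, ...) {
  graphics::plot(seq_along(x$info), x$info, type = "h", lwd = 3,
                 xlab = "filter rank", ylab = "information (nats)",
                 main = "iSTAC filter information", ...)
  invisible(x)
}
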