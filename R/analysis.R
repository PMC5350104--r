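#' Mean response time courses
#'
#' Collapses responses to one 5-bin time course per unit (mean over examples
#' and, for spiking data, repeats).
#'
#' @param x A fitted [rfam()] model (supply `stimuli`) or a `response_set`.
#' @param stimuli Probe stimuli for a model (`texture_set` or matrix).
#' @param layer Hidden layer for a model.
#' @return `units x 5` matrix.
#' @export
time_courses <- function(x, stimuli = NULL, layer = "hidden1") {
  if (inherits(x, "rfam")) {
    y <- predict(x, stimuli, type = layer)
    return(apply(y, c(2, 3), mean))     # units x 5
  }
  if (inherits(x, "response_set")) {
    return(apply(x$rates, c(1, 3), mean))
  }
  stop("x must be a fitted rfam model or a response_set")
}

#' PCA embedding of response dynamics
#'
#' Each unit's/neuron's 5-bin time course is optionally shifted by its
#' afferent onset delay (neural courses only; hidden units have no afferent
#' delay), max-normalized, stacked into one matrix, and decomposed by PCA
#' (time points mean-centered). Units are embedded by their projections on
#' the first two components.
#'
#' @param courses `units x 5` matrix, or named list of such matrices (one
#'   per group, e.g. `list(H1 = ..., V1 = ...)`).
#' @param neural Logical vector (or vector of group names) marking rows/
#'   groups to be shifted by the onset delay.
#' @param shift_bins Onset delay in bins (40 ms = 1 bin).
#' @return List of class `"dynamics_embedding"`: `components` (5 x k),
#'   `variance_explained`, `projections` (units x 2), `group`.
#' @export
dynamics_pca <- function(courses, neural = NULL, shift_bins = 1) {
  if (is.list(courses) && !is.matrix(courses)) {
    group <- rep(names(courses), vapply(courses, nrow, numeric(1)))
    is_neural <- group %in% neural
    courses <- do.call(rbind, courses)
  } else {
    group <- rep("all", nrow(courses))
    is_neural <- if (is.null(neural)) rep(FALSE, nrow(courses)) else neural
  }
  T_ <- ncol(courses)
  shifted <- courses
  if (shift_bins > 0 && any(is_neural)) {
    idx <- pmin(seq_len(T_) + shift_bins, T_)
    shifted[is_neural, ] <- courses[is_neural, idx, drop = FALSE]
  }
  mx <- apply(shifted, 1, max)
  if (any(mx <= 0)) stop("cannot max-normalize an all-non-positive time course")
  normed <- shifted / mx
  pc <- stats::prcomp(normed, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(components = pc$rotation, variance_explained = ve,
                 projections = pc$x[, 1:2, drop = FALSE], group = group,
                 normalized = normed, center = pc$center),
            class = "dynamics_embedding")
}

#' @export
print.dynamics_embedding <- function(x, ...) {
  cat("Dynamics embedding:", nrow(x$projections), "units;",
      "PC1+PC2 explain",
      sprintf("%.1f%%", 100 * sum(x$variance_explained[1:2])), "of variance\n")
  invisible(x)
}

#' @export
plot.dynamics_embedding <- function(x, ...) {
  grp <- as.factor(x$group)
  graphics::plot(x$projections, col = as.integer(grp), pch = 16,
                 xlab = "PC1", ylab = "PC2", ...)
  if (nlevels(grp) > 1) {
    graphics::legend("topright", legend = levels(grp), col = seq_len(nlevels(grp)),
                     pch = 16, bty = "n")
  }
  invisible(x)
}

# Sutherland-Hodgman clipping of polygon P (n x 2, counter-clockwise) by the
# convex polygon C (counter-clockwise)
clip_polygon <- function(P, C) {
  nC <- nrow(C)
  for (i in seq_len(nC)) {
    if (nrow(P) == 0) return(P)
    a <- C[i, ]; b <- C[i %% nC + 1, ]
    inside <- function(p) (b[1] - a[1]) * (p[2] - a[2]) -
      (b[2] - a[2]) * (p[1] - a[1]) >= -1e-12
    out <- matrix(numeric(0), 0, 2)
    nP <- nrow(P)
    for (j in seq_len(nP)) {
      p <- P[j, ]; q <- P[j %% nP + 1, ]
      pin <- inside(p); qin <- inside(q)
      if (pin) out <- rbind(out, p)
      if (xor(pin, qin)) {
        d <- q - p
        denom <- (b[1] - a[1]) * d[2] - (b[2] - a[2]) * d[1]
        t <- ((b[2] - a[2]) * (p[1] - a[1]) -
                (b[1] - a[1]) * (p[2] - a[2])) / denom
        out <- rbind(out, p + t * d)
      }
    }
    P <- out
  }
  P
}

polygon_area <- function(P) {
  if (is.null(nrow(P)) || nrow(P) < 3) return(0)
  x <- P[, 1]; y <- P[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# counter-clockwise convex hull vertices
hull_ccw <- function(pts) {
  h <- grDevices::chull(pts)            # chull returns clockwise order
  pts[rev(h), , drop = FALSE]
}

#' Convex-hull overlap of two point sets
#'
#' Area of the intersection of the two convex hulls divided by the area of
#' the first set's hull.
#'
#' @param a,b Two-column matrices of points (at least 3 non-collinear each).
#' @return Fraction in `[0, 1]`.
#' @export
convex_hull_overlap <- function(a, b) {
  ha <- hull_ccw(a); hb <- hull_ccw(b)
  if (polygon_area(ha) <= 0 || polygon_area(hb) <= 0) {
    stop("degenerate convex hull (collinear points)")
  }
  inter <- clip_polygon(ha, hb)
  polygon_area(inter) / polygon_area(ha)
}

#' Ridge-regression similarity between unit sets
#'
#' Fits every target neuron's condition x bin response profile (35 rows:
#' 7 texture classes x 5 bins) as a ridge-penalized linear combination of
#' source-unit profiles, and summarizes similarity as the mean Pearson
#' correlation between fitted and actual profiles over target neurons.
#' Source columns are standardized before penalization and the intercept is
#' unpenalized, so the penalty `lambda` is scale-meaningful.
#'
#' @param r_source `conditions x units` source response matrix.
#' @param r_target `conditions x neurons` target response matrix (same rows).
#' @param lambda Ridge penalty (default 0.2).
#' @param label Optional pair label (e.g. `"V1~H2"`).
#' @return List of class `"similarity_result"`: `beta` (units x neurons,
#'   standardized scale), `r` per neuron, `r_mean`, `lambda`, `label`.
#' @export
ridge_similarity <- function(r_source, r_target, lambda = 0.2, label = NULL) {
  r_target <- as.matrix(r_target)
  stopifnot(nrow(r_source) == nrow(r_target), lambda >= 0)
  sds <- apply(r_source, 2, stats::sd)
  keep_src <- sds > 0
  G <- scale(r_source[, keep_src, drop = FALSE])
  p <- ncol(G)
  A <- crossprod(G) + diag(lambda, p)
  tvar <- apply(r_target, 2, stats::sd)
  if (any(tvar == 0)) {
    warning(sum(tvar == 0), " zero-variance target neuron(s) excluded")
  }
  beta <- matrix(NA_real_, p, ncol(r_target))
  r <- rep(NA_real_, ncol(r_target))
  for (j in which(tvar > 0)) {
    y <- r_target[, j]
    bj <- solve(A, crossprod(G, y - mean(y)))
    beta[, j] <- bj
    fit <- drop(G %*% bj) + mean(y)
    r[j] <- stats::cor(fit, y)
  }
  structure(list(beta = beta, r = r, r_mean = mean(r, na.rm = TRUE),
                 lambda = lambda, label = label),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat("Ridge similarity", if (!is.null(x$label)) paste0("(", x$label, ")"),
      ": mean r =", round(x$r_mean, 3), "over", sum(!is.na(x$r)),
      "target neurons (lambda =", x$lambda, ")\n")
  invisible(x)
}

#' Condition x bin response profile matrix
#'
#' Builds the 35-row (7 classes x 5 bins) response matrix used by
#' [ridge_similarity()]: class-mean response per bin, one column per unit.
#'
#' @param responses `n x units x 5` response array (e.g. from
#'   [predict.rfam()]) or a `response_set` (uses trial-averaged rates).
#' @param classes Factor of per-example class labels.
#' @return `(n_classes*5) x units` matrix, rows ordered class-major.
#' @export
profile_matrix <- function(responses, classes) {
  if (inherits(responses, "response_set")) {
    classes <- responses$classes
    responses <- aperm(responses$rates, c(2, 1, 3))  # examples x neurons x bins
  }
  classes <- as.factor(classes)
  K <- nlevels(classes); U <- dim(responses)[2]
  out <- matrix(0, K * 5, U)
  for (k in seq_len(K)) {
    sel <- classes == levels(classes)[k]
    out[(k - 1) * 5 + 1:5, ] <- t(apply(responses[sel, , , drop = FALSE],
                                        c(2, 3), mean))
  }
  rownames(out) <- paste(rep(levels(classes), each = 5), rep(1:5, K), sep = ".")
  out
}

#' Correlation structure between texture and motion/orientation selectivity
#'
#' Pearson correlations, across the units of one layer, between each texture
#' selectivity index (TSI per constrained class) and each motion/orientation
#' index (OSI, SSIt, DSIt, SSIr, DSIr).
#'
#' @param indices Data frame from [selectivity_indices()].
#' @return Matrix (6 TSI classes x available motion/orientation indices).
#' @export
form_motion_correlations <- function(indices) {
  tsi_cols <- grep("^tsi_", names(indices), value = TRUE)
  mot_cols <- intersect(c("osi", "ssi_t", "dsi_t", "ssi_r", "dsi_r"),
                        names(indices))
  if (length(tsi_cols) == 0 || length(mot_cols) == 0) {
    stop("indices must contain TSI and motion/orientation columns")
  }
  out <- matrix(NA_real_, length(tsi_cols), length(mot_cols),
                dimnames = list(sub("^tsi_", "", tsi_cols), mot_cols))
  for (i in seq_along(tsi_cols)) for (j in seq_along(mot_cols)) {
    x <- indices[[tsi_cols[i]]]; y <- indices[[mot_cols[j]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("constant index column: correlation undefined for ",
              tsi_cols[i], " ~ ", mot_cols[j])
    } else {
      out[i, j] <- stats::cor(x, y)
    }
  }
  out
}

#' Swap the target responses of two texture classes
#'
#' Counterfactual control: exchanges the target curves of two classes
#' (default: the three-point black-triangle class and the four-point even
#' class), leaving everything else untouched. Applying the swap twice is the
#' identity.
#'
#' @param targets `K x 5` class-mean curve matrix with class rownames, or a
#'   `target_patterns` object carrying per-example values and `classes`.
#' @param class_a,class_b The classes to exchange.
#' @return Object of the same type with the two classes' targets exchanged.
#' @export
counterfactual_swap <- function(targets, class_a = "black_triangle",
                                class_b = "even") {
  if (is.matrix(targets)) {
    if (!all(c(class_a, class_b) %in% rownames(targets))) {
      stop("both classes must be present in the target rows")
    }
    targets[c(class_a, class_b), ] <- targets[c(class_b, class_a), ]
    return(targets)
  }
  if (inherits(targets, "target_patterns")) {
    cl <- as.character(targets$classes)
    ia <- which(cl == class_a); ib <- which(cl == class_b)
    if (length(ia) == 0 || length(ib) == 0) stop("missing class in targets")
    if (length(ia) != length(ib)) {
      stop("classes must have equal example counts for a condition-wise swap")
    }
    v <- targets$values
    tmp <- v[ia, , drop = FALSE]
    v[ia, ] <- v[ib, , drop = FALSE]
    v[ib, ] <- tmp
    targets$values <- v
    return(targets)
  }
  stop("unsupported target representation")
}
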