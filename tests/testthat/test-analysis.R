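test_that("dynamics PCA recovers planted low-rank temporal structure", {
  # affine family along one temporal pattern: one component carries all
  # centered variance
  base <- c(1, 0.8, 0.6, 0.5, 0.45)
  v <- c(0, 0.2, -0.1, 0.15, -0.2)        # zero at the max position
  a <- seq(-0.5, 0.5, length.out = 20)
  courses <- t(vapply(a, function(ai) base + ai * v, numeric(5)))
  emb <- dynamics_pca(courses, shift_bins = 0)
  expect_gt(emb$variance_explained[1], 1 - 1e-10)

  # two orthogonal patterns: exactly two components
  set.seed(7)
  p1 <- c(1, 0.5, 0.25, 0.12, 0.06); p2 <- c(0.1, 1, 0.4, 0.2, 0.1)
  w <- matrix(runif(60, 0.2, 1), 30, 2)
  courses2 <- w %*% rbind(p1, p2)
  emb2 <- dynamics_pca(courses2, shift_bins = 0)
  expect_gt(sum(emb2$variance_explained[1:2]), 1 - 1e-10)

  # completeness: reconstruction from all components equals the input
  set.seed(8)
  c3 <- matrix(runif(100, 0.1, 1), 20, 5)
  emb3 <- dynamics_pca(c3, shift_bins = 0)
  norm3 <- c3 / apply(c3, 1, max)
  recon <- tcrossprod(scale(norm3, center = emb3$center, scale = FALSE) %*%
                        emb3$components, emb3$components)
  recon <- sweep(recon, 2, emb3$center, "+")
  expect_lt(max(abs(recon - norm3)), 1e-8)

  # variance fractions form a distribution
  expect_equal(sum(emb3$variance_explained), 1, tolerance = 1e-12)

  expect_error(dynamics_pca(matrix(-1, 3, 5), shift_bins = 0), "normalize")
})

test_that("the onset-delay shift applies only to neural courses", {
  courses <- rbind(h = c(0, 1, 0.5, 0.4, 0.3), n = c(0, 1, 0.5, 0.4, 0.3))
  emb <- dynamics_pca(list(H1 = courses[1, , drop = FALSE],
                           V1 = courses[2, , drop = FALSE]),
                      neural = "V1", shift_bins = 1)
  # shifted neural course differs from the unshifted model course
  expect_false(isTRUE(all.equal(emb$normalized[1, ], emb$normalized[2, ])))
  expect_equal(unname(emb$normalized[2, ]), c(1, 0.5, 0.4, 0.3, 0.3))
})

test_that("convex hull overlap matches geometry oracles", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(convex_hull_overlap(sq, sq), 1)
  far <- sq + 10
  expect_equal(convex_hull_overlap(sq, far), 0)
  half <- cbind(c(0.5, 1.5, 1.5, 0.5), c(0, 0, 1, 1))
  expect_equal(convex_hull_overlap(sq, half), 0.5, tolerance = 1e-10)

  expect_error(convex_hull_overlap(cbind(0:2, 0:2), sq), "degenerate")

  # rejection-sampling oracle on random point clouds
  set.seed(9)
  for (i in 1:3) {
    a <- matrix(rnorm(40), 20, 2)
    b <- matrix(rnorm(40, mean = 0.5), 20, 2)
    got <- convex_hull_overlap(a, b)
    ha <- a[grDevices::chull(a), ]; hb <- b[grDevices::chull(b), ]
    inpoly <- function(P, pts) {
      # point-in-convex-polygon by sign of cross products (ccw or cw)
      n <- nrow(P)
      s <- sapply(seq_len(n), function(k) {
        p1 <- P[k, ]; p2 <- P[k %% n + 1, ]
        (p2[1] - p1[1]) * (pts[, 2] - p1[2]) -
          (p2[2] - p1[2]) * (pts[, 1] - p1[1])
      })
      apply(s >= -1e-12, 1, all) | apply(s <= 1e-12, 1, all)
    }
    box <- cbind(runif(200000, min(a[, 1]), max(a[, 1])),
                 runif(200000, min(a[, 2]), max(a[, 2])))
    area_box <- diff(range(a[, 1])) * diff(range(a[, 2]))
    in_a <- inpoly(ha, box)
    mc <- mean(in_a & inpoly(hb, box)) / mean(in_a)
    expect_equal(got, mc, tolerance = 0.02)
  }
})

test_that("ridge similarity equals the closed form and its limits", {
  set.seed(10)
  G <- matrix(rnorm(35 * 10), 35, 10)
  B <- matrix(rnorm(10 * 4), 10, 4)
  Y <- G %*% B

  # realizable targets at small lambda: near-perfect fit
  fit <- ridge_similarity(G, Y, lambda = 1e-8)
  expect_gt(fit$r_mean, 0.99)

  # closed form via an independent augmented least-squares solve
  lam <- 0.2
  fit2 <- ridge_similarity(G, Y, lambda = lam)
  Gs <- scale(G)
  for (j in 1:4) {
    y <- Y[, j] - mean(Y[, j])
    aug_X <- rbind(Gs, sqrt(lam) * diag(10))
    aug_y <- c(y, rep(0, 10))
    oracle <- stats::lsfit(aug_X, aug_y, intercept = FALSE)$coefficients
    expect_lt(max(abs(fit2$beta[, j] - oracle)), 1e-6)
  }

  # lambda -> 0 coincides with OLS
  fit0 <- ridge_similarity(G, Y[, 1, drop = FALSE], lambda = 1e-10)
  ols <- stats::lm.fit(cbind(1, Gs), Y[, 1])$coefficients[-1]
  expect_lt(max(abs(fit0$beta[, 1] - ols)), 1e-6)

  # zero-variance target excluded with a warning
  Y2 <- cbind(Y[, 1], 5)
  expect_warning(fit3 <- ridge_similarity(G, Y2, lambda = 0.2), "zero-variance")
  expect_true(is.na(fit3$r[2]))
})

test_that("form-motion correlation tables behave like correlations", {
  set.seed(11)
  n <- 1000
  idx <- data.frame(tsi_even = rnorm(n), tsi_odd = rnorm(n),
                    osi = rnorm(n), ssi_t = rnorm(n))
  idx$dsi_t <- idx$tsi_even          # planted perfect correlation
  fm <- form_motion_correlations(idx)
  expect_equal(fm["even", "dsi_t"], 1)
  expect_lt(abs(fm["even", "osi"]), 0.1)
  expect_lt(abs(fm["odd", "ssi_t"]), 0.1)

  # sign flip of one index column negates its row
  idx2 <- idx; idx2$tsi_even <- -idx2$tsi_even
  fm2 <- form_motion_correlations(idx2)
  expect_equal(fm2["even", ], -fm["even", ])

  idx3 <- idx; idx3$ssi_t <- 0
  ws <- testthat::capture_warnings(fm3 <- form_motion_correlations(idx3))
  expect_true(any(grepl("constant", ws)))
  expect_true(all(is.na(fm3[, "ssi_t"])))
})

test_that("counterfactual target swap is an exact class exchange", {
  cm <- toy_class_curves()
  sw <- counterfactual_swap(cm)
  expect_equal(sw["even", ], cm["black_triangle", ])
  expect_equal(sw["black_triangle", ], cm["even", ])
  expect_equal(sw["random", ], cm["random", ])
  expect_equal(counterfactual_swap(sw), cm)
  expect_equal(sort(c(sw)), sort(c(cm)))
  expect_error(counterfactual_swap(cm[1:3, ]), "present")

  # per-example form
  tp <- structure(list(values = matrix(1:70, 14, 5),
                       classes = factor(rep(c("black_triangle", "even"),
                                            each = 7))),
                  class = "target_patterns")
  sw2 <- counterfactual_swap(tp)
  expect_equal(sw2$values[1:7, ], tp$values[8:14, ])
  expect_equal(counterfactual_swap(sw2)$values, tp$values)
})

test_that("profile matrices stack class-by-bin means per unit", {
  set.seed(12)
  resp <- array(runif(6 * 3 * 5), c(6, 3, 5))
  cls <- factor(rep(c("a", "b"), each = 3))
  pm <- profile_matrix(resp, cls)
  expect_equal(dim(pm), c(10, 3))
  expect_equal(unname(pm[1, 2]), mean(resp[1:3, 2, 1]))
  expect_equal(unname(pm[10, 3]), mean(resp[4:6, 3, 5]))
})
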