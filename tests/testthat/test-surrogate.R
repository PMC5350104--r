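test_that("expected counts follow the generative definition", {
  tx <- generate_texture("random", seed = 1)
  n0 <- surrogate_neuron(baseline_rate = 50, class_gains = c(even = 0),
                         transient_amp = 0.6, tau = 1.2,
                         example_sensitivity = 0)
  mu <- simulate_response(n0, tx, expected = TRUE)
  k <- 0.6 * exp(-(0:4) / 1.2) + 0.4
  expect_equal(mu, 50 * k * 0.04, tolerance = 1e-12)

  # fully transient kernel decays monotonically
  ntr <- surrogate_neuron(baseline_rate = 40, transient_amp = 1, tau = 1,
                          example_sensitivity = 0)
  mutr <- simulate_response(ntr, tx, expected = TRUE)
  expect_lt(mutr[5], mutr[1])
  expect_true(all(diff(mutr) < 0))
})

test_that("class gains raise the expected response of the preferred class", {
  ne <- surrogate_neuron(baseline_rate = 30, class_gains = c(even = 0.8),
                         example_sensitivity = 0, transient_amp = 0)
  te <- generate_texture("even", seed = 2)
  tr <- generate_texture("random", seed = 2)
  expect_equal(sum(simulate_response(ne, te, expected = TRUE)) /
                 sum(simulate_response(ne, tr, expected = TRUE)), 1.8,
               tolerance = 1e-9)
})

test_that("Poisson counts match the closed-form mean over many repeats", {
  ts <- make_texture_set(1, seed = 5, classes = "even")
  pop <- list(surrogate_neuron(baseline_rate = 60, class_gains = c(even = 0.4),
                               transient_amp = 0.5, tau = 1, id = "n1"))
  class(pop) <- "surrogate_population"
  rs <- simulate_responses(pop, ts, n_repeats = 10000, seed = 9,
                           shared_gain_sd = 0)
  mu <- rs$expected[1, 1, ] * 0.04
  emp <- apply(rs$counts[1, 1, , ], 1, mean)
  se <- sqrt(mu / 10000)
  expect_true(all(abs(emp - mu) < 3 * se))
})

test_that("responses are deterministic given (neuron, texture, repeat seed)", {
  tx <- generate_texture("odd", seed = 3)
  nn <- surrogate_neuron(id = "det")
  expect_identical(simulate_response(nn, tx, repeat_seed = 4),
                   simulate_response(nn, tx, repeat_seed = 4))
  expect_false(identical(simulate_response(nn, tx, repeat_seed = 4),
                         simulate_response(nn, tx, repeat_seed = 5)))
})

test_that("population generation respects counts, labels, and gain ordering", {
  pop <- make_population(c(V1.gran = 20, V2.supra = 10), seed = 4)
  expect_length(pop, 30)
  labs <- vapply(pop, function(x) paste(x$area, x$layer), character(1))
  expect_equal(sum(labs == "V1 gran"), 20)
  expect_equal(sum(labs == "V2 supra"), 10)

  pop2 <- make_population(c(V1.gran = 20, V2.supra = 10), seed = 4)
  expect_identical(pop, pop2)

  big <- make_population(c(V1.gran = 1000, V2.supra = 1000), seed = 5)
  g <- t(vapply(big, function(x) x$class_gains, numeric(6)))
  is_v2s <- vapply(big, function(x) x$layer == "supra", logical(1))
  expect_gt(mean(abs(g[is_v2s, ])), mean(abs(g[!is_v2s, ])))
  # even-preferring on average in V2 supragranular
  expect_gt(mean(g[is_v2s, "even"]), 0.2)
})

test_that("target normalization is a shared affine map attaining [0, 1]", {
  tp <- normalize_targets(c(2, 6, 10))
  expect_equal(tp$values, c(0, 0.5, 1))
  expect_error(normalize_targets(rep(3, 5)), "degenerate")

  set.seed(1)
  r <- matrix(rexp(40), 8, 5)
  tp2 <- normalize_targets(r)
  expect_equal(range(tp2$values), c(0, 1))
  # monotone transform: rank order within any row unchanged
  expect_equal(order(tp2$values[3, ]), order(r[3, ]))
})

test_that("population average reduces to the obvious special cases", {
  ts <- make_texture_set(4, seed = 6)
  pop <- make_population(c(V2.supra = 3), seed = 7)
  rs <- simulate_responses(pop, ts, n_repeats = 2, seed = 8)

  one <- population_average(rs, subset = 2)
  direct <- normalize_targets(rs$rates[2, , ])
  expect_equal(one$values, direct$values)

  # exact cancellation: two responders r and -r + const average to a constant,
  # which normalize_targets rejects as degenerate
  fake <- rs
  fake$rates <- array(0, c(2, dim(rs$rates)[2], 5))
  fake$rates[1, , ] <- rs$rates[1, , ]
  fake$rates[2, , ] <- max(rs$rates[1, , ]) - rs$rates[1, , ]
  expect_error(population_average(fake, subset = 1:2), "degenerate")
})

test_that("the default V2 supragranular average prefers even textures", {
  ts <- make_texture_set(64, seed = 20)
  pop <- make_population(c(V2.supra = 32), seed = 21)
  rs <- simulate_responses(pop, ts, n_repeats = 2, seed = 22)
  cm <- class_mean_targets(population_average(rs))
  curve <- rowMeans(cm)
  expect_equal(names(which.max(curve)), "even")
})

test_that("consistency behaves as a split-half correlation should", {
  classes <- factor(rep(texture_classes(), each = 40))
  # deterministic class-coded response: identical halves, consistency 1
  resp <- as.integer(classes) * 1.0
  expect_equal(consistency(resp, classes, n_splits = 50, seed = 1), 1)

  # class-independent noise: consistency near 0 on average over datasets
  set.seed(2)
  null_vals <- vapply(1:20, function(i) {
    consistency(rnorm(length(classes)), classes, n_splits = 100, seed = i)
  }, numeric(1))
  se <- stats::sd(null_vals) / sqrt(length(null_vals))
  expect_lt(abs(mean(null_vals)), 3 * se + 0.05)

  # invariant to affine rescaling of the response
  mixed <- resp + rnorm(length(classes), sd = 2)
  c1 <- consistency(mixed, classes, n_splits = 200, seed = 3)
  c2 <- consistency(5 * mixed + 3, classes, n_splits = 200, seed = 3)
  expect_equal(c1, c2, tolerance = 1e-12)

  expect_error(consistency(1:3, factor(c("a", "a", "b"))), "at least 2")
})

test_that("the default V2pa surrogate has high split-half consistency at scale", {
  ts <- make_texture_set(1024, seed = 50)
  pop <- make_population(c(V2.supra = 32), seed = 51)
  rs <- simulate_responses(pop, ts, n_repeats = 2, seed = 52)
  pa <- population_average(rs)
  cons <- consistency(rowMeans(pa$values), pa$classes, n_splits = 1000,
                      seed = 53)
  expect_gt(cons, 0.8)
})
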