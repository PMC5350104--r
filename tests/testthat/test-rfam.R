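test_that("Nguyen-Widrow initialization has the stated geometry", {
  p <- rfam_init(n_in = 256, n1 = 100, n2 = 100, n_out = 123, seed = 1)
  beta1 <- 0.7 * 100^(1 / (256 + 100))
  norms1 <- sqrt(rowSums(cbind(p$w_in, p$w_h1h1)^2))
  expect_true(all(abs(norms1 - beta1) < 1e-10))
  beta2 <- 0.7 * 100^(1 / (100 + 100))
  norms2 <- sqrt(rowSums(cbind(p$w_h1h2, p$w_h2h2)^2))
  expect_true(all(abs(norms2 - beta2) < 1e-10))
  expect_true(all(abs(p$b1) <= beta1 + 1e-12))

  expect_identical(rfam_init(6, 4, 3, 2, seed = 9),
                   rfam_init(6, 4, 3, 2, seed = 9))
})

test_that("the published architecture has 68,223 trainable parameters", {
  p <- rfam_init(n_in = 256, n1 = 100, n2 = 100, n_out = 123, seed = 2)
  # independent shape walk
  shapes <- vapply(p, function(w) length(as.numeric(w)), numeric(1))
  expect_equal(sum(shapes), 68223)
  expect_equal(n_params(p), 68223)
  expect_gt(n_params(p), 20000)
})

test_that("forward dynamics obey the unit equation and reset rule", {
  # all weights and biases zero: every unit outputs sigmoid(0) = 0.5
  p <- tiny_params()
  for (nm in names(p)) p[[nm]][] <- 0
  fw <- rfam_forward(p, runif(6))
  expect_true(all(abs(fw$h1 - 0.5) < 1e-15))
  expect_true(all(abs(fw$out - 0.5) < 1e-15))

  # single-unit chain with weight 1, bias 0 on input 1
  p1 <- rfam_init(1, 1, 1, 1, seed = 1)
  p1$w_in[] <- 1; p1$w_h1h1[] <- 0; p1$b1[] <- 0
  p1$w_h1h2[] <- 1; p1$w_h2h2[] <- 0; p1$b2[] <- 0
  p1$w_out[] <- 1; p1$b_out[] <- 0
  fw1 <- rfam_forward(p1, matrix(1, 1, 1))
  expect_equal(fw1$h1[1, 1, 1], 1 / (1 + exp(-1)), tolerance = 1e-12)

  # step-1 hidden activations are independent of recurrent weights
  pa <- tiny_params(seed = 5)
  pb <- pa
  pb$w_h1h1 <- pb$w_h1h1 * -3
  pb$w_h2h2 <- pb$w_h2h2 * 10
  s <- runif(6)
  fa <- rfam_forward(pa, s); fb <- rfam_forward(pb, s)
  expect_equal(fa$h1[, , 1], fb$h1[, , 1], tolerance = 1e-12)
})

test_that("BPTT gradients match central finite differences in every group", {
  set.seed(11)
  ps <- rfam_init(n_in = 5, n1 = 4, n2 = 3, n_out = 2, seed = 31)
  s <- runif(5)
  tgt <- matrix(runif(10), 2, 5)
  gr <- bptt_gradients(ps, s, tgt)
  eps <- 1e-6
  worst_rel <- 0; worst_abs <- 0
  for (nm in names(ps)) {
    for (i in seq_along(ps[[nm]])) {
      pp <- ps; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- ps; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (attr(bptt_gradients(pp, s, tgt), "error") -
                attr(bptt_gradients(pm, s, tgt), "error")) / (2 * eps)
      a <- gr[[nm]][i]
      if (abs(a) + abs(num) > 1e-4) {
        worst_rel <- max(worst_rel, rel_err(num, a))
      } else {
        # below the resolution of central differences, compare absolutely
        worst_abs <- max(worst_abs, abs(num - a))
      }
    }
  }
  expect_lt(worst_rel, 1e-6)
  expect_lt(worst_abs, 1e-8)
})

test_that("gradients vanish when the output equals the target", {
  ps <- tiny_params(seed = 13)
  s <- runif(6)
  fw <- rfam_forward(ps, s)
  tgt <- matrix(fw$out[1, , ], 2, 5)
  gr <- bptt_gradients(ps, s, tgt)
  expect_equal(attr(gr, "error"), 0)
  for (nm in names(ps)) expect_true(all(gr[[nm]] == 0))
})

test_that("the compiled trainer reproduces the reference update exactly", {
  ps <- tiny_params(seed = 17)
  set.seed(18)
  X <- matrix(runif(4 * 6), 4, 6)
  TG <- matrix(runif(4 * 10), 4, 10)
  res <- cpp_rfam_sgd(unclass(ps), X, TG, 1L, 0.07, 0, integer(0), 0L, 0)
  gr <- bptt_gradients(ps, X[2, ], matrix(TG[2, ], 2, 5))
  for (nm in names(ps)) {
    expect_equal(unname(as.numeric(res[[nm]])),
                 unname(as.numeric(ps[[nm]] - 0.07 * gr[[nm]])),
                 tolerance = 1e-14, label = nm)
  }
})

test_that("training is a no-op at learning rate zero and overfits one pattern", {
  set.seed(19)
  X <- matrix(runif(6), 1, 6)
  TG <- matrix(runif(10), 1, 10)
  f0 <- rfam(X, TG, epochs = 500, n1 = 4, n2 = 4, learning_rate = 0,
             momentum = 0, seed = 1)
  expect_equal(f0$params$w_in, f0$init$w_in, tolerance = 1e-14)

  f1 <- rfam(X, TG, epochs = 10000, n1 = 10, n2 = 10, learning_rate = 0.3,
             momentum = 0, seed = 2)
  expect_lt(utils::tail(f1$trace$error, 1), 1e-3)
})

test_that("the error trace declines on a learnable class-coded target", {
  ts <- make_texture_set(10, seed = 23)
  fit <- rfam(ts, toy_class_curves(), epochs = 20000, n1 = 8, n2 = 8,
              seed = 3)
  expect_lt(utils::tail(fit$trace$error, 1), 0.5 * fit$trace$error[1])
})

test_that("fits are reproducible and the S3 surface is coherent", {
  ts <- make_texture_set(6, seed = 29)
  f1 <- rfam(ts, toy_class_curves(), epochs = 300, n1 = 5, n2 = 5, seed = 4)
  f2 <- rfam(ts, toy_class_curves(), epochs = 300, n1 = 5, n2 = 5, seed = 4)
  expect_identical(f1$params, f2$params)

  expect_equal(n_params(coef(f1)), n_params(f1))
  pr <- predict(f1, ts)
  expect_equal(dim(pr), c(42, 1, 5))
  expect_true(all(pr > 0 & pr < 1))
  pr_avg <- predict(f1, ts, average_time = TRUE)
  expect_equal(pr_avg[3, 1], mean(pr[3, 1, ]))
  h1 <- predict(f1, ts, type = "hidden1", average_time = TRUE)
  expect_equal(dim(h1), c(42, 5))
  res <- residuals(f1)
  expect_equal(dim(res), dim(fitted(f1)))
  expect_output(print(f1), "Recurrent form analysis model")
  expect_output(print(summary(f1)), "probe error")
})

test_that("probes and new data pass through the stored input map", {
  ts <- make_texture_set(6, seed = 31)
  fit <- rfam(ts, toy_class_curves(), epochs = 100, n1 = 4, n2 = 4, seed = 5)
  # predicting the training stimuli via newdata must agree with the stored path
  X <- stimulus_matrix(ts$grids)
  expect_equal(predict(fit), predict(fit, X), tolerance = 1e-12)
})

test_that("tuning evaluation reduces to rank correlation of class means", {
  cls <- factor(rep(letters[1:7], each = 3))
  x <- rep(1:7, each = 3)
  expect_equal(evaluate_tuning(x, x, cls), 1)
  expect_equal(evaluate_tuning(x, -x, cls), -1)
  expect_warning(r <- evaluate_tuning(rep(1, 21), x, cls), "constant")
  expect_true(is.na(r))
})
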