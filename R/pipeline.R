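#' Default pipeline configuration
#'
#' Scaled desk defaults for the full modeling chain: stimulus synthesis,
#' surrogate population, population-average targets, feedforward baseline,
#' recurrent-network training, probing, and population analyses. The
#' published-scale experiment (1024 examples/class, 100+100 hidden units,
#' five million epochs) is reachable by overriding the corresponding fields.
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @param ... Overrides of the default fields.
#' @return Named list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    n_train = 1024,         # examples per class, training set
    n_test = 1000,          # fresh examples per class, generalization set
    population = c(V1.supra = 8, V1.gran = 8, V1.infra = 8,
                   V2.supra = 32, V2.gran = 8, V2.infra = 8),
    n_repeats = 2,
    n1 = 30, n2 = 30,
    epochs = 1e6,
    learning_rate = 0.15,
    momentum = 0.9,
    weight_decay = 1e-5,
    ln_filters = 8,
    probe_examples = 1000,
    counterfactual = TRUE,
    run_ln = TRUE, run_probes = TRUE, run_dynamics = TRUE,
    run_similarity = TRUE,
    out_dir = NULL)
  ov <- list(...)
  cfg[names(ov)] <- ov
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full modeling pipeline
#'
#' Executes, in order: texture synthesis (train and generalization sets),
#' surrogate-population simulation, population-average target construction,
#' the feedforward linear-nonlinear baseline (train and test tuning
#' performance), recurrent-network training and evaluation, hidden-unit
#' probing (selectivity indices and form-motion correlation structure),
#' response-dynamics PCA with convex-hull overlap, ridge similarity between
#' hidden layers and surrogate areas, and the swapped-target counterfactual
#' control. Every random draw derives from the master seed.
#'
#' @param config A [pipeline_config()].
#' @return Nested list of class `"pipeline_report"` with per-stage results;
#'   written as JSON to `file.path(out_dir, "report.json")` when `out_dir`
#'   is set.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  seed <- config$seed
  report <- list(config = config[setdiff(names(config), "out_dir")])

  ts_train <- make_texture_set(config$n_train, seed = derive_seed(seed, "train"))
  ts_test <- make_texture_set(config$n_test, seed = derive_seed(seed, "test"))

  pop <- make_population(config$population, seed = derive_seed(seed, "pop"))
  rs <- simulate_responses(pop, ts_train, n_repeats = config$n_repeats,
                           seed = derive_seed(seed, "resp"))
  pa <- population_average(rs)
  cm <- class_mean_targets(pa)
  tgt_curve <- rowMeans(cm)
  report$targets <- list(
    class_curves = cm,
    consistency = consistency(rowMeans(pa$values), pa$classes,
                              n_splits = 1000,
                              seed = derive_seed(seed, "cons")))

  if (isTRUE(config$run_ln)) {
    X_tr <- stimulus_matrix(ts_train$grids)
    v2pa_rates <- rowMeans(pa$values)
    ln <- ln_istac(X_tr, v2pa_rates, n_filters = config$ln_filters)
    pr_tr <- predict(ln, X_tr)
    pr_te <- predict(ln, ts_test)
    report$ln <- list(
      info = ln$info,
      train_r = evaluate_tuning(pr_tr, v2pa_rates, ts_train$classes,
                                method = "spearman"),
      test_r = stats::cor(tapply(pr_te, ts_test$classes, mean), tgt_curve,
                          method = "spearman"))
  }

  fit <- rfam(ts_train, cm, n1 = config$n1, n2 = config$n2,
              epochs = config$epochs, learning_rate = config$learning_rate,
              momentum = config$momentum, weight_decay = config$weight_decay,
              seed = derive_seed(seed, "net"))
  pr_tr <- rowMeans(predict(fit, average_time = TRUE))
  pr_te <- rowMeans(predict(fit, ts_test, average_time = TRUE))
  report$rfam <- list(
    final_error = utils::tail(fit$trace$error, 1),
    train_r = stats::cor(tapply(pr_tr, ts_train$classes, mean), tgt_curve),
    test_r = stats::cor(tapply(pr_te, ts_test$classes, mean), tgt_curve))

  if (isTRUE(config$run_probes)) {
    idx1 <- selectivity_indices(fit, "hidden1", config$probe_examples,
                                seed = derive_seed(seed, "probe1"))
    idx2 <- selectivity_indices(fit, "hidden2", config$probe_examples,
                                seed = derive_seed(seed, "probe2"))
    report$indices <- list(h1 = idx1, h2 = idx2)
    report$form_motion <- list(h1 = form_motion_correlations(idx1),
                               h2 = form_motion_correlations(idx2))
  }

  if (isTRUE(config$run_dynamics)) {
    courses <- list(
      H1 = time_courses(fit, ts_train, layer = "hidden1"),
      H2 = time_courses(fit, ts_train, layer = "hidden2"))
    areas <- unique(vapply(pop, function(nn) nn$area, character(1)))
    for (ar in areas) {
      sel <- vapply(pop, function(nn) nn$area == ar, logical(1))
      courses[[ar]] <- apply(rs$rates[sel, , , drop = FALSE], c(1, 3), mean)
    }
    emb <- dynamics_pca(courses, neural = areas, shift_bins = 1)
    report$dynamics <- list(
      variance_explained = emb$variance_explained,
      pc12 = sum(emb$variance_explained[1:2]))
    hull <- try({
      h12 <- emb$projections[emb$group %in% c("H1", "H2"), ]
      vapply(intersect(areas, c("V1", "V2")), function(ar)
        convex_hull_overlap(emb$projections[emb$group == ar, ], h12),
        numeric(1))
    }, silent = TRUE)
    if (!inherits(hull, "try-error")) report$dynamics$hull_overlap <- hull
    report$embedding <- emb
  }

  if (isTRUE(config$run_similarity)) {
    prof_h1 <- profile_matrix(predict(fit, ts_train, type = "hidden1"),
                              ts_train$classes)
    prof_h2 <- profile_matrix(predict(fit, ts_train, type = "hidden2"),
                              ts_train$classes)
    sim <- list()
    for (ar in c("V1", "V2")) {
      sel <- vapply(pop, function(nn) nn$area == ar, logical(1))
      if (!any(sel)) next
      prof_n <- profile_matrix(
        aperm(rs$rates[sel, , , drop = FALSE], c(2, 1, 3)), ts_train$classes)
      sim[[paste0(ar, "~H1")]] <- ridge_similarity(prof_h1, prof_n,
                                                   label = paste0(ar, "~H1"))$r_mean
      sim[[paste0(ar, "~H2")]] <- ridge_similarity(prof_h2, prof_n,
                                                   label = paste0(ar, "~H2"))$r_mean
    }
    report$similarity <- sim
  }

  if (isTRUE(config$counterfactual)) {
    cm_swap <- counterfactual_swap(cm)
    fit_sw <- rfam(ts_train, cm_swap, n1 = config$n1, n2 = config$n2,
                   epochs = config$epochs,
                   learning_rate = config$learning_rate,
                   momentum = config$momentum,
                   weight_decay = config$weight_decay,
                   seed = derive_seed(seed, "swapnet"))
    res <- list(
      test_r = stats::cor(
        tapply(rowMeans(predict(fit_sw, ts_test, average_time = TRUE)),
               ts_test$classes, mean),
        rowMeans(cm_swap)))
    if (isTRUE(config$run_probes)) {
      i1 <- selectivity_indices(fit_sw, "hidden1", config$probe_examples,
                                seed = derive_seed(seed, "probe1"))
      i2 <- selectivity_indices(fit_sw, "hidden2", config$probe_examples,
                                seed = derive_seed(seed, "probe2"))
      res$form_motion <- list(h1 = form_motion_correlations(i1),
                              h2 = form_motion_correlations(i2))
      res$max_abs_r <- max(abs(res$form_motion$h1), abs(res$form_motion$h2),
                           na.rm = TRUE)
    }
    report$counterfactual <- res
  }

  class(report) <- "pipeline_report"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    json <- report
    json$embedding <- NULL
    jsonlite::write_json(json, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report\n")
  cat("  target consistency:", round(x$targets$consistency, 3), "\n")
  if (!is.null(x$ln)) {
    cat("  LN baseline tuning r: train", round(x$ln$train_r, 3),
        "test", round(x$ln$test_r, 3), "\n")
  }
  cat("  recurrent model tuning r: train", round(x$rfam$train_r, 3),
      "test", round(x$rfam$test_r, 3), "\n")
  if (!is.null(x$form_motion)) {
    cat("  TSI_even ~ SSIt: H1",
        round(x$form_motion$h1["even", "ssi_t"], 3), "H2",
        round(x$form_motion$h2["even", "ssi_t"], 3), "\n")
  }
  if (!is.null(x$counterfactual$max_abs_r)) {
    cat("  counterfactual max |r|:", round(x$counterfactual$max_abs_r, 3), "\n")
  }
  invisible(x)
}
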