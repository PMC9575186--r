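test_that("the classifier fits separable data and is seed-deterministic", {
  blobs <- make_blobs(n_per_class = 25, delta = 5, seed = 1)
  X <- t(blobs$expression$values)
  fit <- train_classifier(X, blobs$labels, seed = 3)
  expect_equal(mean(as.character(predict(fit, X)) ==
                      blobs$labels$labels[rownames(X)]), 1)
  fit2 <- train_classifier(X, blobs$labels, seed = 3)
  expect_identical(as.character(predict(fit2, X)),
                   as.character(predict(fit, X)))
  one_class <- setNames(rep("A", nrow(X)), rownames(X))
  expect_error(train_classifier(X, one_class), "single class")
})

test_that("cross-validated accuracy behaves at both extremes", {
  blobs <- make_blobs(n_per_class = 25, delta = 5, seed = 2)
  X <- t(blobs$expression$values)
  expect_equal(cv_accuracy(X, blobs$labels, seed = 1), 1)
  expect_equal(cv_accuracy(X, blobs$labels, seed = 7), 1)

  null <- make_blobs(n_per_class = 100, delta = 0, seed = 5)
  Xn <- t(null$expression$values)
  for (s in c(1, 2, 3)) {
    acc <- cv_accuracy(Xn, null$labels, seed = s)
    expect_gte(acc, 0.35); expect_lte(acc, 0.65)
  }
  tiny <- make_blobs(n_per_class = 3, delta = 1, seed = 1)
  expect_error(cv_accuracy(t(tiny$expression$values), tiny$labels),
               "5-fold CV")
})

test_that("the signature-by-cohort grid has the announced cardinality", {
  configs <- lapply(2:5, function(k)
    simulation_config(samples_per_cohort = 60, k = k,
                      n_signature_genes_per_class = 6,
                      n_background_genes = 60, batch_shift_sd = 0.5,
                      contamination_range = c(0, 0.2), seed = k))
  bat <- simulate_battery(configs, seed = 8)
  pp <- preprocess_cohorts(lapply(bat$cohorts, `[[`, "expression"))
  cohorts <- lapply(seq_along(pp), function(i)
    list(expression = pp[[i]], labels = bat$cohorts[[i]]$labels))
  names(cohorts) <- names(bat$cohorts)
  grid <- build_model_grid(bat$signatures, cohorts, seed = 1)
  expect_length(grid$models, 16)
  expect_equal(nrow(grid$failures), 0)
  accs <- vapply(grid$models, `[[`, numeric(1), "cv_accuracy")
  expect_true(all(accs >= 0 & accs <= 1))

  single <- build_model_grid(bat$signatures[1], cohorts[1], seed = 1)
  expect_length(single$models, 1)

  # zero-overlap signature: its cells fail, the rest of the grid proceeds
  ghost <- gene_signature("ghost", c("NOPE1", "NOPE2"))
  mixed <- build_model_grid(list(sig1 = bat$signatures$sig1, ghost = ghost),
                            cohorts[1:2], seed = 1)
  expect_length(mixed$models, 2)
  expect_equal(nrow(mixed$failures), 2)
  expect_match(mixed$failures$reason[1], "no overlap")
  expect_error(build_model_grid(bat$signatures,
                                list(c1 = list(expression = pp[[1]]))),
               "truth labels")
})

test_that("external prediction is consistent and order-invariant", {
  cfg <- simulation_config(n_cohorts = 2, samples_per_cohort = 80, k = 2,
                           effect_size = 3, n_background_genes = 100,
                           contamination_range = c(0, 0.2), seed = 3)
  sim <- simulate_cohorts(cfg)
  pp <- preprocess_cohorts(lapply(sim$cohorts, `[[`, "expression"))
  cohorts <- list(c1 = list(expression = pp[[1]],
                            labels = sim$cohorts[[1]]$labels))
  grid <- build_model_grid(list(planted = sim$signature), cohorts, seed = 2)
  model <- grid$models[[1]]

  # in-sample sanity: accuracy on the training cohort within 0.1 of CV
  pred_train <- predict_external(model, pp[[1]])
  acc <- mean(pred_train$labels == sim$cohorts[[1]]$labels$labels[names(pred_train$labels)])
  expect_gte(acc, model$cv_accuracy - 0.1)

  pred2 <- predict_external(model, pp[[2]])
  expect_equal(pred2$origin, "predicted")
  expect_setequal(names(pred2$labels), samples(pp[[2]]))

  # sample order does not change predictions
  shuffled <- expression_matrix(pp[[2]]$values[, rev(samples(pp[[2]]))],
                                "rev", "synthetic")
  pred_rev <- predict_external(model, shuffled)
  expect_identical(pred_rev$labels[names(pred2$labels)], pred2$labels)

  one <- expression_matrix(pp[[2]]$values[, 1, drop = FALSE], "one", "synthetic")
  expect_length(predict_external(model, one)$labels, 1)

  missing <- expression_matrix(pp[[2]]$values[-1, , drop = FALSE],
                               "missing", "synthetic")
  expect_error(predict_external(model,
                                restrict_genes(missing,
                                               setdiff(genes(missing),
                                                       model$feature_genes[1]))),
               "missing feature gene")
})

test_that("cross-scheme confusion conserves the sample count", {
  ids <- sprintf("s%d", 1:40)
  a <- subtype_labels(setNames(rep(c("basal", "classical"), 20), ids),
                      subtype_scheme(c("basal", "classical")), "predicted")
  b <- subtype_labels(setNames(rep(c("sq", "im", "pp", "adex"), 10), ids),
                      subtype_scheme(c("sq", "im", "pp", "adex")), "predicted")
  tab <- cross_scheme_confusion(a, b)
  expect_equal(sum(tab), 40)
  expect_equal(dim(tab), c(2L, 4L))

  same <- cross_scheme_confusion(a, a)
  expect_equal(sum(diag(same)), 40)

  b_short <- subtype_labels(setNames(rep("sq", 10), ids[1:10]),
                            subtype_scheme(c("sq", "im")), "predicted")
  expect_error(cross_scheme_confusion(a, b_short), "different samples")
})
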