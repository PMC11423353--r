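test_that("a 60:40 split of 1,057 items gives 634 train and 423 test", {
  labels <- stats::setNames(rep(c("lytic", "temperate"), length.out = 1057),
                            sprintf("p%04d", 1:1057))
  sp <- split_dataset(labels, train_fraction = 0.6, seed = 1)
  expect_length(sp$train, 634L)
  expect_length(sp$test, 423L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), names(labels))
})

test_that("split is seed-deterministic and floor-sized for all n", {
  labels <- stats::setNames(rep(c("lytic", "temperate"), 50), sprintf("p%03d", 1:100))
  s1 <- split_dataset(labels, seed = 7)
  s2 <- split_dataset(labels, seed = 7)
  expect_identical(s1, s2)
  s3 <- split_dataset(labels, seed = 8)
  expect_false(identical(s1$train, s3$train))
  expect_length(s3$train, length(s1$train))

  # exhaustive size law over n = 2..1100
  ns <- 2:1100
  sizes <- vapply(ns, function(n) {
    lab <- stats::setNames(rep(c("lytic", "temperate"), length.out = n),
                           sprintf("q%04d", 1:n))
    length(split_dataset(lab, seed = 1)$train)
  }, numeric(1))
  expect_equal(sizes, floor(0.6 * ns))

  expect_error(split_dataset(c(a = "lytic"), seed = 1),
               class = "phagetools_parameter_error")
  expect_error(split_dataset(labels, train_fraction = 1, seed = 1),
               class = "phagetools_parameter_error")
})

sim_separable <- implant_domains(n_per_class = 100, genome_length = 3000, seed = 11)
features_sep <- build_feature_matrix(sim_separable$genomes, sim_separable$domains)

test_that("separable fixture trains to zero held-out error", {
  sp <- split_dataset(sim_separable$labels, seed = 11)
  model <- train_lifestyle_model(features_sep[sp$train, ], sim_separable$labels,
                                 seed = 11, domains = sim_separable$domains)
  err <- evaluate_lifestyle(model, features_sep[sp$test, ], sim_separable$labels)
  expect_equal(err, 0)
  # and the implanted marker drives the call
  pred <- predict_lifestyle(model, features_sep[sp$test, ])
  truth <- stats::setNames(sim_separable$labels$lifestyle, sim_separable$labels$id)
  expect_true(all(pred$p_temperate[truth[pred$genome_id] == "temperate"] > 0.5))
})

test_that("training is deterministic under a fixed seed", {
  sub <- features_sep[c(1:30, 101:130), ]
  m1 <- train_lifestyle_model(sub, sim_separable$labels, seed = 3)
  m2 <- train_lifestyle_model(sub, sim_separable$labels, seed = 3)
  expect_identical(m1$hyperparameters, m2$hyperparameters)
  expect_identical(m1$cv_report, m2$cv_report)
  expect_identical(predict_lifestyle(m1, sub), predict_lifestyle(m2, sub))
})

test_that("label-shuffled data trains to chance-level CV accuracy", {
  set.seed(99)
  shuffled <- sim_separable$labels
  shuffled$lifestyle <- sample(shuffled$lifestyle)
  model <- train_lifestyle_model(features_sep, shuffled, seed = 99)
  mean_cv <- mean(model$cv_report$accuracy)
  expect_gt(mean_cv, 0.4)
  expect_lt(mean_cv, 0.6)
})

test_that("model selection prefers the highest minimum fold accuracy", {
  model <- train_lifestyle_model(features_sep[c(1:40, 101:140), ],
                                 sim_separable$labels, seed = 5)
  summary <- model$cv_summary
  expect_equal(model$min_cv_accuracy, max(summary$min_accuracy))
  # ties broken by fewer trees
  top <- summary[summary$min_accuracy == max(summary$min_accuracy), ]
  expect_equal(model$hyperparameters$ntree, min(top$ntree))
  # CV report covers the whole documented grid
  expect_equal(nrow(model$cv_report), 6L * 5L)
})

test_that("prediction probabilities sum to one and handle degenerate input", {
  sp <- split_dataset(sim_separable$labels, seed = 2)
  model <- train_lifestyle_model(features_sep[sp$train, ], sim_separable$labels,
                                 seed = 2)
  pred <- predict_lifestyle(model, features_sep[sp$test, ])
  expect_true(all(abs(pred$p_lytic + pred$p_temperate - 1) < 1e-9))
  # all-zero feature vector: valid probabilities, no crash
  zero <- matrix(0L, 1, ncol(features_sep),
                 dimnames = list("empty", colnames(features_sep)))
  p0 <- predict_lifestyle(model, zero)
  expect_equal(p0$p_lytic + p0$p_temperate, 1)
})

test_that("single-class labels and mismatched features are rejected", {
  lab1 <- sim_separable$labels[sim_separable$labels$lifestyle == "lytic", ]
  expect_error(
    train_lifestyle_model(features_sep[lab1$id, ], lab1, seed = 1),
    class = "phagetools_validation_error"
  )
  model <- train_lifestyle_model(features_sep[c(1:25, 101:125), ],
                                 sim_separable$labels, seed = 1)
  bad <- features_sep[1:5, 1:3]
  expect_error(predict_lifestyle(model, bad), class = "phagetools_validation_error")
})

test_that("evaluate matches a brute-force confusion tally", {
  sp <- split_dataset(sim_separable$labels, seed = 6)
  model <- train_lifestyle_model(features_sep[sp$train, ], sim_separable$labels,
                                 seed = 6)
  err <- evaluate_lifestyle(model, features_sep[sp$test, ], sim_separable$labels)
  pred <- predict_lifestyle(model, features_sep[sp$test, ])
  truth <- stats::setNames(sim_separable$labels$lifestyle, sim_separable$labels$id)
  calls <- ifelse(pred$p_lytic >= 0.5, "lytic", "temperate")
  expect_equal(err, sum(calls != truth[pred$genome_id]) / nrow(pred))
})

test_that("probability table export rounds to 3 decimals unless asked not to", {
  pred <- tibble::tibble(genome_id = c("a", "b"),
                         p_lytic = c(0.9934, 0.25),
                         p_temperate = c(0.0066, 0.75))
  tf <- tempfile(fileext = ".csv")
  export_probability_table(pred, tf)
  lines <- readLines(tf)
  expect_equal(lines[1], "id,lytic,temperate")
  expect_equal(lines[2], "a,0.993,0.007")
  export_probability_table(pred, tf, full_precision = TRUE)
  out <- readr::read_csv(tf, show_col_types = FALSE)
  expect_equal(out$lytic[1], 0.9934)
  expect_error(export_probability_table(pred[0, ], tf),
               class = "phagetools_parameter_error")
})

test_that("model archives round-trip and reject foreign objects", {
  model <- train_lifestyle_model(features_sep[c(1:25, 101:125), ],
                                 sim_separable$labels,
                                 seed = 4, domains = sim_separable$domains)
  tf <- tempfile(fileext = ".rds")
  write_lifestyle_model(model, tf)
  back <- read_lifestyle_model(tf)
  expect_identical(back$fingerprint, model$fingerprint)
  expect_identical(predict_lifestyle(back, features_sep[1:5, ]),
                   predict_lifestyle(model, features_sep[1:5, ]))
  saveRDS(list(not = "a model"), tf)
  expect_error(read_lifestyle_model(tf), class = "phagetools_validation_error")
})

test_that("tidy and glance summarise the fitted model", {
  model <- train_lifestyle_model(features_sep[c(1:25, 101:125), ],
                                 sim_separable$labels, seed = 4)
  td <- tidy(model)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("ntree", "mtry_rule", "fold", "accuracy"))
  gl <- glance(model)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$n_domains, 5L)
})
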