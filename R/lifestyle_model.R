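lifestyle_classes <- c("lytic", "temperate")

as_label_vector <- function(labels) {
  if (is.data.frame(labels)) {
    cols <- intersect(c("lifestyle", "class", "label"), names(labels))
    if (!"id" %in% names(labels) || !length(cols)) {
      stop_parameter("label table needs columns `id` and `lifestyle`")
    }
    labels <- stats::setNames(labels[[cols[1L]]], labels$id)
  }
  if (is.null(names(labels))) stop_parameter("labels must be named by genome id")
  bad <- setdiff(unique(labels), lifestyle_classes)
  if (length(bad)) {
    stop_validation(sprintf("unknown lifestyle label(s): %s", paste(bad, collapse = ", ")))
  }
  labels
}

#' Random train/test split of labeled genomes
#'
#' Shuffles the ids with the given seed and assigns the first
#' `floor(train_fraction * n)` to the training set; the split is disjoint
#' and exhaustive. The default 60:40 ratio sends 634 of 1,057 items to
#' training and 423 to testing.
#'
#' @param labels Named label vector or a tibble with columns `id`,
#'   `lifestyle`.
#' @param train_fraction Fraction assigned to training (strictly between 0
#'   and 1).
#' @param seed Integer seed driving the shuffle.
#' @return List with character vectors `train` and `test`.
#' @export
split_dataset <- function(labels, train_fraction = 0.6, seed = 1L) {
  labels <- as_label_vector(labels)
  n <- length(labels)
  if (n < 2L) stop_parameter("need at least 2 labeled items to split")
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop_parameter("train_fraction must be strictly between 0 and 1")
  }
  ids <- names(labels)
  set.seed(seed)
  perm <- sample(ids)
  n_train <- floor(train_fraction * n)
  list(train = perm[seq_len(n_train)], test = perm[seq.int(n_train + 1L, n)])
}

# deterministic stratified fold assignment
cv_folds_assign <- function(labels, cv_folds, seed) {
  fold <- integer(length(labels))
  set.seed(seed + 1L)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
  }
  fold
}

mtry_value <- function(rule, p) {
  switch(rule,
         sqrt = max(1L, floor(sqrt(p))),
         log2 = max(1L, floor(log2(p))),
         stop_parameter(sprintf("unknown mtry rule `%s`", rule)))
}

#' Train the lifestyle random-forest classifier
#'
#' Grid-searches a random forest over `ntree` in \{100, 500, 1000\} and
#' `mtry` rules \{sqrt, log2\} with stratified k-fold cross-validation,
#' selecting the configuration with the **highest minimum fold accuracy**
#' (ties broken by fewer trees, then `sqrt` before `log2`), and refits the
#' selected configuration on all provided data.
#'
#' @param features Binary feature matrix from [build_feature_matrix()]
#'   (rows = genome ids, columns = domains).
#' @param labels Named lifestyle labels (`"lytic"`/`"temperate"`) or a
#'   tibble `id`, `lifestyle`; every feature row must be labeled and both
#'   classes must be present.
#' @param cv_folds Number of cross-validation folds (default 5).
#' @param seed Integer seed; fixes folds and forest fits, so the selected
#'   hyperparameters and fold accuracies are reproducible.
#' @param domains Optional `domain_set` stored with the model so genomes
#'   can be predicted directly.
#' @return A `lifestyle_model`: list carrying the fitted forest, the
#'   ordered domain names and fingerprint, chosen hyperparameters, the
#'   full CV report (per-fold accuracies for every grid point), training
#'   ids, seed and package version.
#' @export
train_lifestyle_model <- function(features, labels, cv_folds = 5L, seed = 1L,
                                  domains = NULL) {
  labels <- as_label_vector(labels)
  if (is.null(rownames(features))) stop_parameter("feature matrix must have row names")
  missing <- setdiff(rownames(features), names(labels))
  if (length(missing)) {
    stop_validation(sprintf("unlabeled genome(s): %s", paste(missing, collapse = ", ")))
  }
  y <- factor(labels[rownames(features)], levels = lifestyle_classes)
  if (length(unique(y)) < 2L) {
    stop_validation("both lifestyle classes must be present in the training labels")
  }
  x <- as.data.frame(features)
  p <- ncol(features)
  grid <- expand.grid(ntree = c(100L, 500L, 1000L), mtry_rule = c("sqrt", "log2"),
                      stringsAsFactors = FALSE)
  fold <- cv_folds_assign(as.character(y), cv_folds, seed)

  cv_report <- purrr::pmap_dfr(grid, function(ntree, mtry_rule) {
    acc <- vapply(seq_len(cv_folds), function(f) {
      tr <- fold != f
      set.seed(seed + 1000L * ntree + f)
      fit <- randomForest::randomForest(
        x = x[tr, , drop = FALSE], y = y[tr],
        ntree = ntree, mtry = mtry_value(mtry_rule, p)
      )
      pred <- stats::predict(fit, x[!tr, , drop = FALSE])
      mean(pred == y[!tr])
    }, numeric(1))
    tibble(ntree = ntree, mtry_rule = mtry_rule,
           fold = seq_len(cv_folds), accuracy = acc)
  })

  summary <- cv_report %>%
    dplyr::group_by(.data$ntree, .data$mtry_rule) %>%
    dplyr::summarise(min_accuracy = min(.data$accuracy),
                     mean_accuracy = mean(.data$accuracy), .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$min_accuracy), .data$ntree,
                   match(.data$mtry_rule, c("sqrt", "log2")))
  best <- summary[1L, ]

  set.seed(seed)
  forest <- randomForest::randomForest(
    x = x, y = y, ntree = best$ntree, mtry = mtry_value(best$mtry_rule, p)
  )
  structure(
    list(
      forest = forest,
      domain_names = colnames(features),
      fingerprint = attr(features, "fingerprint") %||%
        (if (!is.null(domains)) attr(domains, "fingerprint") else NA_character_),
      domains = domains,
      hyperparameters = list(ntree = best$ntree, mtry_rule = best$mtry_rule,
                             mtry = mtry_value(best$mtry_rule, p)),
      cv_report = cv_report,
      cv_summary = summary,
      min_cv_accuracy = best$min_accuracy,
      training_ids = rownames(features),
      seed = seed,
      version = as.character(utils::packageVersion("phagetools"))
    ),
    class = "lifestyle_model"
  )
}

check_feature_compat <- function(model, features) {
  if (is.null(dim(features))) {
    features <- matrix(features, nrow = 1,
                       dimnames = list("query", names(features)))
  }
  if (ncol(features) != length(model$domain_names) ||
      !identical(colnames(features), model$domain_names)) {
    stop_validation(
      "feature columns do not match the model's domain set (length or order differs)"
    )
  }
  fp <- attr(features, "fingerprint")
  if (!is.null(fp) && !is.na(model$fingerprint) && !identical(fp, model$fingerprint)) {
    stop_validation(sprintf(
      "domain-set fingerprint mismatch: model %s vs features %s",
      model$fingerprint, fp
    ))
  }
  features
}

#' Predict phage lifestyle probabilities
#'
#' Class probabilities are the forest's vote fractions; each row's
#' `p_lytic` and `p_temperate` sum to 1.
#'
#' @param model A `lifestyle_model`.
#' @param newdata A feature matrix over the model's domain set, a single
#'   named feature vector, or a genome tibble (in which case the model
#'   must carry its `domain_set` and features are built on the fly).
#' @param ... Passed to [build_feature_matrix()] when `newdata` is a
#'   genome tibble.
#' @return Tibble `genome_id`, `p_lytic`, `p_temperate`.
#' @export
predict_lifestyle <- function(model, newdata, ...) {
  if (!inherits(model, "lifestyle_model")) stop_parameter("`model` must be a lifestyle_model")
  if (is.data.frame(newdata) && "sequence" %in% names(newdata)) {
    if (is.null(model$domains)) {
      stop_parameter("model carries no domain_set; supply a feature matrix instead")
    }
    newdata <- build_feature_matrix(newdata, model$domains, ...)
  }
  features <- check_feature_compat(model, newdata)
  prob <- stats::predict(model$forest, as.data.frame(features), type = "prob")
  tibble(
    genome_id = rownames(features),
    p_lytic = unname(prob[, "lytic"]),
    p_temperate = unname(prob[, "temperate"])
  )
}

#' Misclassification rate of a lifestyle model
#'
#' @param model A `lifestyle_model`.
#' @param features Feature matrix over the model's domain set.
#' @param labels Known labels (named vector or tibble `id`, `lifestyle`).
#' @return Error rate in `[0, 1]`: argmax-probability misclassifications
#'   over n.
#' @export
evaluate_lifestyle <- function(model, features, labels) {
  labels <- as_label_vector(labels)
  pred <- predict_lifestyle(model, features)
  call <- ifelse(pred$p_lytic >= pred$p_temperate, "lytic", "temperate")
  truth <- labels[pred$genome_id]
  if (anyNA(truth)) stop_validation("labels missing for some feature rows")
  mean(call != truth)
}

#' Write the lifestyle probability table as CSV
#'
#' Columns `id`, `lytic`, `temperate`; probabilities are printed with
#' three decimals by default (so 0.9934 prints as 0.993), or at full
#' precision on request.
#'
#' @param predictions Tibble from [predict_lifestyle()] (>= 1 row).
#' @param path Output CSV path.
#' @param full_precision Write unrounded doubles instead of 3-decimal
#'   formatting.
#' @return `path`, invisibly.
#' @export
export_probability_table <- function(predictions, path, full_precision = FALSE) {
  if (nrow(predictions) == 0L) stop_parameter("no predictions to export")
  out <- tibble(
    id = predictions$genome_id,
    lytic = predictions$p_lytic,
    temperate = predictions$p_temperate
  )
  if (!full_precision) {
    out$lytic <- sprintf("%.3f", out$lytic)
    out$temperate <- sprintf("%.3f", out$temperate)
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' Persist a lifestyle model to disk
#'
#' The archive is a serialized R object carrying the fitted forest, the
#' ordered domain list and its fingerprint, the chosen hyperparameters,
#' the CV report, the training seed and the package version.
#'
#' @param model A `lifestyle_model`.
#' @param path Output path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
write_lifestyle_model <- function(model, path) {
  if (!inherits(model, "lifestyle_model")) stop_parameter("`model` must be a lifestyle_model")
  saveRDS(model, path)
  invisible(path)
}

#' Load a lifestyle model archive
#' @param path Path written by [write_lifestyle_model()].
#' @return The `lifestyle_model`.
#' @export
read_lifestyle_model <- function(path) {
  model <- tryCatch(readRDS(path), error = function(e) {
    abort(sprintf("cannot read model archive %s: %s", path, conditionMessage(e)),
          class = "phagetools_io_error")
  })
  if (!inherits(model, "lifestyle_model")) {
    stop_validation(sprintf("%s is not a lifestyle model archive", path))
  }
  model
}

#' @export
print.lifestyle_model <- function(x, ...) {
  cat(sprintf(
    "Lifestyle random-forest model (v%s)\n  domains: %d  ntree: %d  mtry: %d (%s)\n  min CV accuracy: %.3f  trained on %d genomes (seed %d)\n",
    x$version, length(x$domain_names), x$hyperparameters$ntree,
    x$hyperparameters$mtry, x$hyperparameters$mtry_rule,
    x$min_cv_accuracy, length(x$training_ids), x$seed
  ))
  invisible(x)
}

#' Per-fold cross-validation accuracies of a lifestyle model
#' @param x A `lifestyle_model`.
#' @param ... Unused.
#' @return Tibble `ntree`, `mtry_rule`, `fold`, `accuracy`.
#' @export
tidy.lifestyle_model <- function(x, ...) x$cv_report

#' One-row summary of a lifestyle model
#' @param x A `lifestyle_model`.
#' @param ... Unused.
#' @return One-row tibble with the chosen hyperparameters, minimum CV
#'   accuracy, out-of-bag error and training size.
#' @export
glance.lifestyle_model <- function(x, ...) {
  tibble(
    ntree = x$hyperparameters$ntree,
    mtry_rule = x$hyperparameters$mtry_rule,
    mtry = x$hyperparameters$mtry,
    min_cv_accuracy = x$min_cv_accuracy,
    oob_error = tail(x$forest$err.rate[, "OOB"], 1L),
    n_train = length(x$training_ids),
    n_domains = length(x$domain_names)
  )
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom utils tail
NULL
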