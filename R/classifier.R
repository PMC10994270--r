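#' Classifier specification
#'
#' Settings for the control-anchored similarity classifier. The primary
#' algorithm is a three-layer (single hidden layer) neural network with
#' hidden-layer `size` and weight `decay` chosen by two-fold cross-validated
#' accuracy; random-forest and SVM comparators share the same interface.
#'
#' @param algorithm `"nn"`, `"rf"` or `"svm"`.
#' @param size_grid Hidden-layer sizes searched (nn only).
#' @param decay_grid Weight-decay values searched (nn only).
#' @param cv_folds Cross-validation folds for the grid search (default 2).
#' @param test_fraction Held-out fraction of control wells (default 0.2).
#' @param focus_class Class whose probability is the similarity score
#'   (default `"WT"`, the wild-type vehicle positive control).
#' @param maxit nn optimiser iteration cap.
#' @param seed RNG seed for splits and weight initialisation.
#' @export
classifier_spec <- function(algorithm = c("nn", "rf", "svm"),
                            size_grid = c(4, 8),
                            decay_grid = c(0.01, 0.1),
                            cv_folds = 2,
                            test_fraction = 0.2,
                            focus_class = "WT",
                            maxit = 300,
                            seed = 1) {
  algorithm <- match.arg(algorithm)
  if (!length(size_grid) || !length(decay_grid))
    stop("hyperparameter grids must be non-empty")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  structure(list(algorithm = algorithm, size_grid = sort(size_grid),
                 decay_grid = sort(decay_grid), cv_folds = as.integer(cv_folds),
                 test_fraction = test_fraction, focus_class = focus_class,
                 maxit = as.integer(maxit), seed = as.integer(seed)),
            class = "classifier_spec")
}

score_columns <- function(tab) grep("^PC[0-9]+$", names(tab), value = TRUE)

#' Split control records into train and test sets by well
#'
#' Stratified by class; all image fields of a well land on the same side.
#' Per class, the number of held-out wells is `round(test_fraction * wells)`.
#'
#' @param controls Image-level component-score table of control records with a
#'   `class` column (or `genotype` used as class).
#' @param spec A [classifier_spec()].
#' @return list with `train` and `test` tables.
#' @export
split_controls <- function(controls, spec = classifier_spec()) {
  cls <- control_class(controls)
  wells_key <- paste(controls$plate_id, controls$well)
  test_wells <- character(0)
  for (cl in unique(cls)) {
    w <- unique(wells_key[cls == cl])
    if (length(w) < 2) stop("class ", cl, " has fewer than 2 wells")
    n_test <- round(spec$test_fraction * length(w))
    n_test <- max(1L, min(n_test, length(w) - 1L))
    test_wells <- c(test_wells,
                    with_seed(spec$seed + match(cl, sort(unique(cls))),
                              sample(w, n_test)))
  }
  in_test <- wells_key %in% test_wells
  list(train = controls[!in_test, , drop = FALSE],
       test = controls[in_test, , drop = FALSE])
}

control_class <- function(tab) {
  if (!is.null(tab$class)) as.character(tab$class) else as.character(tab$genotype)
}

fit_algorithm <- function(x, y, w, spec, size = NULL, decay = NULL) {
  switch(spec$algorithm,
    nn = nnet::nnet(x, class.ind(y), size = size, decay = decay,
                    weights = w, softmax = TRUE, maxit = spec$maxit,
                    abstol = 1e-6, reltol = 1e-8, trace = FALSE,
                    MaxNWts = 100000),
    rf = randomForest::randomForest(x, y),
    svm = e1071::svm(x, y, probability = TRUE, class.weights =
                       tapply(w, y, mean)))
}

predict_focus_prob <- function(fit, x, spec, levels_y) {
  switch(spec$algorithm,
    nn = {
      pr <- predict(fit, x)
      pr[, spec$focus_class]
    },
    rf = predict(fit, x, type = "prob")[, spec$focus_class],
    svm = {
      pr <- attr(predict(fit, x, probability = TRUE), "probabilities")
      pr[, spec$focus_class]
    })
}

class.ind <- function(y) {
  y <- as.factor(y)
  out <- matrix(0, length(y), nlevels(y),
                dimnames = list(NULL, levels(y)))
  out[cbind(seq_along(y), as.integer(y))] <- 1
  out
}

#' Train the control-anchored classifier
#'
#' Trains on image-level component scores of the vehicle-treated control
#' records. For the neural network, the (`size`, `decay`) pair is chosen by
#' `cv_folds`-fold cross-validated accuracy over the grid, with folds split
#' by well; ties prefer the smaller size, then the larger decay. Class
#' imbalance is handled by inverse-class-frequency case weights.
#'
#' @param train Image-level component-score table of control records.
#' @param spec A [classifier_spec()].
#' @return A `morph_classifier` object.
#' @export
train_classifier <- function(train, spec = classifier_spec()) {
  cls <- factor(control_class(train))
  if (nlevels(cls) < 2) stop("training set must contain both control classes")
  if (any(table(cls) < 2)) stop("each class needs at least 2 records")
  if (!spec$focus_class %in% levels(cls))
    stop("focus class ", spec$focus_class, " absent from training labels")
  pcs <- score_columns(train)
  if (!length(pcs)) stop("no component-score (PC) columns in training data")
  x <- as.matrix(as.data.frame(train)[, pcs, drop = FALSE])
  w <- (1 / table(cls))[as.character(cls)] * length(cls) / nlevels(cls)
  w <- as.numeric(w)

  chosen <- list(size = NA, decay = NA)
  if (spec$algorithm == "nn") {
    grid <- expand.grid(size = spec$size_grid, decay = spec$decay_grid,
                        KEEP.OUT.ATTRS = FALSE)
    wells_key <- paste(train$plate_id, train$well)
    uw <- unique(wells_key)
    fold_of_well <- with_seed(spec$seed,
      sample(rep(seq_len(spec$cv_folds), length.out = length(uw))))
    fold <- fold_of_well[match(wells_key, uw)]
    acc <- vapply(seq_len(nrow(grid)), function(gi) {
      hits <- 0
      for (f in seq_len(spec$cv_folds)) {
        tr <- fold != f
        fit <- with_seed(spec$seed + 100 * gi + f,
          fit_algorithm(x[tr, , drop = FALSE], cls[tr], w[tr], spec,
                        grid$size[gi], grid$decay[gi]))
        pr <- predict_focus_prob(fit, x[!tr, , drop = FALSE], spec)
        pred <- ifelse(pr > 0.5, spec$focus_class,
                       setdiff(levels(cls), spec$focus_class)[1])
        hits <- hits + sum(pred == as.character(cls[!tr]))
      }
      hits / length(cls)
    }, numeric(1))
    # ties: smaller size, then larger decay
    ord <- order(-acc, grid$size, -grid$decay)
    chosen <- as.list(grid[ord[1], ])
    fit <- with_seed(spec$seed,
      fit_algorithm(x, cls, w, spec, chosen$size, chosen$decay))
    cv_accuracy <- acc[ord[1]]
  } else {
    fit <- with_seed(spec$seed, fit_algorithm(x, cls, w, spec))
    cv_accuracy <- NA_real_
  }
  structure(list(fit = fit, spec = spec, feature_names = pcs,
                 levels = levels(cls), chosen = chosen,
                 cv_accuracy = cv_accuracy),
            class = "morph_classifier")
}

#' Image-level focus-class probabilities from a trained classifier
#' @param model A `morph_classifier`.
#' @param tab Component-score table with the training PC columns.
#' @export
classifier_prob <- function(model, tab) {
  missing <- setdiff(model$feature_names, names(tab))
  if (length(missing))
    stop("schema mismatch; missing component columns: ",
         paste(missing, collapse = ", "))
  x <- as.matrix(as.data.frame(tab)[, model$feature_names, drop = FALSE])
  as.numeric(predict_focus_prob(model$fit, x, model$spec))
}

#' Evaluate a classifier on held-out control records
#'
#' Confusion matrix with the focus class as positive, plus sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`, detection rate `TP/total`,
#' accuracy, and the mean focus-class probability within each control class.
#'
#' @param model A `morph_classifier`.
#' @param test Held-out control records (image level).
#' @return A `classifier_report` list.
#' @export
evaluate_classifier <- function(model, test) {
  if (!nrow(test)) stop("empty test set")
  cls <- control_class(test)
  prob <- classifier_prob(model, test)
  focus <- model$spec$focus_class
  other <- setdiff(model$levels, focus)[1]
  pred <- ifelse(prob > 0.5, focus, other)
  tp <- sum(pred == focus & cls == focus)
  fn <- sum(pred != focus & cls == focus)
  tn <- sum(pred != focus & cls != focus)
  fp <- sum(pred == focus & cls != focus)
  total <- tp + fp + tn + fn
  mean_prob <- tapply(prob, cls, mean)
  structure(list(confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 detection_rate = tp / total,
                 accuracy = (tp + tn) / total,
                 mean_focus_prob = as.list(mean_prob),
                 chosen = model$chosen,
                 algorithm = model$spec$algorithm,
                 seed = model$spec$seed),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("classifier_report (%s): sens %.3f, spec %.3f, detection rate %.3f, accuracy %.3f\n",
              x$algorithm, x$sensitivity, x$specificity, x$detection_rate,
              x$accuracy))
  invisible(x)
}

#' Score compound-treated records for wild-type similarity
#'
#' Applies the trained classifier to image-level records of treated wells and
#' aggregates to a per-well similarity score `s` = median of the well's
#' image-level focus-class probabilities; `s = 1` means fully wild-type-like.
#'
#' @param model A `morph_classifier`.
#' @param treated Image-level component-score table of treated records.
#' @return data.frame: `compound_id`, `subclone_id`, `concentration_nM`,
#'   `plate_id`, `well`, `score`, `n_fields`.
#' @export
score_treated <- function(model, treated) {
  prob <- classifier_prob(model, treated)
  dt <- data.table::data.table(
    compound_id = treated$treatment,
    subclone_id = treated$subclone_id,
    concentration_nM = treated$concentration_nM,
    plate_id = treated$plate_id, well = treated$well, prob = prob)
  out <- dt[, .(score = median(prob), n_fields = .N),
            by = c("compound_id", "subclone_id", "concentration_nM",
                   "plate_id", "well")]
  as.data.frame(out)
}
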