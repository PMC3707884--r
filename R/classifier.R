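# Class-weighted linear SVM training and evaluation. Training is delegated
# to the libsvm binding in e1071 (linear kernel); the decision function is
# extracted to an explicit (w, b) pair so scores, threshold sweeps and
# persisted models are independent of the fitting backend.

.as_label <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    out <- ifelse(labels %in% c("coding", "1", "+1"), 1L,
                  ifelse(labels %in% c("noncoding", "-1"), -1L, NA_integer_))
  } else {
    out <- ifelse(labels > 0, 1L, -1L)
  }
  if (anyNA(out)) stop("labels must be +1/-1 or coding/noncoding", call. = FALSE)
  out
}

#' Train a class-weighted linear SVM
#'
#' Fits a linear support vector classifier with per-class misclassification
#' costs `C * w_plus` for the coding class and `C * w_minus` for the
#' non-coding class, where `w_plus = 1` and `w_minus = w_ratio`. The
#' decision score of a vector `x` is `w . x + b`; a sequence is predicted
#' coding iff its score is > 0. Defaults are the tuned values
#' `C = 2^-3.5`, `w_ratio = 2^0.6`.
#'
#' @param x Numeric feature matrix (rows = samples), already scaled with
#'   the `scaler` that will travel with the model.
#' @param labels Labels, +1/-1 (or "coding"/"noncoding"), one per row.
#' @param C Cost parameter (positive).
#' @param w_ratio Ratio of the negative-class to positive-class cost
#'   multiplier (positive).
#' @param scaler Optional `minmax_scaler` fit on the *unscaled* training
#'   vectors; stored on the model and applied by [predict_orfs()].
#' @param selection Measurement selection the features were encoded with;
#'   stored for [predict_orfs()].
#' @param tolerance libsvm termination tolerance.
#' @return An object of class `orf_model`: fields `w` (named weight
#'   vector), `b`, `C`, `w_ratio`, `scaler`, `selection`.
#' @export
svm_train <- function(x, labels, C = 2^-3.5, w_ratio = 2^0.6,
                      scaler = NULL, selection = NULL, tolerance = 1e-4) {
  stopifnot(is.matrix(x), C > 0, w_ratio > 0)
  y <- .as_label(labels)
  if (length(y) != nrow(x))
    stop("one label per row required", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes", call. = FALSE)
  yf <- factor(ifelse(y > 0, "coding", "noncoding"),
               levels = c("coding", "noncoding"))
  fit <- e1071::svm(x, yf, type = "C-classification", kernel = "linear",
                    cost = C, class.weights = c(coding = 1, noncoding = w_ratio),
                    scale = FALSE, tolerance = tolerance, fitted = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # align the explicit (w, b) with libsvm's decision values so that
  # positive score always means the coding class
  probe <- x[seq_len(min(25L, nrow(x))), , drop = FALSE]
  dv <- attr(stats::predict(fit, probe, decision.values = TRUE),
             "decision.values")
  target <- if (colnames(dv)[1L] == "coding/noncoding") dv[, 1L] else -dv[, 1L]
  mine <- drop(probe %*% w) + b
  if (sum(abs(mine - target)) > sum(abs(mine + target))) {
    w <- -w
    b <- -b
  }
  names(w) <- colnames(x)
  structure(
    list(w = w, b = b, C = C, w_ratio = w_ratio, scaler = scaler,
         selection = selection, n_support = nrow(fit$SV),
         feature_order = "orfsvm-v1"),
    class = "orf_model"
  )
}

#' @export
print.orf_model <- function(x, ...) {
  cat(sprintf(
    "linear SVM: %d features, C = %.4g, w_ratio = %.4g, bias = %.4g (%d SV)\n",
    length(x$w), x$C, x$w_ratio, x$b, x$n_support %||% NA_integer_))
  invisible(x)
}

#' Decision scores of feature vectors
#'
#' Raw signed margin `w . x + b` per vector; positive means predicted
#' coding.
#'
#' @param model An `orf_model`.
#' @param x Feature matrix (or single vector) on the same scale the model
#'   was trained on.
#' @return Numeric vector of scores.
#' @export
decision_scores <- function(model, x) {
  stopifnot(inherits(model, "orf_model"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(model$w))
    stop(sprintf("width mismatch: model has %d features, input has %d",
                 length(model$w), ncol(x)), call. = FALSE)
  drop(x %*% model$w) + model$b
}

#' Confusion counts to sensitivity, specificity and accuracy
#'
#' `Sn = TP / (TP + FN)` (percentage of coding sequences identified
#' correctly), `Sp = TN / (TN + FP)` (percentage of non-coding sequences
#' identified correctly), and accuracy their arithmetic mean — all reported
#' as percentages.
#'
#' @param TP,FN,TN,FP Non-negative confusion counts; each class must be
#'   non-empty.
#' @return An object of class `performance_report` with fields `TP`, `FN`,
#'   `TN`, `FP`, `Sn`, `Sp`, `accuracy` (percent).
#' @export
#' @examples
#' evaluate(TP = 4820, FN = 15, TN = 3508, FP = 7)
evaluate <- function(TP, FN, TN, FP) {
  counts <- c(TP = TP, FN = FN, TN = TN, FP = FP)
  if (any(counts < 0)) stop("confusion counts must be non-negative", call. = FALSE)
  if (TP + FN == 0) stop("no positive samples (TP + FN = 0)", call. = FALSE)
  if (TN + FP == 0) stop("no negative samples (TN + FP = 0)", call. = FALSE)
  sn <- 100 * TP / (TP + FN)
  sp <- 100 * TN / (TN + FP)
  structure(
    list(TP = TP, FN = FN, TN = TN, FP = FP,
         Sn = sn, Sp = sp, accuracy = (sn + sp) / 2),
    class = "performance_report"
  )
}

#' Accuracy from sensitivity and specificity
#'
#' The arithmetic mean of Sn and Sp (both in percent).
#'
#' @param Sn,Sp Percentages.
#' @return Accuracy in percent.
#' @export
#' @examples
#' accuracy_from_snsp(97.52, 96.68)  # 97.10
accuracy_from_snsp <- function(Sn, Sp) (Sn + Sp) / 2

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("TP %d  FN %d  TN %d  FP %d | Sn %.2f%%  Sp %.2f%%  accuracy %.2f%%\n",
              x$TP, x$FN, x$TN, x$FP, x$Sn, x$Sp, x$accuracy))
  invisible(x)
}

.check_dataset <- function(dataset) {
  need <- c("seq_id", "sequence", "label")
  if (!is.data.frame(dataset) || !all(need %in% names(dataset)))
    stop("`dataset` needs columns seq_id, sequence, label", call. = FALSE)
  if (anyDuplicated(dataset$seq_id))
    stop("seq_id values must be unique", call. = FALSE)
  dataset
}

# stratified k-fold assignment: samples are dealt class by class into a
# shuffled fold order, so fold sizes are equal (+/-1), each class spreads
# as evenly as possible, and k = n reduces to leave-one-out; redrawn
# (seeded) until every training split holds both classes
.stratified_folds <- function(y, k, seed, max_attempts = 10L) {
  n <- length(y)
  if (k > n) stop("`k` cannot exceed the sample count", call. = FALSE)
  for (attempt in seq_len(max_attempts)) {
    set.seed(seed + attempt - 1L)
    fold <- integer(n)
    deal <- sample.int(k)
    pos <- 0L
    for (cls in sort(unique(y))) {
      for (j in sample(which(y == cls))) {
        pos <- pos + 1L
        fold[j] <- deal[(pos - 1L) %% k + 1L]
      }
    }
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(y[fold != f])) == 2L, logical(1)))
    if (ok) return(fold)
  }
  stop("could not build folds with both classes in every training split",
       call. = FALSE)
}

# CV given a precomputed feature matrix; shared by cross_validate,
# screen_combinations and grid_search so a single fold partition can be
# reused across configurations
.cv_matrix <- function(x, y, ids, folds, k, C, w_ratio, refit_scaler = TRUE) {
  per_fold <- data.frame(fold = seq_len(k), TP = NA_integer_, FN = NA_integer_,
                         TN = NA_integer_, FP = NA_integer_,
                         Sn = NA_real_, Sp = NA_real_)
  mis_pos <- character(0)
  for (f in seq_len(k)) {
    tr <- folds != f
    xtr <- x[tr, , drop = FALSE]
    xte <- x[!tr, , drop = FALSE]
    if (refit_scaler) {
      sc <- fit_scaler(xtr)
      xtr <- apply_scaler(sc, xtr)
      xte <- apply_scaler(sc, xte)
    }
    model <- svm_train(xtr, y[tr], C = C, w_ratio = w_ratio)
    sc_te <- decision_scores(model, xte)
    yte <- y[!tr]
    pred <- ifelse(sc_te > 0, 1L, -1L)
    per_fold$TP[f] <- sum(pred == 1L & yte == 1L)
    per_fold$FN[f] <- sum(pred == -1L & yte == 1L)
    per_fold$TN[f] <- sum(pred == -1L & yte == -1L)
    per_fold$FP[f] <- sum(pred == 1L & yte == -1L)
    mis_pos <- c(mis_pos, ids[!tr][pred == -1L & yte == 1L])
  }
  per_fold$Sn <- 100 * per_fold$TP / (per_fold$TP + per_fold$FN)
  per_fold$Sp <- 100 * per_fold$TN / (per_fold$TN + per_fold$FP)
  # folds holding a single class (e.g. leave-one-out) yield NaN for the
  # absent side; they are excluded from the fold means and sds
  sn <- mean(per_fold$Sn, na.rm = TRUE)
  sp <- mean(per_fold$Sp, na.rm = TRUE)
  structure(
    list(per_fold = per_fold,
         Sn = sn, Sn_sd = sd(per_fold$Sn, na.rm = TRUE),
         Sp = sp, Sp_sd = sd(per_fold$Sp, na.rm = TRUE),
         accuracy = (sn + sp) / 2,
         misclassified_positives = mis_pos),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV: Sn %.2f%% (sd %.2f)  Sp %.2f%% (sd %.2f)  accuracy %.2f%%\n",
              nrow(x$per_fold), x$Sn, x$Sn_sd, x$Sp, x$Sp_sd, x$accuracy))
  if (length(x$misclassified_positives))
    cat("missed positives:", paste(head(x$misclassified_positives, 20L),
                                   collapse = " "), "\n")
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' Randomly partitions the dataset into `k` stratified folds (seeded); for
#' each fold the min-max scaler and the SVM are fit on the remaining
#' `k - 1` folds and evaluated on the held-out fold, so no scaling
#' information leaks from test to training data. Reports per-fold Sn/Sp,
#' their means and standard deviations, overall accuracy (mean of mean Sn
#' and mean Sp), and the identities of misclassified positive sequences.
#'
#' @param dataset Data frame with columns `seq_id`, `sequence`, `label`
#'   (+1 coding / -1 non-coding).
#' @param selection Measurement blocks to encode (subset of `1:6`).
#' @param k Number of folds (>= 2).
#' @param C,w_ratio SVM hyperparameters, see [svm_train()].
#' @param seed Integer seed for the fold partition.
#' @param refit_scaler Refit the min-max scale inside every fold (default)
#'   or fit it once on the full dataset before splitting.
#' @return A `cv_report` object.
#' @export
cross_validate <- function(dataset, selection = 1:6, k = 10,
                           C = 2^-3.5, w_ratio = 2^0.6, seed = 1,
                           refit_scaler = TRUE) {
  dataset <- .check_dataset(dataset)
  if (k < 2L) stop("`k` must be at least 2", call. = FALSE)
  y <- .as_label(dataset$label)
  x <- encode_features(stats::setNames(dataset$sequence, dataset$seq_id),
                       selection)
  if (!refit_scaler) x <- apply_scaler(fit_scaler(x), x)
  folds <- .stratified_folds(y, k, seed)
  .cv_matrix(x, y, dataset$seq_id, folds, k, C, w_ratio,
             refit_scaler = refit_scaler)
}

# all non-empty subsets of 1..6 ordered singletons first, full set last
feature_combinations <- function() {
  out <- list()
  for (size in 1:6)
    out <- c(out, combn(6L, size, simplify = FALSE))
  out
}

#' Cross-validation screen over all 63 feature combinations
#'
#' Runs [cross_validate()] for every non-empty subset of the six
#' measurement blocks, reusing one fold partition and one full 4682-wide
#' encoding across all 63 rows so the combinations are compared on
#' identical splits.
#'
#' @inheritParams cross_validate
#' @return Data frame with 63 rows: `measurements` (e.g. `"1, 3, 5"`),
#'   `Sn`, `Sn_sd`, `Sp`, `Sp_sd`, `accuracy` (percent).
#' @export
screen_combinations <- function(dataset, k = 10, C = 2^-3.5,
                                w_ratio = 2^0.6, seed = 1) {
  dataset <- .check_dataset(dataset)
  y <- .as_label(dataset$label)
  x_full <- encode_features(stats::setNames(dataset$sequence, dataset$seq_id), 1:6)
  folds <- .stratified_folds(y, k, seed)
  combos <- feature_combinations()
  rows <- lapply(combos, function(sel) {
    cv <- .cv_matrix(x_full[, block_columns(sel), drop = FALSE], y,
                     dataset$seq_id, folds, k, C, w_ratio)
    data.frame(measurements = paste(sel, collapse = ", "),
               Sn = cv$Sn, Sn_sd = cv$Sn_sd, Sp = cv$Sp, Sp_sd = cv$Sp_sd,
               accuracy = cv$accuracy)
  })
  do.call(rbind, rows)
}

#' Grid search over cost and class-weight ratio
#'
#' Cross-validated accuracy for every `(log2 C, log2 w_ratio)` cell on a
#' shared fold partition. Ties on accuracy are broken toward the smaller
#' `C`, then the smaller `|log2 w_ratio|` (the simpler model). The default
#' grids cover the tuned optimum `C = 2^-3.5`, `w_ratio = 2^0.6`.
#'
#' @inheritParams cross_validate
#' @param log2C_grid,log2w_grid Numeric grids of `log2 C` and
#'   `log2 w_ratio` values.
#' @return List with `grid` (data frame: `log2C`, `log2w`, `Sn`, `Sp`,
#'   `accuracy`) and `best` (the winning row).
#' @export
grid_search <- function(dataset, selection = 1:6,
                        log2C_grid = seq(-8, 4, by = 0.5),
                        log2w_grid = seq(-2, 2, by = 0.2),
                        k = 10, seed = 1) {
  dataset <- .check_dataset(dataset)
  if (!length(log2C_grid) || !length(log2w_grid))
    stop("grids must be non-empty", call. = FALSE)
  y <- .as_label(dataset$label)
  x <- encode_features(stats::setNames(dataset$sequence, dataset$seq_id),
                       selection)
  folds <- .stratified_folds(y, k, seed)
  cells <- expand.grid(log2C = log2C_grid, log2w = log2w_grid,
                       KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    cv <- .cv_matrix(x, y, dataset$seq_id, folds, k,
                     C = 2^cells$log2C[i], w_ratio = 2^cells$log2w[i])
    c(Sn = cv$Sn, Sp = cv$Sp, accuracy = cv$accuracy)
  })
  grid <- cbind(cells, do.call(rbind, res))
  ord <- order(-grid$accuracy, grid$log2C, abs(grid$log2w))
  list(grid = grid, best = grid[ord[1L], ])
}

#' Sensitivity/specificity along a decision-threshold sweep
#'
#' For each offset `t`, a sample is predicted coding iff its decision score
#' exceeds `t`. As `t` increases, Sn is non-increasing and Sp
#' non-decreasing.
#'
#' @param model An `orf_model`.
#' @param x Feature matrix on the model's scale.
#' @param labels +1/-1 labels per row.
#' @param offsets Numeric vector of thresholds.
#' @return Data frame with columns `offset`, `TP`, `FN`, `TN`, `FP`, `Sn`,
#'   `Sp` (percent).
#' @export
threshold_sweep <- function(model, x, labels, offsets) {
  stopifnot(all(is.finite(offsets)))
  y <- .as_label(labels)
  s <- decision_scores(model, x)
  rows <- lapply(offsets, function(t) {
    pred <- s > t
    data.frame(offset = t,
               TP = sum(pred & y == 1L), FN = sum(!pred & y == 1L),
               TN = sum(!pred & y == -1L), FP = sum(pred & y == -1L))
  })
  out <- do.call(rbind, rows)
  out$Sn <- 100 * out$TP / (out$TP + out$FN)
  out$Sp <- 100 * out$TN / (out$TN + out$FP)
  out
}

#' Score and label ORF sequences with a trained model
#'
#' Encodes each sequence with the model's stored measurement selection,
#' applies the stored min-max scale, computes decision scores and labels
#' (`coding` iff score > 0). Sequences shorter than one codon are flagged
#' `unscorable` with `NA` score rather than dropped; output order follows
#' input order.
#'
#' @param model An `orf_model` carrying `scaler` and `selection`.
#' @param sequences Named character vector of nucleotide sequences.
#' @return Data frame: `orf_id`, `length_bp`, `score`, `label`.
#' @export
predict_orfs <- function(model, sequences) {
  stopifnot(inherits(model, "orf_model"))
  if (is.null(model$selection) || is.null(model$scaler))
    stop("model must carry its scaler and measurement selection", call. = FALSE)
  n <- length(sequences)
  ids <- names(sequences) %||% as.character(seq_len(n))
  out <- data.frame(orf_id = ids,
                    length_bp = if (n) nchar(sequences) else integer(0),
                    score = rep(NA_real_, n),
                    label = rep("unscorable", n),
                    stringsAsFactors = FALSE)
  scorable <- out$length_bp >= 3L
  if (any(scorable)) {
    x <- encode_features(sequences[scorable], model$selection)
    s <- decision_scores(model, apply_scaler(model$scaler, x))
    out$score[scorable] <- s
    out$label[scorable] <- ifelse(s > 0, "coding", "noncoding")
  }
  rownames(out) <- NULL
  out
}

#' Train a model end-to-end from a labeled sequence dataset
#'
#' Encodes, fits the min-max scaler on the full training set, and trains
#' the class-weighted linear SVM; the returned model carries the scaler
#' and selection so [predict_orfs()] can be applied to raw sequences.
#'
#' @inheritParams cross_validate
#' @return An `orf_model`.
#' @export
train_orf_model <- function(dataset, selection = 1:6, C = 2^-3.5,
                            w_ratio = 2^0.6) {
  dataset <- .check_dataset(dataset)
  selection <- .check_selection(selection)
  x <- encode_features(stats::setNames(dataset$sequence, dataset$seq_id),
                       selection)
  scaler <- fit_scaler(x)
  svm_train(apply_scaler(scaler, x), .as_label(dataset$label),
            C = C, w_ratio = w_ratio, scaler = scaler, selection = selection)
}

#' Persist / restore a trained model as plain text
#'
#' JSON with full-precision numbers: weights, bias, hyperparameters,
#' measurement selection, scaler min/max and a feature-ordering version
#' tag. A reloaded model reproduces decision scores to better than 1e-10.
#'
#' @param model An `orf_model`.
#' @param path File path.
#' @return `write_model()` returns `path` invisibly; `read_model()` the
#'   restored `orf_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "orf_model"))
  payload <- list(
    format = "orfsvm-model-1",
    feature_order = model$feature_order,
    C = model$C, w_ratio = model$w_ratio, b = model$b,
    selection = model$selection,
    feature_names = names(model$w),
    w = unname(model$w),
    scaler = if (!is.null(model$scaler))
      list(min = unname(model$scaler$min), max = unname(model$scaler$max))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "orfsvm-model-1"))
    stop("not an orfsvm model file", call. = FALSE)
  scaler <- NULL
  if (!is.null(p$scaler)) {
    scaler <- structure(
      list(min = p$scaler$min, max = p$scaler$max, dim = length(p$scaler$min)),
      class = "minmax_scaler")
  }
  structure(
    list(w = stats::setNames(p$w, p$feature_names), b = p$b, C = p$C,
         w_ratio = p$w_ratio, scaler = scaler,
         selection = as.integer(p$selection),
         n_support = NA_integer_, feature_order = p$feature_order),
    class = "orf_model"
  )
}
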