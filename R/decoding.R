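# Cached handle to libsvm's training routine (registered by e1071).
.svm_env <- new.env(parent = emptyenv())

.svmtrain_symbol <- function() {
  if (is.null(.svm_env$sym)) {
    .svm_env$sym <- tryCatch(
      get("R_svmtrain", envir = asNamespace("e1071")),
      error = function(e) NA
    )
  }
  .svm_env$sym
}

# Direct call into libsvm (C-classification, linear kernel), mirroring
# the argument layout of e1071::svm but skipping the wrapper's
# formula/NA/scaling machinery, which dominates runtime at our problem
# sizes. y_int must be 1/2 class codes; returns w, b oriented so that
# positive decision values mean class 1.
.svm_linear_direct <- function(x, y_int, cost) {
  sym <- .svmtrain_symbol()
  if (!inherits(sym, "NativeSymbolInfo")) return(NULL)
  nr <- nrow(x)
  err <- paste(rep(" ", 255), collapse = "")
  cret <- .C(
    sym,
    as.double(t(x)), as.integer(nr), as.integer(ncol(x)),
    as.double(y_int), as.integer(0), as.integer(0),
    as.integer(0),              # type: C-classification
    as.integer(0),              # kernel: linear
    as.integer(3), as.double(1 / ncol(x)), as.double(0),
    as.double(cost), as.double(0.5),
    integer(0), double(0), as.integer(0),   # no class weights
    as.double(40), as.double(0.001), as.double(0.1),
    as.integer(1), as.integer(0), as.integer(0), as.integer(0),
    nclasses = integer(1), nr = integer(1), index = integer(nr),
    labels = integer(2), nSV = integer(2), rho = double(1),
    coefs = double(nr), sigma = double(1), probA = double(1),
    probB = double(1), cresults = double(0), ctotal1 = double(1),
    ctotal2 = double(1), error = err
  )
  if (cret$error != err) stop(trimws(cret$error))
  idx <- cret$index[seq_len(cret$nr)]
  w <- as.numeric(cret$coefs[seq_len(cret$nr)] %*% x[idx, , drop = FALSE])
  b <- -cret$rho[1]
  if (cret$labels[1] != 1L) {
    w <- -w
    b <- -b
  }
  list(weights = w, bias = b)
}

#' Fit a linear soft-margin SVM
#'
#' Thin wrapper around libsvm (via e1071) that returns an explicit
#' weight vector and bias, oriented so that a positive decision value
#' `w . x + b` predicts the first training label. A decision value of
#' exactly 0 is resolved to the first training label, which keeps runs
#' bit-reproducible.
#'
#' @param x feature matrix (samples x features).
#' @param y labels (2 classes; coerced to factor, order of levels = the
#'   training label order).
#' @param cost soft-margin penalty (SVM cost parameter).
#' @param engine `"direct"` calls libsvm's training routine straight
#'   through its registered C entry point; `"e1071"` goes through
#'   [e1071::svm()]. Both produce the same solution (libsvm underneath);
#'   the direct path avoids per-call wrapper overhead, which matters
#'   when fitting tens of thousands of cross-validation folds.
#' @return object of class `linear_svm`: `weights`, `bias`, `labels`.
#' @export
fit_linear_classifier <- function(x, y, cost = 1,
                                  engine = c("direct", "e1071")) {
  engine <- match.arg(engine)
  y <- if (is.factor(y)) droplevels(y) else factor(y, levels = unique(y))
  if (nlevels(y) != 2) {
    stop("training set must contain exactly 2 classes, got ", nlevels(y))
  }
  if (cost <= 0) stop("cost must be positive")
  wb <- if (engine == "direct") {
    .svm_linear_direct(x, as.integer(y), cost)
  }
  if (is.null(wb)) {
    fit <- e1071::svm(
      x = x, y = y, kernel = "linear", cost = cost,
      scale = FALSE, fitted = FALSE
    )
    w <- as.numeric(t(fit$coefs) %*% fit$SV)
    b <- -fit$rho
    # libsvm's decision-value sign follows the order labels appear in
    # the training data; flip so positive always means levels(y)[1]
    if (fit$levels[fit$labels[1]] != levels(y)[1]) {
      w <- -w
      b <- -b
    }
    wb <- list(weights = w, bias = b)
  }
  structure(
    list(weights = wb$weights, bias = wb$bias, labels = levels(y),
         cost = cost),
    class = "linear_svm"
  )
}

#' Decision values of a linear SVM
#' @param model a `linear_svm`.
#' @param x feature matrix.
#' @export
decision_values <- function(model, x) {
  as.numeric(x %*% model$weights + model$bias)
}

#' @export
predict.linear_svm <- function(object, newdata, ...) {
  d <- decision_values(object, newdata)
  ifelse(d >= 0, object$labels[1], object$labels[2])
}

# Exact linear-kernel compression: rotate the fold's (train + test)
# samples onto the basis they span, via the eigendecomposition of the
# Gram matrix. Decision values of a linear SVM are unchanged; fits on
# n-dimensional features are much cheaper than on the full voxel space.
.span_project <- function(train, test) {
  a <- rbind(train, test)
  if (ncol(a) <= nrow(a)) {
    return(list(train = train, test = test))
  }
  g <- tcrossprod(a)
  e <- eigen(g, symmetric = TRUE)
  keep <- e$values > max(e$values, 0) * 1e-12
  z <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), sum(keep))
  list(
    train = z[seq_len(nrow(train)), , drop = FALSE],
    test = z[nrow(train) + seq_len(nrow(test)), , drop = FALSE]
  )
}

# One train/test evaluation: fold-wise z-scoring, span projection,
# SVM fit, accuracy on the test samples. Uses the direct libsvm entry
# point when available; falls back to the e1071 wrapper otherwise.
.decode_fold <- function(train_x, train_y, test_x, test_y, cost,
                         fold_name = "fold") {
  lv <- unique(train_y)
  if (length(lv) < 2) {
    stop("training set of ", fold_name, " is missing a class")
  }
  z <- zscore_fold(train_x, test_x)
  pr <- .span_project(z$train, z$test)
  wb <- .svm_linear_direct(pr$train, match(train_y, lv), cost)
  if (is.null(wb)) {
    model <- fit_linear_classifier(pr$train, factor(train_y, levels = lv),
                                   cost = cost, engine = "e1071")
    wb <- list(weights = model$weights, bias = model$bias)
  }
  d <- pr$test %*% wb$weights + wb$bias
  mean(ifelse(d >= 0, lv[1], lv[2]) == test_y)
}

.decoding_result <- function(kind, accuracy, folds, participant = NA,
                             roi = NA, phase = NA, condition = NA) {
  structure(
    list(
      kind = kind, accuracy = accuracy, fold_accuracies = folds,
      n_folds = length(folds), participant = participant, roi = roi,
      phase = phase, condition = condition
    ),
    class = "decoding_result"
  )
}

#' Leave-one-run-out decoding accuracy
#'
#' Each retained run serves once as the test set; z-scoring is computed
#' inside each fold on the training runs only. The participant's
#' accuracy is the mean of the per-fold accuracies. Folds whose test run
#' contains no samples are skipped with a warning; a training fold
#' missing one of the two orientations is an error.
#'
#' @param set a `pattern_set` (one condition, phase, ROI, participant).
#' @param cost SVM cost.
#' @return a `decoding_result` with `kind = "same"`.
#' @export
loro_accuracy <- function(set, cost = 1) {
  run_vec <- set$meta$run
  ori_vec <- set$meta$orientation
  runs <- sort(unique(run_vec))
  if (length(runs) < 2) stop("leave-one-run-out needs at least 2 runs")
  folds <- vapply(runs, function(r) {
    te <- run_vec == r
    if (!any(te)) {
      warning("run ", r, " has no test samples; fold skipped")
      return(NA_real_)
    }
    .decode_fold(
      set$x[!te, , drop = FALSE], ori_vec[!te],
      set$x[te, , drop = FALSE], ori_vec[te],
      cost, fold_name = paste0("fold run ", r)
    )
  }, numeric(1))
  .decoding_result(
    "same", mean(folds, na.rm = TRUE), folds,
    participant = set$meta$participant[1], roi = set$roi,
    phase = set$meta$phase[1], condition = set$meta$condition[1]
  )
}

#' Cross-condition transfer decoding accuracy
#'
#' Trains on all samples of one condition and tests on all samples of
#' the other, in both directions; the reported accuracy is the mean of
#' the two directions (both retained in `fold_accuracies`). Z-scoring is
#' applied per direction with training statistics only.
#'
#' @param set_a,set_b `pattern_set`s sharing ROI, phase and feature
#'   space.
#' @param cost SVM cost.
#' @param kind result label.
#' @return a `decoding_result` with `kind = "transfer"`.
#' @export
transfer_accuracy <- function(set_a, set_b, cost = 1, kind = "transfer") {
  if (ncol(set_a$x) != ncol(set_b$x)) stop("feature-length mismatch")
  ab <- .decode_fold(
    set_a$x, set_a$meta$orientation, set_b$x, set_b$meta$orientation,
    cost, fold_name = "direction A->B"
  )
  ba <- .decode_fold(
    set_b$x, set_b$meta$orientation, set_a$x, set_a$meta$orientation,
    cost, fold_name = "direction B->A"
  )
  folds <- c(a_to_b = ab, b_to_a = ba)
  .decoding_result(
    kind, mean(folds), folds,
    participant = set_a$meta$participant[1], roi = set_a$roi,
    phase = paste(unique(c(set_a$meta$phase[1], set_b$meta$phase[1])),
                  collapse = "|"),
    condition = paste(unique(c(set_a$meta$condition[1],
                               set_b$meta$condition[1])), collapse = "&")
  )
}

#' Cross-phase transfer decoding accuracy
#'
#' Trains on the instruction-phase samples of a condition and tests on
#' its action-phase samples, and vice versa; accuracies of the two
#' directions are averaged. Accuracy below chance indicates
#' anti-correlated orientation coding across phases.
#'
#' @param set_instruction,set_action `pattern_set`s of the same
#'   condition, ROI and participant.
#' @param cost SVM cost.
#' @return a `decoding_result` with `kind = "cross_phase"`.
#' @export
cross_phase_accuracy <- function(set_instruction, set_action, cost = 1) {
  transfer_accuracy(set_instruction, set_action, cost, kind = "cross_phase")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(
    x$kind, "decoding:", sprintf("%.1f%%", 100 * x$accuracy),
    "over", x$n_folds, "folds",
    if (!is.na(x$roi)) paste0("(", x$roi, ", ", x$condition, ", ",
                              x$phase, ")") else "", "\n"
  )
  invisible(x)
}
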