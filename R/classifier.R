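#' Nested leave-one-out cross-validated linear SVC
#'
#' Classifies patients against controls from edge strengths with a linear
#' support vector classifier (LIBSVM via \pkg{e1071}). The outer loop is
#' leave-one-out: each subject is held out once. Within each outer
#' training set, features are z-scored using training statistics only (no
#' leakage), and an inner stratified k-fold cross-validation selects the
#' regularization constant from `c_grid` by mean balanced accuracy (ties
#' to the smallest constant). The tuned model is refit on the full
#' training set and the held-out subject's predicted label and signed
#' decision value are recorded. Accuracy, sensitivity, specificity and
#' AUC are computed from the pooled held-out predictions; per-feature
#' weights are averaged over the outer folds. Optional permutation
#' testing reruns the entire nested procedure on label permutations.
#'
#' @param x Subjects x features numeric matrix (e.g. frame-network edge
#'   strengths via [apply_edge_mask()]).
#' @param y Class labels; `positive` names the patient class.
#' @param c_grid Candidate regularization constants (default
#'   `10^(-1:3)`; constants below about 0.1 are excluded because with
#'   balanced class weights the weighted hinge loss is knife-edge
#'   degenerate there under leave-one-out, producing all-or-nothing
#'   predictions from floating-point noise).
#' @param inner_folds Inner stratified folds (default 5; must not exceed
#'   the smallest class size of any training split).
#' @param n_permutations Label permutations for significance (default 0:
#'   skip).
#' @param seed Integer seed controlling fold shuffling and permutations.
#' @param positive Positive-class label (default `"patient"`).
#' @param scale `"training"` (z-score per outer fold from training data;
#'   default) or `"none"` (use features as supplied).
#' @param class_weights `"balanced"` (default; per-class weights inversely
#'   proportional to training frequency, removing the leave-one-out
#'   majority-class bias and compensating unequal group sizes) or
#'   `"none"` (plain unweighted hinge loss).
#' @return An object of class `svc_report`: list with `predictions`
#'   (data frame: truth, predicted, decision value per subject),
#'   `accuracy`, `sensitivity`, `specificity`, `auc`, `mean_weights`,
#'   `chosen_c`, and when permuted, `permutation_p` plus the permuted
#'   metric draws.
#' @export
svc_nested_loocv <- function(x, y, c_grid = 10^(-1:3), inner_folds = 5L,
                             n_permutations = 0L, seed = 1L,
                             positive = "patient",
                             scale = c("training", "none"),
                             class_weights = c("balanced", "none")) {
  scale <- match.arg(scale)
  class_weights <- match.arg(class_weights)
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("features must be finite")
  if (!length(c_grid) || any(c_grid <= 0))
    stop("c_grid must be positive and non-empty")
  y <- as.character(y)
  if (!positive %in% y) stop("positive class '", positive, "' absent from labels")
  classes <- c(setdiff(unique(y), positive)[1L], positive)
  if (length(unique(y)) != 2L) stop("exactly two classes required")
  if (min(table(y)) < 2L) stop("each class needs at least 2 subjects")
  set.seed(seed)
  report <- run_nested(x, y, c_grid, inner_folds, positive, classes, scale,
                       class_weights)
  if (n_permutations > 0L) {
    metrics <- c("accuracy", "sensitivity", "specificity", "auc")
    perms <- matrix(NA_real_, n_permutations, length(metrics),
                    dimnames = list(NULL, metrics))
    for (b in seq_len(n_permutations)) {
      yp <- sample(y)
      rp <- run_nested(x, yp, c_grid, inner_folds, positive, classes, scale,
                       class_weights)
      perms[b, ] <- unlist(rp[metrics])
    }
    obs <- unlist(report[metrics])
    report$permutation_p <- vapply(metrics, function(m)
      (1 + sum(perms[, m] >= obs[[m]], na.rm = TRUE)) / (1 + n_permutations),
      0)
    report$permutation_draws <- perms
    report$n_permutations <- n_permutations
  }
  report$seed <- seed
  report
}

run_nested <- function(x, y, c_grid, inner_folds, positive, classes, scale,
                       class_weights = "balanced") {
  n <- nrow(x)
  pred <- character(n); dec <- numeric(n); chosen <- numeric(n)
  W <- matrix(0, n, ncol(x))
  for (s in seq_len(n)) {
    tr_x <- x[-s, , drop = FALSE]; tr_y <- y[-s]
    if (min(table(tr_y)) < inner_folds)
      stop("inner_folds (", inner_folds, ") exceeds smallest class size (",
           min(table(tr_y)), ") in a training split")
    if (scale == "training") {
      mu <- colMeans(tr_x); sdv <- apply(tr_x, 2L, stats::sd)
      sdv[sdv == 0] <- 1
    } else { mu <- rep(0, ncol(x)); sdv <- rep(1, ncol(x)) }
    cost <- tune_cost(tr_x, tr_y, c_grid, inner_folds, positive, scale,
                      class_weights)
    fit <- svm_linear(sweep(sweep(tr_x, 2L, mu), 2L, sdv, "/"),
                      tr_y, cost, classes, class_weights)
    te <- (x[s, ] - mu) / sdv
    out <- predict_svc(fit, matrix(te, 1L), positive)
    pred[s] <- out$label; dec[s] <- out$decision; chosen[s] <- cost
    W[s, ] <- out$weights
  }
  metrics <- performance_metrics(truth = y, predicted = pred, decision = dec,
                                 positive = positive)
  structure(c(list(predictions = data.frame(truth = y, predicted = pred,
                                            decision = dec),
                   mean_weights = stats::setNames(colMeans(W),
                                                  colnames(x)),
                   chosen_c = chosen, positive = positive),
              metrics),
            class = "svc_report")
}

# inner stratified k-fold selection of the cost constant
tune_cost <- function(x, y, c_grid, k, positive, scale, class_weights) {
  if (length(c_grid) == 1L) return(c_grid[1L])
  folds <- integer(length(y))
  for (cl in unique(y)) {
    ix <- sample(which(y == cl))
    folds[ix] <- rep_len(seq_len(k), length(ix))
  }
  classes <- c(setdiff(unique(y), positive)[1L], positive)
  bal_acc <- vapply(c_grid, function(cost) {
    accs <- vapply(seq_len(k), function(f) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L || !any(!tr)) return(NA_real_)
      if (scale == "training") {
        mu <- colMeans(x[tr, , drop = FALSE])
        sdv <- apply(x[tr, , drop = FALSE], 2L, stats::sd); sdv[sdv == 0] <- 1
      } else { mu <- rep(0, ncol(x)); sdv <- rep(1, ncol(x)) }
      xs <- sweep(sweep(x, 2L, mu), 2L, sdv, "/")
      fit <- svm_linear(xs[tr, , drop = FALSE], y[tr], cost, classes,
                        class_weights)
      ph <- predict_svc(fit, xs[!tr, , drop = FALSE], positive)$label
      yt <- y[!tr]
      sens <- mean(ph[yt == positive] == positive)
      spec <- mean(ph[yt != positive] != positive)
      mean(c(sens, spec), na.rm = TRUE)
    }, 0)
    mean(accs, na.rm = TRUE)
  }, 0)
  c_grid[which.max(bal_acc)]  # ties -> smallest constant (grid ascending)
}

svm_linear <- function(x, y, cost, classes, class_weights = "balanced") {
  cw <- if (class_weights == "balanced") {
    tb <- table(factor(y, levels = classes))
    stats::setNames(as.numeric(sum(tb) / (2 * tb)), names(tb))
  } else NULL
  e1071::svm(x, factor(y, levels = classes), kernel = "linear", cost = cost,
             scale = FALSE, class.weights = cw)
}

# label, signed decision value (positive class = positive side) and the
# primal weight vector w = t(coefs) %*% SV, oriented the same way
predict_svc <- function(fit, newdata, positive) {
  pr <- stats::predict(fit, newdata, decision.values = TRUE)
  dv <- drop(attr(pr, "decision.values"))
  w <- drop(t(fit$coefs) %*% fit$SV)
  # e1071 orients decision values toward the first label of the model
  if (strsplit(colnames(attr(pr, "decision.values")), "/")[[1L]][1L] != positive) {
    dv <- -dv; w <- -w
  }
  list(label = as.character(pr), decision = dv, weights = w)
}

#' Classification performance metrics
#'
#' Accuracy, sensitivity (recall of the positive class), specificity and
#' AUC. The AUC is the Mann-Whitney statistic of the decision values
#' (probability a random positive scores above a random negative, ties
#' counted one half).
#'
#' @param truth,predicted Label vectors.
#' @param decision Signed decision values (higher = more positive class).
#' @param positive Positive-class label.
#' @return Named list `accuracy`, `sensitivity`, `specificity`, `auc`
#'   (`NA` with a warning if a class is absent from `truth`).
#' @export
performance_metrics <- function(truth, predicted, decision,
                                positive = "patient") {
  truth <- as.character(truth); predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted),
            length(truth) == length(decision))
  pos <- truth == positive
  acc <- mean(predicted == truth)
  sens <- if (any(pos)) mean(predicted[pos] == positive) else {
    warning("no positive cases in truth; sensitivity undefined"); NA_real_ }
  spec <- if (any(!pos)) mean(predicted[!pos] != positive) else {
    warning("no negative cases in truth; specificity undefined"); NA_real_ }
  auc <- if (any(pos) && any(!pos)) {
    r <- rank(decision)
    n1 <- sum(pos)
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * sum(!pos))
  } else NA_real_
  list(accuracy = acc, sensitivity = sens, specificity = spec, auc = auc)
}

#' Extract a feature matrix for a fixed edge set
#'
#' Subsets a subjects x edges strength matrix to the columns of an edge
#' mask, in mask order - the mechanism for reusing one cohort's frame
#' network as the feature set of another cohort.
#'
#' @param mask A `frame_network`, a character vector of "A-B" edge labels,
#'   or a two-column matrix/data frame of region index pairs.
#' @param strengths Subjects x edges matrix whose columns follow the
#'   canonical edge order (and are labelled when built with an atlas).
#' @param atlas Optional `atlas_spec`, needed to resolve label masks when
#'   `strengths` has no column names.
#' @return The reduced subjects x |mask| matrix, columns in mask order.
#' @export
apply_edge_mask <- function(mask, strengths, atlas = NULL) {
  strengths <- as.matrix(strengths)
  if (inherits(mask, "frame_network")) {
    idx <- mask$edges$edge
    labs <- mask$edges$label
    if (n_edges(mask$n_regions) != ncol(strengths))
      stop("mask is over ", mask$n_regions, " regions; strengths has ",
           ncol(strengths), " edge columns")
  } else if (is.character(mask)) {
    if (!is.null(colnames(strengths))) {
      idx <- match(mask, colnames(strengths))
      # accept either orientation of the hyphenated label
      flip <- is.na(idx)
      if (any(flip)) {
        parts <- strsplit(mask[flip], "-", fixed = TRUE)
        rev_lab <- vapply(parts, function(p)
          paste(rev(p), collapse = "-"), "")
        idx[flip] <- match(rev_lab, colnames(strengths))
      }
    } else {
      if (is.null(atlas)) stop("need an atlas or column names to resolve labels")
      pairs <- match_edge_labels(mask, atlas)
      idx <- pair_to_edge_index(pairs, atlas$n_regions)
    }
    if (anyNA(idx)) stop("edge not present in cohort: ", mask[is.na(idx)][1L])
    labs <- mask
  } else {
    pairs <- as.matrix(mask)[, 1:2, drop = FALSE]
    n <- region_count_for_edges(ncol(strengths))
    idx <- pair_to_edge_index(cbind(pmin(pairs[, 1L], pairs[, 2L]),
                                    pmax(pairs[, 1L], pairs[, 2L])), n)
    labs <- colnames(strengths)[idx] %||% paste0(pairs[, 1L], "-", pairs[, 2L])
  }
  if (any(idx < 1L | idx > ncol(strengths)))
    stop("edge index out of range for this cohort")
  out <- strengths[, idx, drop = FALSE]
  colnames(out) <- labs
  out
}

#' @export
print.svc_report <- function(x, ...) {
  pct <- function(v) sprintf("%.2f%%", 100 * v)
  cat("Linear SVC, nested leave-one-out cross-validation\n")
  cat("  n =", nrow(x$predictions), "subjects,",
      length(x$mean_weights), "features\n")
  cat("  accuracy ", pct(x$accuracy), ", sensitivity ", pct(x$sensitivity),
      ", specificity ", pct(x$specificity),
      sprintf(", AUC %.3f", x$auc), "\n", sep = "")
  if (!is.null(x$permutation_p))
    cat("  permutation p (", x$n_permutations, " perms): ",
        paste(names(x$permutation_p),
              sprintf("%.4g", x$permutation_p), sep = "=", collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' @export
summary.svc_report <- function(object, ...) {
  print(object)
  w <- sort(abs(object$mean_weights), decreasing = TRUE)
  cat("\nTop |mean weight| features:\n")
  print(utils::head(round(object$mean_weights[names(w)], 3), 5L))
  cat("\nchosen cost constants:\n")
  print(table(object$chosen_c))
  invisible(object)
}
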