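#' Covariate-adjusted edgewise group comparison
#'
#' For every edge, fits the linear model
#' `strength ~ intercept + group + covariates` by ordinary least squares
#' (one QR decomposition shared across edges) and reports the
#' patient-minus-control adjusted difference, its t statistic and
#' two-sided p-value with `df = n - p` (p model columns), plus the raw
#' per-group mean and SD. P-values are Benjamini-Hochberg adjusted across
#' the supplied edge family and flagged at `q`. With no covariates the
#' group t is exactly the pooled two-sample t; `method = "welch"` gives
#' the unequal-variance t instead (no covariates allowed).
#'
#' @param strengths Subjects x edges numeric matrix.
#' @param group Vector of `"control"` / `"patient"` labels (or a
#'   two-level factor; the second level is treated as patient).
#' @param covariates Optional data frame of per-subject covariates (e.g.
#'   age, sex, handedness, head motion). Character/factor columns are
#'   expanded to indicators, dropping levels that do not occur.
#' @param q FDR level for significance flags (default 0.05).
#' @param method `"ols"` (regression-adjusted, default) or `"welch"`.
#' @return Data frame of class `edgewise_test` with one row per edge:
#'   `edge`, `label`, `group_coefficient`, `t_stat`, `df`, `p_value`,
#'   `p_adjusted`, `significant`, and per-group `mean`/`sd` columns.
#' @export
edgewise_group_test <- function(strengths, group, covariates = NULL,
                                q = 0.05, method = c("ols", "welch")) {
  method <- match.arg(method)
  strengths <- as.matrix(strengths)
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("group must have exactly two levels")
  lv <- levels(group)
  patient <- if ("patient" %in% lv) "patient" else lv[2L]
  g <- as.numeric(group == patient)
  if (min(table(group)) < 3L) stop("need at least 3 subjects per group")
  if (nrow(strengths) != length(g))
    stop("strengths and group have different subject counts")

  labels <- colnames(strengths) %||% as.character(seq_len(ncol(strengths)))
  m0 <- colMeans(strengths[g == 0, , drop = FALSE])
  s0 <- apply(strengths[g == 0, , drop = FALSE], 2L, stats::sd)
  m1 <- colMeans(strengths[g == 1, , drop = FALSE])
  s1 <- apply(strengths[g == 1, , drop = FALSE], 2L, stats::sd)

  if (method == "welch") {
    if (!is.null(covariates)) stop("welch method does not accept covariates")
    n0 <- sum(g == 0); n1 <- sum(g == 1)
    se <- sqrt(s1^2 / n1 + s0^2 / n0)
    tt <- (m1 - m0) / se
    df <- se^4 / ((s1^2 / n1)^2 / (n1 - 1) + (s0^2 / n0)^2 / (n0 - 1))
    pv <- 2 * stats::pt(-abs(tt), df)
    coefs <- m1 - m0
  } else {
    X <- cbind(`(Intercept)` = 1, group = g)
    if (!is.null(covariates)) {
      covariates <- as.data.frame(covariates, stringsAsFactors = TRUE)
      # categorical covariates: collapse absent levels; a single observed
      # level carries no information and is dropped (e.g. an all-right-
      # handed cohort)
      for (nm in names(covariates))
        if (is.factor(covariates[[nm]]) || is.character(covariates[[nm]])) {
          covariates[[nm]] <- droplevels(as.factor(covariates[[nm]]))
          if (nlevels(covariates[[nm]]) < 2L) covariates[[nm]] <- NULL
        }
      if (ncol(covariates)) {
        cm <- stats::model.matrix(~ ., data = covariates)[, -1L, drop = FALSE]
        X <- cbind(X, cm)
      }
    }
    const <- apply(X[, -1L, drop = FALSE], 2L, function(col) stats::sd(col) == 0)
    if (any(const))
      stop("constant model column: ", colnames(X)[-1L][const][1L])
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      drop_col <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]][1L]
      stop("design matrix is rank deficient (column '", drop_col,
           "' is collinear)")
    }
    df <- nrow(X) - ncol(X)
    if (df < 1L) stop("no residual degrees of freedom")
    beta <- qr.coef(qx, strengths)
    res <- strengths - X %*% beta
    sigma2 <- colSums(res^2) / df
    xtx_inv_gg <- solve(crossprod(X))[2L, 2L]
    coefs <- beta[2L, ]
    tt <- coefs / sqrt(sigma2 * xtx_inv_gg)
    tt[sigma2 == 0] <- 0
    pv <- 2 * stats::pt(-abs(tt), df)
    df <- rep(df, length(tt))
  }
  adj <- fdr_adjust(pv, q)
  out <- data.frame(edge = seq_len(ncol(strengths)), label = labels,
                    group_coefficient = unname(coefs), t_stat = unname(tt),
                    df = unname(df), p_value = unname(pv),
                    p_adjusted = adj$p_adjusted, significant = adj$significant,
                    control_mean = unname(m0), control_sd = unname(s0),
                    patient_mean = unname(m1), patient_sd = unname(s1),
                    row.names = NULL)
  attr(out, "q") <- q
  attr(out, "method") <- method
  class(out) <- c("edgewise_test", "data.frame")
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values with significance flags at level `q`.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return List with `p_adjusted` and logical `significant`
#'   (`p_adjusted <= q`).
#' @export
fdr_adjust <- function(p_values, q = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, significant = adj <= q)
}

#' Direction of significant group differences
#'
#' Labels each edge `decreased` (significant, patient below control),
#' `increased` (significant, patient above control) or `ns`.
#'
#' @param result An `edgewise_test`, or any data frame with
#'   `significant` and `group_coefficient` columns.
#' @return Character vector, one label per edge.
#' @export
classify_direction <- function(result) {
  ifelse(!result$significant, "ns",
         ifelse(result$group_coefficient < 0, "decreased", "increased"))
}

#' Correlate edge strengths with symptom scores
#'
#' Pearson correlation of each designated edge's strength with each
#' symptom score over patients, two-sided p-values, BH adjustment across
#' all tested (edge, score) pairs jointly. A zero-variance score is
#' skipped with a warning and reported with `NA` correlation.
#'
#' @param strengths Patients x edges matrix.
#' @param scores Data frame of named symptom scores (one row per patient).
#' @param edges Columns of `strengths` to test: integer indices or column
#'   labels. Default all columns.
#' @param q FDR level for flags (default 0.05).
#' @return Data frame of class `symptom_correlation` with columns `edge`,
#'   `score`, `r`, `n`, `p_value`, `p_adjusted`, `significant`.
#' @export
symptom_correlation <- function(strengths, scores, edges = NULL, q = 0.05) {
  strengths <- as.matrix(strengths)
  scores <- as.data.frame(scores)
  if (nrow(scores) != nrow(strengths))
    stop("scores and strengths have different subject counts")
  if (is.null(edges)) edges <- seq_len(ncol(strengths))
  if (is.character(edges)) {
    ix <- match(edges, colnames(strengths))
    if (anyNA(ix)) stop("unknown edge label: ", edges[is.na(ix)][1L])
    edges <- ix
  }
  if (nrow(strengths) < 4L) stop("need at least 4 patients with scores")
  grid <- expand.grid(edge = edges, score = names(scores),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(k) {
    x <- strengths[, grid$edge[k]]
    y <- scores[[grid$score[k]]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 4L || stats::sd(y[ok]) == 0 || stats::sd(x[ok]) == 0) {
      warning("constant or insufficient data for edge ", grid$edge[k],
              " x score ", grid$score[k], "; skipped", call. = FALSE)
      return(c(r = NA_real_, n = sum(ok), p = NA_real_))
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    c(r = unname(ct$estimate), n = sum(ok), p = ct$p.value)
  })
  res <- do.call(rbind, res)
  out <- data.frame(edge = grid$edge,
                    label = colnames(strengths)[grid$edge] %||% grid$edge,
                    score = grid$score, r = res[, "r"], n = res[, "n"],
                    p_value = res[, "p"], row.names = NULL)
  ok <- is.finite(out$p_value)
  out$p_adjusted <- NA_real_
  out$p_adjusted[ok] <- fdr_adjust(out$p_value[ok], q)$p_adjusted
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted <= q
  class(out) <- c("symptom_correlation", "data.frame")
  out
}
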