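#' Within-subject edge ranks
#'
#' Ranks one subject's edge strengths in ascending order of the signed
#' Fisher-z value: the weakest edge receives rank 1 and the strongest rank E
#' (number of edges). Ties receive the average of the ranks they span, so
#' every rank vector sums to E (E + 1) / 2 exactly.
#'
#' @param edge_vector Numeric vector of finite edge strengths.
#' @return Numeric rank vector of the same length.
#' @export
rank_edges <- function(edge_vector) {
  if (!is.numeric(edge_vector) || any(!is.finite(edge_vector)))
    stop("edge strengths must be finite numeric values")
  rank(edge_vector, ties.method = "average")
}

#' Per-edge rank-stability statistics across a cohort
#'
#' For every edge, ranks are computed within each subject ([rank_edges()]),
#' then summarized across subjects: mean rank, standard deviation of rank
#' (sample SD, denominator S - 1), their ratio (the coefficient of
#' variation), and the mean Fisher-z strength. The CV is the stability
#' statistic: an edge whose rank barely moves across subjects has a small
#' CV. Division by zero is impossible since every rank is at least 1.
#'
#' @param strengths Numeric matrix, subjects x edges, of Fisher-z strengths
#'   (see [cohort_edge_matrix()]); at least 2 subjects.
#' @return A data frame of class `edge_stability` with one row per edge and
#'   columns `edge`, `mean_rank`, `sd_rank`, `cv`, `mean_strength`.
#' @export
edge_stability <- function(strengths) {
  strengths <- as.matrix(strengths)
  if (nrow(strengths) < 2L)
    stop("rank stability requires at least 2 subjects (SD undefined for 1)")
  ranks <- rank_matrix(strengths)
  mean_rank <- colMeans(ranks)
  sd_rank <- apply(ranks, 2L, stats::sd)
  out <- data.frame(edge = seq_len(ncol(strengths)),
                    mean_rank = mean_rank,
                    sd_rank = sd_rank,
                    cv = sd_rank / mean_rank,
                    mean_strength = colMeans(strengths),
                    row.names = NULL)
  if (!is.null(colnames(strengths))) out$label <- colnames(strengths)
  class(out) <- c("edge_stability", "data.frame")
  out
}

#' Subjects-by-edges rank matrix
#' @param strengths Subjects x edges strength matrix.
#' @return Matrix of within-subject ranks (each row a rank vector).
#' @export
rank_matrix <- function(strengths) {
  strengths <- as.matrix(strengths)
  t(apply(strengths, 1L, rank_edges))
}

#' Number of edges selected at a proportional threshold
#'
#' The selection size follows the full-matrix convention: for N regions the
#' N x N matrix holds N^2 cells, and a fraction f of them - halved because
#' each connection appears twice - gives round(N^2 f / 2) edges, rounding
#' halves up. With N = 90 and f = 0.01 this yields 41 (8100 x 1% / 2),
#' not 4005 x 1% = 40: the convention counts diagonal cells in the base.
#'
#' @param n_regions Number of regions.
#' @param fraction Proportional threshold in (0, 1].
#' @return Integer number of edges.
#' @examples
#' frame_edge_count(90, 0.01)   # 41
#' frame_edge_count(90, 0.005)  # 20
#' @export
frame_edge_count <- function(n_regions, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction <= 0)
    stop("fraction must be a positive number")
  # round half up; the 1e-9 guard keeps binary-representation error in the
  # fraction (e.g. 0.05 arriving as 0.049999...) from flipping a half case
  k <- as.integer(floor(n_regions^2 * fraction / 2 + 0.5 + 1e-9))
  if (k < 1L) stop("fraction ", fraction, " selects no edges")
  if (k > n_edges(n_regions))
    stop("fraction ", fraction, " selects ", k, " edges but only ",
         n_edges(n_regions), " exist")
  k
}

#' Fit a frame network: the most rank-stable edges of a cohort
#'
#' The core estimator. Each subject's Fisher-z edge strengths are converted
#' to within-subject ranks; each edge's coefficient of variation of rank
#' across subjects (SD / mean) measures how stable its position in the
#' strength ordering is. The edges with the smallest CV - the top
#' `fraction` of the connectivity matrix, see [frame_edge_count()] - form
#' the frame network.
#'
#' Ties at the CV cutoff are broken deterministically by preferring larger
#' mean rank (stronger edges), then lower edge index.
#'
#' @param x Subjects x edges strength matrix (see [cohort_edge_matrix()]),
#'   an `edge_stability` table, or a cohort list accepted by
#'   [cohort_edge_matrix()].
#' @param fraction Proportional threshold, default 0.01 (the top 1\%).
#' @param atlas Optional `atlas_spec`; enables labels, degrees and
#'   hemisphere summaries.
#' @param cohort_label Optional cohort name carried into printing.
#' @return An object of class `frame_network`: list with `edges` (data frame
#'   of selected edges sorted by ascending CV, with `i`, `j`, `label`, `cv`,
#'   `mean_rank`, `mean_strength`), `stats` (the full `edge_stability`
#'   table), `fraction`, `n_regions`, `atlas`, `cohort_label`.
#' @examples
#' spec <- cohort_spec(n_control = 8, n_patient = 0, n_regions = 10,
#'                     n_timepoints = 80, seed = 1)
#' co <- generate_cohort(spec)
#' fn <- frame_network(cohort_edge_matrix(co), fraction = 0.1)
#' print(fn)
#' @export
frame_network <- function(x, fraction = 0.01, atlas = NULL,
                          cohort_label = NULL) {
  stats_tab <- if (inherits(x, "edge_stability")) x else {
    if (is.list(x) && !is.matrix(x)) x <- cohort_edge_matrix(x, atlas)
    edge_stability(x)
  }
  n_regions <- region_count_for_edges(nrow(stats_tab))
  if (!is.null(atlas) && atlas$n_regions != n_regions)
    stop("edge count implies ", n_regions, " regions; atlas has ",
         atlas$n_regions)
  k <- frame_edge_count(n_regions, fraction)
  ord <- order(stats_tab$cv, -stats_tab$mean_rank, stats_tab$edge)
  sel <- ord[seq_len(k)]
  pairs <- edge_pairs(n_regions)
  edges <- data.frame(i = pairs[sel, 1L], j = pairs[sel, 2L],
                      stats_tab[sel, c("mean_rank", "sd_rank", "cv",
                                       "mean_strength")],
                      edge = sel, row.names = NULL)
  edges$label <- if (!is.null(atlas)) edge_labels(pairs[sel, , drop = FALSE], atlas)
                 else if (!is.null(stats_tab$label)) stats_tab$label[sel]
                 else paste0(edges$i, "-", edges$j)
  structure(list(edges = edges, stats = stats_tab, fraction = fraction,
                 n_regions = n_regions, atlas = atlas,
                 cohort_label = cohort_label),
            class = "frame_network")
}

# invert E = n(n-1)/2, validating that E is a triangular count
region_count_for_edges <- function(E) {
  n <- as.integer(round((1 + sqrt(1 + 8 * E)) / 2))
  if (n_edges(n) != E)
    stop(E, " edges does not correspond to a whole number of regions")
  n
}

#' @export
print.frame_network <- function(x, ...) {
  cat("Frame network", if (!is.null(x$cohort_label)) paste0("(", x$cohort_label, ")"),
      "\n  ", nrow(x$edges), " edges (top ", format(100 * x$fraction),
      "% of ", x$n_regions, "x", x$n_regions, " matrix)\n", sep = "")
  cat("  CV range of selected edges: ",
      format(signif(range(x$edges$cv), 3), trim = TRUE)[1L], " - ",
      format(signif(range(x$edges$cv), 3), trim = TRUE)[2L], "\n", sep = "")
  if (!is.null(x$atlas)) {
    cl <- table(factor(edge_hemisphere_class(x$atlas,
                                             as.matrix(x$edges[, c("i", "j")])),
                       levels = c("interhemispheric", "intra_left",
                                  "intra_right", "other")))
    cat("  hemisphere classes:",
        paste(names(cl), cl, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.frame_network <- function(object, ...) {
  cat("Selected edges (ascending CV):\n")
  print(utils::head(object$edges[, c("label", "cv", "mean_rank",
                                     "mean_strength")], 15L))
  if (nrow(object$edges) > 15L)
    cat("  ... and", nrow(object$edges) - 15L, "more\n")
  if (!is.null(object$atlas)) {
    cat("\nLateralization:\n")
    print(lateralization_summary(object))
    cat("\nHighest-degree regions:\n")
    deg <- node_degrees(object)
    print(utils::head(deg[order(-deg$degree), ], 5L), row.names = FALSE)
  }
  invisible(object)
}

#' Scatter of mean rank against rank SD
#'
#' The diagnostic view of rank stability: each point is an edge, frame
#' edges highlighted. In control-like cohorts the cloud shows a negative
#' association - stronger (higher-ranked) edges have smaller rank SD.
#'
#' @param x A `frame_network`.
#' @param ... Passed to [plot()].
#' @export
plot.frame_network <- function(x, ...) {
  d <- rank_sd_diagnostic(x)
  plot(d$mean_rank, d$sd_rank, pch = 16, cex = 0.4,
       col = ifelse(d$selected, "red", "grey50"),
       xlab = "mean rank across subjects", ylab = "SD of rank", ...)
  graphics::legend("topleft", pch = 16, col = c("grey50", "red"),
                   legend = c("edge", "frame edge"), bty = "n")
  invisible(d)
}

#' Frame networks across a range of proportional thresholds
#'
#' Reuses one set of stability statistics, so the selections are nested:
#' the edge set at a smaller fraction is contained in that at any larger
#' fraction.
#'
#' @param x Strength matrix or `edge_stability` table.
#' @param fractions Numeric vector of thresholds.
#' @param ... Passed on to [frame_network()].
#' @return A list of `frame_network` objects, one per fraction.
#' @export
threshold_sweep <- function(x, fractions, ...) {
  stats_tab <- if (inherits(x, "edge_stability")) x else edge_stability(x)
  lapply(fractions, function(f) frame_network(stats_tab, fraction = f, ...))
}

#' Intersection of two frame networks
#'
#' @param a,b `frame_network` objects over the same atlas/region count.
#' @return Data frame of the shared edges (columns `i`, `j`, `label`),
#'   ordered by edge index.
#' @export
network_overlap <- function(a, b) {
  stopifnot(inherits(a, "frame_network"), inherits(b, "frame_network"))
  if (a$n_regions != b$n_regions)
    stop("frame networks are over different atlases (",
         a$n_regions, " vs ", b$n_regions, " regions)")
  common <- sort(intersect(a$edges$edge, b$edges$edge))
  ix <- match(common, a$edges$edge)
  data.frame(i = a$edges$i[ix], j = a$edges$j[ix],
             label = a$edges$label[ix], row.names = NULL)
}

#' Node degrees within a frame network
#'
#' @param network A `frame_network` (with an atlas for labels, or not).
#' @return Data frame `region`, `label`, `degree`, one row per region; the
#'   degrees sum to twice the number of edges.
#' @export
node_degrees <- function(network) {
  stopifnot(inherits(network, "frame_network"))
  n <- network$n_regions
  deg <- tabulate(c(network$edges$i, network$edges$j), nbins = n)
  data.frame(region = seq_len(n),
             label = if (!is.null(network$atlas)) network$atlas$labels
                     else as.character(seq_len(n)),
             degree = deg, row.names = NULL)
}

#' Hemispheric composition of a frame network
#'
#' Counts selected edges by hemisphere class and reports the left-minus-
#' right difference of intra-hemispheric counts (positive = left-lateralized).
#'
#' @param network A `frame_network` fitted with an atlas.
#' @param atlas Optional `atlas_spec` overriding the one stored in the fit.
#' @return Data frame with `interhemispheric`, `intra_left`, `intra_right`,
#'   `other` counts and `left_minus_right`.
#' @export
lateralization_summary <- function(network, atlas = NULL) {
  stopifnot(inherits(network, "frame_network"))
  atlas <- atlas %||% network$atlas
  if (is.null(atlas)) stop("an atlas is required for lateralization counts")
  cl <- factor(edge_hemisphere_class(atlas,
                                     as.matrix(network$edges[, c("i", "j")])),
               levels = c("interhemispheric", "intra_left", "intra_right",
                          "other"))
  tab <- as.list(table(cl))
  data.frame(interhemispheric = tab$interhemispheric,
             intra_left = tab$intra_left, intra_right = tab$intra_right,
             other = tab$other,
             left_minus_right = tab$intra_left - tab$intra_right)
}

#' Rank-versus-SD diagnostic table
#'
#' One row per edge with its mean rank, rank SD and whether it was
#' selected, plus (as an attribute) the Pearson correlation between mean
#' rank and rank SD - negative when stronger edges are also more stable.
#' The correlation is `NA` when either quantity is constant.
#'
#' @param network A `frame_network`.
#' @return Data frame with attribute `rank_sd_correlation`.
#' @export
rank_sd_diagnostic <- function(network) {
  stopifnot(inherits(network, "frame_network"))
  s <- network$stats
  out <- data.frame(edge = s$edge, mean_rank = s$mean_rank,
                    sd_rank = s$sd_rank,
                    selected = s$edge %in% network$edges$edge)
  r <- if (stats::sd(s$mean_rank) == 0 || stats::sd(s$sd_rank) == 0) NA_real_
       else stats::cor(s$mean_rank, s$sd_rank)
  attr(out, "rank_sd_correlation") <- r
  out
}

#' Write a frame network as a delimited edge list
#'
#' Writes `label_i, label_j, cv, mean_rank, mean_strength` rows plus a JSON
#' sidecar recording the threshold and cohort label.
#'
#' @param network A `frame_network`.
#' @param path Output path for the edge list (tab-separated).
#' @return `path`, invisibly.
#' @export
write_frame_network <- function(network, path) {
  stopifnot(inherits(network, "frame_network"))
  lab <- strsplit(network$edges$label, "-", fixed = TRUE)
  tab <- data.frame(label_i = vapply(lab, `[`, "", 1L),
                    label_j = vapply(lab, `[`, "", 2L),
                    cv = network$edges$cv,
                    mean_rank = network$edges$mean_rank,
                    mean_strength = network$edges$mean_strength)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(fraction = network$fraction,
                  n_regions = network$n_regions,
                  n_edges = nrow(network$edges),
                  cohort = network$cohort_label)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
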