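#' Read an atlas node table
#'
#' Parses a delimited node table defining the parcellation used throughout an
#' analysis: one row per region, in the order that indexes every connectivity
#' matrix. Hemisphere membership is inferred from the conventional AAL-style
#' label suffix (`_L` left, `_R` right, anything else midline/unassigned),
#' unless an explicit `hemisphere` column overrides it.
#'
#' @param path Path to a tab- or comma-delimited text file with columns
#'   `index` and `label`, and optionally `hemisphere` (values `L`, `R`, `M`).
#' @return An object of class `atlas_spec`: a list with `n_regions`,
#'   `labels` (character, in table order) and `hemisphere` (factor with
#'   levels L/R/M).
#' @examples
#' atlas <- aal90_atlas()
#' table(atlas$hemisphere)
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) stop("atlas node table not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "")
  if (!all(c("index", "label") %in% names(tab)))
    stop("atlas node table must have columns 'index' and 'label'")
  tab <- tab[order(tab$index), , drop = FALSE]
  hemi <- if ("hemisphere" %in% names(tab)) tab$hemisphere else NULL
  atlas_spec(tab$label, hemisphere = hemi)
}

#' Construct an atlas specification from region labels
#'
#' @param labels Character vector of unique, non-empty region labels in
#'   atlas order.
#' @param hemisphere Optional per-region codes in `L`, `R`, `M`; if `NULL`,
#'   inferred from trailing `_L` / `_R` (case-sensitive).
#' @return An `atlas_spec` object.
#' @export
atlas_spec <- function(labels, hemisphere = NULL) {
  labels <- as.character(labels)
  if (any(is.na(labels) | !nzchar(labels))) {
    bad <- which(is.na(labels) | !nzchar(labels))
    stop("empty region label at row ", bad[1L])
  }
  if (anyDuplicated(labels)) {
    dup <- labels[duplicated(labels)][1L]
    stop("duplicate region label '", dup, "' at row ",
         which(labels == dup)[2L])
  }
  if (is.null(hemisphere)) {
    hemisphere <- ifelse(endsWith(labels, "_L"), "L",
                         ifelse(endsWith(labels, "_R"), "R", "M"))
  } else {
    hemisphere <- as.character(hemisphere)
    if (length(hemisphere) != length(labels))
      stop("hemisphere must have one code per label")
    if (!all(hemisphere %in% c("L", "R", "M")))
      stop("hemisphere codes must be 'L', 'R' or 'M'")
  }
  structure(list(n_regions = length(labels), labels = labels,
                 hemisphere = factor(hemisphere, levels = c("L", "R", "M"))),
            class = "atlas_spec")
}

#' The bundled 90-region AAL atlas
#'
#' Convenience accessor for the packaged AAL90 node table (45 left / 45
#' right cerebral regions, labels suffixed `_L` / `_R`).
#'
#' @return An `atlas_spec` with 90 regions.
#' @export
aal90_atlas <- function() {
  read_atlas(system.file("extdata", "aal90_nodes.tsv", package = "framenet",
                         mustWork = TRUE))
}

#' @export
print.atlas_spec <- function(x, ...) {
  cat("Atlas with", x$n_regions, "regions (",
      sum(x$hemisphere == "L"), "L /", sum(x$hemisphere == "R"), "R /",
      sum(x$hemisphere == "M"), "midline )\n")
  invisible(x)
}

#' Enumerate the unordered region pairs of an atlas
#'
#' Defines the canonical edge universe: every distinct unordered pair (i, j),
#' i < j, in row-major upper-triangle order. All edge vectors, rank matrices
#' and frame networks use this ordering.
#'
#' @param n_regions Number of regions (>= 2).
#' @return Integer matrix with `n_regions (n_regions - 1) / 2` rows and
#'   columns `i`, `j` (1-based region indices, i < j).
#' @examples
#' edge_pairs(3)  # (1,2), (1,3), (2,3)
#' nrow(edge_pairs(90))  # 4005
#' @export
edge_pairs <- function(n_regions) {
  n_regions <- as.integer(n_regions)
  if (length(n_regions) != 1L || is.na(n_regions) || n_regions < 2L)
    stop("n_regions must be a single integer >= 2")
  i <- rep.int(seq_len(n_regions - 1L), (n_regions - 1L):1L)
  j <- sequence((n_regions - 1L):1L) + i
  cbind(i = i, j = j)
}

#' Number of edges among n regions
#' @param n_regions Number of regions.
#' @return `n_regions (n_regions - 1) / 2`.
#' @export
n_edges <- function(n_regions) as.integer(n_regions * (n_regions - 1) / 2)

#' Hemispheric class of an edge
#'
#' Classifies an edge by the hemispheres of its endpoints: `interhemispheric`
#' (one L, one R), `intra_left`, `intra_right`, or `other` when either
#' endpoint is midline/unassigned. Symmetric in the pair.
#'
#' @param atlas An `atlas_spec`.
#' @param pair Integer vector of two region indices, or a two-column matrix
#'   of pairs.
#' @return Character vector of classes, one per pair.
#' @export
edge_hemisphere_class <- function(atlas, pair) {
  stopifnot(inherits(atlas, "atlas_spec"))
  if (is.null(dim(pair))) pair <- matrix(pair, ncol = 2L)
  if (any(pair < 1L | pair > atlas$n_regions))
    stop("region index out of range for this atlas")
  h1 <- as.character(atlas$hemisphere[pair[, 1L]])
  h2 <- as.character(atlas$hemisphere[pair[, 2L]])
  out <- rep("other", nrow(pair))
  out[h1 == "L" & h2 == "L"] <- "intra_left"
  out[h1 == "R" & h2 == "R"] <- "intra_right"
  out[(h1 == "L" & h2 == "R") | (h1 == "R" & h2 == "L")] <- "interhemispheric"
  out
}

#' Format edge labels in "LabelA-LabelB" convention
#' @param pairs Two-column matrix of region indices.
#' @param atlas An `atlas_spec`.
#' @return Character vector of hyphenated label pairs.
#' @export
edge_labels <- function(pairs, atlas) {
  if (is.null(dim(pairs))) pairs <- matrix(pairs, ncol = 2L)
  paste(atlas$labels[pairs[, 1L]], atlas$labels[pairs[, 2L]], sep = "-")
}

# resolve "A-B" labels (either orientation) to canonical pair rows of the
# atlas edge universe; errors name the first unknown pair
match_edge_labels <- function(labels, atlas) {
  parts <- strsplit(labels, "-", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) stop("malformed edge label: ", labels[bad[1L]])
  i <- match(vapply(parts, `[`, "", 1L), atlas$labels)
  j <- match(vapply(parts, `[`, "", 2L), atlas$labels)
  if (anyNA(i) || anyNA(j)) {
    k <- which(is.na(i) | is.na(j))[1L]
    stop("edge refers to unknown region: ", labels[k])
  }
  cbind(i = pmin(i, j), j = pmax(i, j))
}

# map canonical (i<j) pairs to positions in the row-major edge ordering
pair_to_edge_index <- function(pairs, n_regions) {
  if (is.null(dim(pairs))) pairs <- matrix(pairs, ncol = 2L)
  i <- pairs[, 1L]; j <- pairs[, 2L]
  if (any(i >= j) || any(i < 1L) || any(j > n_regions))
    stop("pairs must satisfy 1 <= i < j <= n_regions")
  as.integer((i - 1L) * n_regions - i * (i - 1L) / 2 + (j - i))
}
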