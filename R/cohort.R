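#' Specify a synthetic two-group cohort
#'
#' Defines a latent-factor generative model for regional time series plus
#' demographic covariates and symptom scores, used to exercise the whole
#' pipeline without real scans. Each planted edge (a, b) contributes a
#' shared unit-variance latent series loaded with `sqrt(lambda)` onto both
#' regions, on top of independent white noise, so the population
#' correlation of a planted pair is `lambda / (lambda + sigma^2)` (when
#' each region carries one factor) - monotone in lambda and positive
#' semidefinite by construction. Patients modify selected loadings through
#' multiplicative effects. Between-subject variability enters as truncated
#' normal jitter on each loading, which makes planted edges stable and
#' strong (low rank-CV) while unplanted edges have noisy ranks.
#'
#' Defaults emulate a medicated-schizophrenia case-control study: 71
#' controls vs 60 patients, 90 AAL regions, 140 timepoints; all 45
#' homotopic (X_L, X_R) pairs planted as the strong stable backbone;
#' in patients a subset of homotopic edges is weakened and a left-frontal
#' clique is strengthened (left-lateralized concentration); covariates
#' (age, sex, handedness, head motion) follow the published cohort
#' demographics, with patient head motion exceeding control motion so
#' covariate adjustment is exercised; a designated homotopic edge
#' (supplementary motor area) drives a PANSS-style negative-symptom score
#' with target correlation 0.36.
#'
#' @param n_control,n_patient Subjects per group.
#' @param n_regions Number of regions.
#' @param n_timepoints Timepoints per subject (>= 10).
#' @param planted_edges Data frame `i`, `j`, `lambda` with loadings in
#'   (0, 1); `NULL` selects the default backbone (homotopic pairs when an
#'   atlas with `_L`/`_R` labels is given, else disjoint consecutive
#'   pairs), loadings spread over 0.5-0.9.
#' @param effect_edges Data frame `i`, `j`, `multiplier` (> 0) applied to
#'   the planted loading in the patient group; pairs must be planted.
#'   `NULL` selects the default patient alteration (see Details) when
#'   patients are requested with the bundled AAL90 atlas, else none.
#' @param baseline_noise_sd Region noise SD sigma (default 0.4).
#' @param jitter_sd SD of the per-subject truncated normal jitter on each
#'   loading (default 0.05).
#' @param covariate_params Per-group list of covariate distributions; see
#'   [default_covariate_params()].
#' @param symptom_edge `NULL`, or `list(i =, j =, rho =, score = "name")`
#'   naming the edge whose realized strength drives the symptom score and
#'   the target correlation (|rho| < 1).
#' @param atlas Optional `atlas_spec` (defaults to the bundled AAL90 atlas
#'   when `n_regions == 90`).
#' @param seed Integer seed; the same spec and seed reproduce the cohort
#'   exactly.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 71, n_patient = 60, n_regions = 90,
                        n_timepoints = 140, planted_edges = NULL,
                        effect_edges = NULL, baseline_noise_sd = 0.4,
                        jitter_sd = 0.05, covariate_params = NULL,
                        symptom_edge = NULL, atlas = NULL, seed = 1) {
  if (n_timepoints < 10L) stop("n_timepoints must be at least 10")
  if (baseline_noise_sd <= 0) stop("baseline_noise_sd must be positive")
  if (jitter_sd < 0) stop("jitter_sd must be nonnegative")
  if (is.null(atlas) && n_regions == 90) atlas <- aal90_atlas()
  if (!is.null(atlas) && atlas$n_regions != n_regions)
    stop("atlas has ", atlas$n_regions, " regions, spec asks for ", n_regions)
  aal_default <- !is.null(atlas) && n_regions == 90 &&
    identical(atlas$labels, aal90_atlas()$labels)

  if (is.null(planted_edges)) {
    hp <- homotopic_pairs(atlas, n_regions)
    planted_edges <- data.frame(i = hp[, 1L], j = hp[, 2L],
                                lambda = seq(0.5, 0.9,
                                             length.out = max(nrow(hp), 1L)))
    if (n_patient > 0 && aal_default) {
      # left-frontal clique, weak in controls, strengthened in patients
      lf <- left_frontal_clique(atlas)
      planted_edges <- rbind(planted_edges,
                             data.frame(i = lf[, 1L], j = lf[, 2L],
                                        lambda = 0.15))
    }
  }
  planted_edges <- validate_pairs(planted_edges, n_regions, "planted_edges")
  if (nrow(planted_edges) &&
      (any(planted_edges$lambda <= 0) || any(planted_edges$lambda >= 1)))
    stop("planted loadings must lie strictly in (0, 1)")

  if (is.null(effect_edges)) {
    effect_edges <- if (n_patient > 0 && aal_default)
      default_patient_effects(atlas, planted_edges)
    else data.frame(i = integer(), j = integer(), multiplier = numeric())
  } else {
    effect_edges <- validate_pairs(effect_edges, n_regions, "effect_edges")
  }
  if (nrow(effect_edges)) {
    if (any(effect_edges$multiplier <= 0)) stop("effect multipliers must be > 0")
    key_p <- paste(planted_edges$i, planted_edges$j)
    key_e <- paste(effect_edges$i, effect_edges$j)
    if (!all(key_e %in% key_p))
      stop("effect edge (", key_e[!key_e %in% key_p][1L],
           ") is not a planted edge")
  }

  # lambda of an edge that is planted only through an effect multiplier > 1
  # must still be < 1 in the patient group
  if (is.null(covariate_params)) covariate_params <- default_covariate_params()
  if (is.null(symptom_edge) && n_patient > 0 && aal_default) {
    sma <- match(c("Supp_Motor_Area_L", "Supp_Motor_Area_R"), atlas$labels)
    symptom_edge <- list(i = sma[1L], j = sma[2L], rho = 0.36,
                         score = "panss_negative")
  }
  if (!is.null(symptom_edge)) {
    if (abs(symptom_edge$rho) >= 1)
      stop("target symptom correlation must satisfy |rho| < 1")
    if (symptom_edge$i < 1 || symptom_edge$j > n_regions)
      stop("symptom edge out of range")
  }
  structure(list(n_control = as.integer(n_control),
                 n_patient = as.integer(n_patient),
                 n_regions = as.integer(n_regions),
                 n_timepoints = as.integer(n_timepoints),
                 planted_edges = planted_edges, effect_edges = effect_edges,
                 baseline_noise_sd = baseline_noise_sd, jitter_sd = jitter_sd,
                 covariate_params = covariate_params,
                 symptom_edge = symptom_edge, atlas = atlas,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

validate_pairs <- function(d, n_regions, what) {
  d <- as.data.frame(d)
  if (!nrow(d)) return(d)
  i <- pmin(d$i, d$j); j <- pmax(d$i, d$j)
  if (any(i < 1L) || any(j > n_regions) || any(i == j))
    stop(what, " contains an invalid region pair")
  d$i <- as.integer(i); d$j <- as.integer(j)
  if (anyDuplicated(paste(d$i, d$j))) stop(what, " contains duplicate pairs")
  d
}

homotopic_pairs <- function(atlas, n_regions) {
  if (!is.null(atlas)) {
    left <- which(endsWith(atlas$labels, "_L"))
    stems <- sub("_L$", "", atlas$labels[left])
    right <- match(paste0(stems, "_R"), atlas$labels)
    keep <- !is.na(right)
    if (any(keep))
      return(cbind(pmin(left[keep], right[keep]),
                   pmax(left[keep], right[keep])))
  }
  k <- seq_len(n_regions %/% 2L)
  cbind(2L * k - 1L, 2L * k)
}

#' Default demographic covariate distributions
#'
#' Per-group parameters for age (normal), sex (probability male),
#' handedness (probabilities right/left/both) and a mean-framewise-
#' displacement-like head-motion summary (normal truncated positive),
#' matching the medicated case-control cohort demographics: controls aged
#' 36.23 +/- 11.63 with motion 0.15 +/- 0.08, patients 38.77 +/- 16.28
#' with larger motion 0.20 +/- 0.11.
#'
#' @return Named list with `control` and `patient` sublists.
#' @export
default_covariate_params <- function() {
  list(control = list(age_mean = 36.23, age_sd = 11.63, p_male = 48 / 71,
                      p_hand = c(R = 68, L = 1, both = 2) / 71,
                      motion_mean = 0.15, motion_sd = 0.08),
       patient = list(age_mean = 38.77, age_sd = 16.28, p_male = 48 / 60,
                      p_hand = c(R = 48, L = 10, both = 2) / 60,
                      motion_mean = 0.20, motion_sd = 0.11))
}

# patient alteration bundled with the AAL90 default: weaken eight homotopic
# backbone edges and strengthen the left-frontal clique planted weak in
# controls, so patient frame networks concentrate on the left frontal lobe
default_patient_effects <- function(atlas, planted) {
  weak_stems <- c("Frontal_Sup", "Supp_Motor_Area", "Insula", "Cuneus",
                  "Precuneus", "Postcentral", "Temporal_Mid",
                  "Frontal_Sup_Medial")
  li <- match(paste0(weak_stems, "_L"), atlas$labels)
  ri <- match(paste0(weak_stems, "_R"), atlas$labels)
  weak <- data.frame(i = pmin(li, ri), j = pmax(li, ri), multiplier = 0.7)
  lf <- left_frontal_clique(atlas)
  strong <- data.frame(i = lf[, 1L], j = lf[, 2L], multiplier = 4)
  out <- rbind(weak, strong)
  out[paste(out$i, out$j) %in% paste(planted$i, planted$j), , drop = FALSE]
}

left_frontal_clique <- function(atlas) {
  rg <- match(c("Frontal_Sup_L", "Frontal_Mid_L", "Frontal_Sup_Medial_L",
                "Precentral_L"), atlas$labels)
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4))
  cbind(pmin(rg[pairs[, 1L]], rg[pairs[, 2L]]),
        pmax(rg[pairs[, 1L]], rg[pairs[, 2L]]))
}

#' Population correlation matrix implied by a cohort spec
#'
#' Closed form for the latent-factor model: region variance is
#' `sigma^2 + sum of incident loadings`, the covariance of a planted pair
#' is its loading, everything else zero. Serves as the analytic oracle for
#' the simulator.
#'
#' @param spec A `cohort_spec`.
#' @param group `"control"` or `"patient"` (applies effect multipliers).
#' @return Symmetric N x N correlation matrix with unit diagonal.
#' @export
population_correlation <- function(spec, group = c("control", "patient")) {
  stopifnot(inherits(spec, "cohort_spec"))
  group <- match.arg(group)
  lam <- group_lambdas(spec, group)
  n <- spec$n_regions
  S <- diag(spec$baseline_noise_sd^2, n)
  if (nrow(lam)) {
    for (k in seq_len(nrow(lam))) {
      a <- lam$i[k]; b <- lam$j[k]; l <- lam$lambda[k]
      S[a, a] <- S[a, a] + l; S[b, b] <- S[b, b] + l
      S[a, b] <- S[a, b] + l; S[b, a] <- S[b, a] + l
    }
  }
  stats::cov2cor(S)
}

group_lambdas <- function(spec, group) {
  lam <- spec$planted_edges
  if (group == "patient" && nrow(spec$effect_edges) && nrow(lam)) {
    key <- match(paste(spec$effect_edges$i, spec$effect_edges$j),
                 paste(lam$i, lam$j))
    lam$lambda[key] <- pmin(lam$lambda[key] * spec$effect_edges$multiplier,
                            0.99)
  }
  lam
}

# truncated normal via inverse-CDF, exact and vectorized
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), length.out = n))
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

#' Generate a synthetic cohort
#'
#' Draws every subject's regional time series from the latent-factor model
#' of the spec (controls first, then patients), together with demographic
#' covariates; when a symptom edge is designated, patients additionally
#' receive an integer PANSS-style score constructed from the realized
#' Fisher-z strength of that edge so that its correlation with the score
#' matches the target rho (up to rounding).
#'
#' @param spec A `cohort_spec`.
#' @return A list of class `cohort`; each element is a subject record with
#'   `subject_id`, `group`, `age`, `sex`, `handedness`, `head_motion`,
#'   `symptom_scores` (patients only, when requested) and `timeseries`
#'   (timepoints x regions, columns named by atlas labels when available).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  groups <- rep(c("control", "patient"), c(spec$n_control, spec$n_patient))
  n <- length(groups)
  ids <- sprintf("%s%03d", ifelse(groups == "control", "HC", "SZ"),
                 unlist(lapply(c(spec$n_control, spec$n_patient), seq_len)))
  subjects <- vector("list", n)
  for (s in seq_len(n)) {
    g <- groups[s]
    lam <- group_lambdas(spec, g)
    if (nrow(lam) && spec$jitter_sd > 0)
      lam$lambda <- rtruncnorm(nrow(lam), lam$lambda, spec$jitter_sd,
                               0.01, 0.99)
    ts <- matrix(stats::rnorm(spec$n_timepoints * spec$n_regions,
                              sd = spec$baseline_noise_sd),
                 spec$n_timepoints, spec$n_regions)
    if (nrow(lam)) {
      f <- matrix(stats::rnorm(spec$n_timepoints * nrow(lam)),
                  spec$n_timepoints, nrow(lam))
      for (k in seq_len(nrow(lam))) {
        load <- sqrt(lam$lambda[k]) * f[, k]
        ts[, lam$i[k]] <- ts[, lam$i[k]] + load
        ts[, lam$j[k]] <- ts[, lam$j[k]] + load
      }
    }
    if (!is.null(spec$atlas)) colnames(ts) <- spec$atlas$labels
    cp <- spec$covariate_params[[g]]
    subjects[[s]] <- list(
      subject_id = ids[s], group = g,
      age = round(rtruncnorm(1L, cp$age_mean, cp$age_sd, 0, Inf), 1L),
      sex = sample(c("M", "F"), 1L, prob = c(cp$p_male, 1 - cp$p_male)),
      handedness = sample(names(cp$p_hand), 1L, prob = cp$p_hand),
      head_motion = round(rtruncnorm(1L, cp$motion_mean, cp$motion_sd,
                                     0.01, Inf), 4L),
      symptom_scores = NULL, timeseries = ts)
  }
  if (!is.null(spec$symptom_edge) && spec$n_patient > 0)
    subjects <- add_symptom_scores(subjects, spec)
  structure(subjects, class = "cohort")
}

# PANSS-negative-like integer score (7 items x 1-7, range 7-49) tied to the
# realized Fisher-z strength of the designated edge at the target rho
add_symptom_scores <- function(subjects, spec) {
  se <- spec$symptom_edge
  pat <- which(vapply(subjects, function(s) s$group, "") == "patient")
  z <- vapply(pat, function(k) {
    ts <- subjects[[k]]$timeseries
    atanh(min(max(stats::cor(ts[, se$i], ts[, se$j]), -1 + 1e-7), 1 - 1e-7))
  }, 0)
  zs <- if (stats::sd(z) > 0) (z - mean(z)) / stats::sd(z) else z * 0
  # noise orthogonalized to the edge strength and unit-scaled, so the
  # pre-rounding sample correlation equals rho by construction
  eps <- stats::rnorm(length(pat))
  if (length(pat) >= 3L && stats::sd(zs) > 0) {
    eps <- eps - mean(eps) - zs * stats::cov(eps, zs) / stats::var(zs)
    if (stats::sd(eps) > 0) eps <- eps / stats::sd(eps)
  }
  raw <- se$rho * zs + sqrt(1 - se$rho^2) * eps
  score <- pmin(pmax(round(20 + 5 * raw), 7L), 49L)
  for (k in seq_along(pat))
    subjects[[pat[k]]]$symptom_scores <-
      stats::setNames(list(score[k]), se$score %||% "symptom")
  subjects
}

#' Phenotype table of a cohort
#'
#' @param cohort A `cohort` list.
#' @return Data frame with one row per subject (id, group, covariates and
#'   any symptom scores).
#' @export
cohort_phenotypes <- function(cohort) {
  base <- do.call(rbind, lapply(cohort, function(s)
    data.frame(subject_id = s$subject_id, group = s$group, age = s$age,
               sex = s$sex, handedness = s$handedness,
               head_motion = s$head_motion)))
  scores <- unique(unlist(lapply(cohort, function(s) names(s$symptom_scores))))
  for (nm in scores)
    base[[nm]] <- vapply(cohort, function(s)
      if (!is.null(s$symptom_scores[[nm]])) as.numeric(s$symptom_scores[[nm]])
      else NA_real_, 0)
  base
}

#' @export
print.cohort <- function(x, ...) {
  ph <- cohort_phenotypes(x)
  cat("Synthetic cohort:", nrow(ph), "subjects (",
      sum(ph$group == "control"), "control /", sum(ph$group == "patient"),
      "patient ),", nrow(x[[1L]]$timeseries), "timepoints x",
      ncol(x[[1L]]$timeseries), "regions\n")
  invisible(x)
}

#' Write a cohort to delimited text files
#'
#' One `<subject_id>_timeseries.tsv` per subject (timepoints x regions,
#' header = region labels) plus `phenotypes.tsv`.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort)
    utils::write.table(s$timeseries,
                       file.path(dir, paste0(s$subject_id, "_timeseries.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort_phenotypes(cohort),
                     file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
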