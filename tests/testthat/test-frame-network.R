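test_that("rank_edges ranks ascending on signed strength with average ties", {
  expect_equal(rank_edges(c(0.2, 0.5, 0.1)), c(2, 3, 1))
  expect_equal(rank_edges(c(0.3, 0.3)), c(1.5, 1.5))
  expect_error(rank_edges(c(1, NA)), "finite")
  set.seed(11)
  v <- rnorm(50)
  r <- rank_edges(v)
  # distinct values: ranks are the permutation implied by sorting
  expect_identical(sort(r), as.numeric(1:50))
  expect_identical(order(v), order(r))
  # negative (anticorrelated) edges rank lowest, not by magnitude
  expect_equal(rank_edges(c(-0.9, 0.1, 0.5))[1], 1)
})

test_that("rank matrix rows always sum to E(E+1)/2, ties included", {
  set.seed(12)
  m <- matrix(rnorm(5 * 10), 5)
  m[2, c(1, 4, 7)] <- 0.5  # force ties
  rm_ <- rank_matrix(m)
  expect_equal(unname(rowSums(rm_)), rep(10 * 11 / 2, 5))
  expect_true(all(rm_ >= 1 & rm_ <= 10))
})

test_that("stability statistics match the direct formula", {
  # permutation rows: values equal ranks; edge 10 and 30 swapped in row 2
  row1 <- as.numeric(1:40)
  row2 <- row1; row2[c(10, 30)] <- row2[c(30, 10)]
  st <- edge_stability(rbind(row1, row2))
  expect_equal(st$mean_rank[10], 20)
  expect_equal(st$sd_rank[10], sqrt(200), tolerance = 1e-6)   # 14.14214
  expect_equal(st$cv[10], sqrt(200) / 20, tolerance = 1e-6)   # 0.7071068
  # untouched edges have identical ranks in both subjects
  expect_equal(st$sd_rank[1], 0)
  expect_equal(st$cv[1], 0)
  expect_equal(st$mean_strength[10], 20)  # mean of raw values 10 and 30
  expect_error(edge_stability(matrix(1:4, 1)), "at least 2 subjects")
})

test_that("stability is invariant to subject order and common rescaling", {
  set.seed(13)
  m <- matrix(rnorm(6 * n_edges(6)), 6)
  st <- edge_stability(m)
  expect_equal(st, edge_stability(m[sample(6), ]))
  st2 <- edge_stability(3.7 * m)
  expect_equal(st$cv, st2$cv)
  expect_equal(st$mean_rank, st2$mean_rank)
})

test_that("frame_edge_count follows the full-matrix rounding convention", {
  expect_identical(frame_edge_count(90, 0.01), 41L)   # 40.5 rounds up
  expect_identical(frame_edge_count(90, 0.005), 20L)  # 20.25 rounds down
  expect_identical(frame_edge_count(90, 0.05), 203L)  # 202.5 rounds up
  expect_error(frame_edge_count(3, 0.9), "only")
  expect_error(frame_edge_count(90, -0.1), "positive")
})

test_that("frame selection agrees with the brute-force oracle on small cohorts", {
  set.seed(14)
  for (draw in 1:25) {
    S <- sample(2:5, 1); N <- sample(3:6, 1)
    m <- matrix(rnorm(S * n_edges(N)), S)
    f <- runif(1, 0.2, 0.9)
    k <- floor(N^2 * f / 2 + 0.5)
    if (k < 1 || k > n_edges(N)) next
    fn <- frame_network(m, fraction = f)
    expect_identical(sort(fn$edges$edge), brute_force_frame(m, f))
  }
})

test_that("selection is deterministic and respects the CV cutoff", {
  set.seed(15)
  m <- matrix(rnorm(8 * n_edges(8)), 8)
  fn1 <- frame_network(m, fraction = 0.2)
  fn2 <- frame_network(m[sample(8), ], fraction = 0.2)
  expect_identical(fn1$edges$edge, fn2$edges$edge)
  # max selected CV <= min unselected CV
  sel <- fn1$edges$edge
  expect_lte(max(fn1$stats$cv[sel]), min(fn1$stats$cv[-sel]))
  # scale invariance of the whole fit
  fn3 <- frame_network(5 * m, fraction = 0.2)
  expect_identical(fn1$edges$edge, fn3$edges$edge)
  expect_equal(fn1$edges$cv, fn3$edges$cv)
  # covering fraction selects every edge
  all_edges <- frame_network(m, fraction = 2 * n_edges(8) / 64)
  expect_identical(sort(all_edges$edges$edge), seq_len(n_edges(8)))
})

test_that("planted stable edges are recovered at the matching threshold", {
  # 10 disjoint planted pairs among 20 regions; top 5% of 400 cells = 10
  spec <- small_control_spec(n = 12, regions = 20, timepoints = 100, seed = 3)
  em <- cohort_edge_matrix(generate_cohort(spec))
  fn <- frame_network(em, fraction = 0.05)
  planted <- framenet:::pair_to_edge_index(
    as.matrix(spec$planted_edges[, c("i", "j")]), 20)
  expect_setequal(fn$edges$edge, planted)
})

test_that("threshold sweep produces nested networks of the expected sizes", {
  set.seed(16)
  m <- matrix(rnorm(4 * 4005), 4)
  sweep_f <- seq(0.005, 0.05, by = 0.005)
  nets <- threshold_sweep(m, sweep_f)
  expect_equal(vapply(nets, function(x) nrow(x$edges), 0L),
               c(20L, 41L, 61L, 81L, 101L, 122L, 142L, 162L, 182L, 203L))
  for (k in 2:length(nets))
    expect_true(all(nets[[k - 1]]$edges$edge %in% nets[[k]]$edges$edge))
  expect_identical(threshold_sweep(m, numeric()), list())
})

test_that("network overlap is a symmetric intersection with guards", {
  set.seed(17)
  m1 <- matrix(rnorm(4 * n_edges(8)), 4)
  m2 <- matrix(rnorm(4 * n_edges(8)), 4)
  a <- frame_network(m1, 0.3); b <- frame_network(m2, 0.3)
  ov <- network_overlap(a, b)
  expect_identical(paste(ov$i, ov$j),
                   paste(network_overlap(b, a)$i, network_overlap(b, a)$j))
  self <- network_overlap(a, a)
  expect_setequal(framenet:::pair_to_edge_index(as.matrix(self[, 1:2]), 8),
                  a$edges$edge)
  c6 <- frame_network(matrix(rnorm(4 * n_edges(6)), 4), 0.3)
  expect_error(network_overlap(a, c6), "different atlases")
})

test_that("node degrees count incident selected edges", {
  m <- matrix(rnorm(3 * n_edges(5)), 3)
  fn <- frame_network(m, fraction = 2 / 25)  # one edge
  deg <- node_degrees(fn)
  expect_equal(sum(deg$degree), 2 * nrow(fn$edges))
  expect_setequal(deg$region[deg$degree == 1],
                  c(fn$edges$i, fn$edges$j))
})

test_that("lateralization counts homotopic-only networks as interhemispheric", {
  atlas <- aal90_atlas()
  spec <- cohort_spec(n_control = 6, n_patient = 0, seed = 5,
                      n_timepoints = 60)
  em <- cohort_edge_matrix(generate_cohort(spec), atlas)
  fn <- frame_network(em, 0.01, atlas)
  lat <- lateralization_summary(fn)
  expect_equal(lat$interhemispheric + lat$intra_left + lat$intra_right +
                 lat$other, 41)
  # default control cohort plants only homotopic pairs
  expect_equal(lat$interhemispheric, 41)
  expect_equal(lat$left_minus_right, 0)
})

test_that("rank-SD diagnostic shows the negative stability-strength relation", {
  spec <- small_control_spec(n = 15, regions = 16, timepoints = 80, seed = 8)
  em <- cohort_edge_matrix(generate_cohort(spec))
  fn <- frame_network(em, 0.05)
  d <- rank_sd_diagnostic(fn)
  expect_lt(attr(d, "rank_sd_correlation"), 0)
  expect_equal(sum(d$selected), nrow(fn$edges))
  # constant ranks: correlation undefined, reported as NA
  const <- frame_network(matrix(rep(1:n_edges(5), each = 3), 3,
                                byrow = FALSE), 0.1)
  expect_true(is.na(attr(rank_sd_diagnostic(const), "rank_sd_correlation")))
})

test_that("frame networks round-trip through the delimited writer", {
  atlas <- aal90_atlas()
  spec <- cohort_spec(n_control = 4, n_patient = 0, n_timepoints = 40,
                      seed = 9)
  em <- cohort_edge_matrix(generate_cohort(spec), atlas)
  fn <- frame_network(em, 0.005, atlas)
  path <- file.path(withr::local_tempdir(), "net.tsv")
  write_frame_network(fn, path)
  back <- read.delim(path)
  expect_equal(nrow(back), 20)
  expect_equal(back$cv, fn$edges$cv, tolerance = 1e-12)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$n_edges, 20)
})
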