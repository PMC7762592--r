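test_that("published worked examples classify to their printed architectures", {
  g <- printed_genome_fit()
  grid <- t_grid(40)
  # the four T = 3 isolates
  four <- assign_t(c(11600, 11700, 14300, 14500), g, grid)
  expect_equal(four$assigned_t, rep(3, 4))
  expect_true(all(four$is_small_candidate))
  # smallest MCP-encoding gut contig and the crAssphage isolate
  expect_equal(assign_t(7400, g, grid)$assigned_t, 7 / 3, tolerance = 1e-9)
  expect_equal(assign_t(102000, g, grid)$assigned_t, 13)
  # smallest gut contigs adopt the trihexagonal T = 4/3
  expect_equal(assign_t(c(4500, 5400), g, grid)$assigned_t, rep(4 / 3, 2))
  # dataset extremes
  expect_equal(assign_t(11600, g, grid)$assigned_t, 3)
  expect_equal(assign_t(497500, g, grid)$assigned_t, 39)
  expect_equal(assign_t(294500, g, grid)$assigned_t, 27)
})

test_that("midpoint ties go to the smaller architecture", {
  g <- printed_genome_fit()
  grid <- t_grid(40)
  means <- predict_mean(g, grid)
  for (i in c(1, 5, 12)) {
    mid_bp <- (means[i] + means[i + 1]) / 2 * 1000
    expect_equal(assign_t(mid_bp, g, grid)$assigned_t, grid[i],
                 tolerance = 1e-12)
    expect_equal(assign_t(mid_bp + 1, g, grid)$assigned_t, grid[i + 1],
                 tolerance = 1e-12)
  }
})

test_that("assignment is monotone in genome length", {
  g <- printed_genome_fit()
  lengths <- sort(unique(round(10^seq(0, log10(6e5), length.out = 800))))
  asg <- assign_t(lengths, g)
  expect_true(all(diff(asg$assigned_t) >= -1e-12))
})

test_that("nearest-mean search agrees with the midpoint-interval oracle", {
  g <- printed_genome_fit()
  grid <- t_grid(40)
  lengths <- round(10^seq(2.5, log10(6e5), length.out = 500))
  mine <- assign_t(lengths, g, grid)$assigned_t
  oracle <- oracle_assign_midpoints(lengths, g, grid)
  expect_equal(mine, oracle, tolerance = 1e-12)
})

test_that("log-space matching is available as a sensitivity flag", {
  g <- printed_genome_fit()
  # in log space the boundary is the geometric midpoint
  means <- predict_mean(g, t_grid(40))
  geo_mid <- sqrt(means[5] * means[6]) * 1000
  expect_equal(assign_t(geo_mid - 1, g, log_space = TRUE)$assigned_t,
               t_grid(40)[5], tolerance = 1e-12)
})

test_that("batch classification tabulates frequencies and flags candidates", {
  g <- printed_genome_fit()
  recs <- data.frame(id = paste0("g", 1:6),
                     length_bp = c(11600, 11700, 14300, 14500, 42000, 42000))
  cls <- classify_batch(recs, g)
  expect_identical(nrow(cls$assignments), 6L)
  expect_equal(sum(cls$frequency$percent), 100)
  expect_equal(cls$frequency$count[cls$frequency$t == 3], 4L)
  # a uniform 42 kbp batch collapses to a single T = 7 bin
  all42 <- classify_batch(data.frame(id = paste0("x", 1:10),
                                     length_bp = rep(42000, 10)), g)
  expect_identical(nrow(all42$frequency), 1L)
  expect_equal(all42$frequency$t, 7)
  # nothing above 30 kbp is a small-capsid candidate
  big <- classify_batch(data.frame(id = paste0("b", 1:5),
                                   length_bp = seq(31000, 500000,
                                                   length.out = 5)), g)
  expect_identical(nrow(candidate_report(big)$candidates), 0L)
})

test_that("candidate reports filter, sort and count by architecture", {
  g <- printed_genome_fit()
  # printed T < 3 gut contig lengths: 4.5/5.4 kbp -> 4/3; 7.3-8.5 kbp -> 7/3
  lens <- c(4500, 5400, 7300, 7400, 7600, 7800, 7900, 8000, 8200, 8400, 8500)
  cls <- classify_batch(data.frame(id = paste0("c", seq_along(lens)),
                                   length_bp = lens), g)
  rep3 <- candidate_report(cls, threshold_t = 3)
  expect_equal(rep3$counts$count[abs(rep3$counts$t - 4 / 3) < 1e-9], 2L)
  expect_equal(rep3$counts$count[abs(rep3$counts$t - 7 / 3) < 1e-9], 9L)
  expect_true(!is.unsorted(rep3$candidates$assigned_t))
  expect_identical(nrow(candidate_report(cls, threshold_t = 0)$candidates), 0L)
  expect_identical(nrow(candidate_report(cls, threshold_t = Inf)$candidates),
                   length(lens))
})

test_that("the genome-length KDE is a proper density with located peaks", {
  set.seed(31)
  recs <- data.frame(id = paste0("s", 1:400),
                     length_bp = round(c(rnorm(200, 20000, 1500),
                                         rnorm(200, 80000, 4000))))
  est <- estimate_density(recs)
  expect_equal(sum(est$density) * diff(est$grid[1:2]), 1, tolerance = 0.01)
  expect_gte(nrow(est$peaks), 2)
  top2 <- sort(est$peaks$location_kbp[1:2])
  expect_equal(top2, c(20, 80), tolerance = est$bandwidth / 20)
  # single tight cluster: one peak
  one <- estimate_density(data.frame(length_bp = round(rnorm(200, 40000, 800))))
  expect_identical(nrow(one$peaks), 1L)
  expect_error(estimate_density(data.frame(length_bp = rep(500, 5))),
               "distinct")
})

test_that("find_peaks reports strict interior maxima only", {
  mono <- list(grid = 1:100, density = seq(0, 1, length.out = 100))
  expect_identical(nrow(find_peaks(mono)), 0L)
  flat <- list(grid = 1:100, density = rep(0.5, 100))
  expect_identical(nrow(find_peaks(flat)), 0L)
  bumpy <- list(grid = 1:7, density = c(0, 1, 0, 2, 0, 3, 0))
  pk <- find_peaks(bumpy)
  expect_equal(pk$location_kbp, c(6, 4, 2))  # sorted by density
})

test_that("mixture presets reproduce their anchor peaks", {
  for (preset in c("isolates", "gut")) {
    comp <- genome_mixture_preset(preset)
    recs <- gen_genome_mixture(comp, n = 3000, seed = 17)
    est <- estimate_density(recs, bandwidth = 5)
    pk <- find_peaks(est)
    top <- pk$location_kbp[seq_len(nrow(comp))]
    for (m in comp$mean_kbp) {
      expect_lt(min(abs(top - m)), est$bandwidth,
                label = sprintf("%s peak at %.1f kbp", preset, m))
    }
  }
})
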