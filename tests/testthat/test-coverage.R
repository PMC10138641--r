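test_that("coverage rate counts bases at or above each depth", {
  uniform <- coverage_profile(rep(30, 100))
  tab <- coverage_rate(uniform)
  expect_equal(tab$rate[tab$depth == 15], 1.0)
  expect_equal(tab$rate[tab$depth == 30], 1.0)
  expect_equal(tab$rate[tab$depth == 50], 0.0)

  steps <- coverage_profile(c(0, 10, 20, 30, 40))
  expect_equal(coverage_rate(steps, 20)$rate, 0.6)
})

test_that("coverage rate is monotone non-increasing in the threshold", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      prof <- coverage_profile(rpois(500, 30))
      rates <- coverage_rate(prof, 0:80)$rate
      expect_true(all(diff(rates) <= 0))
      expect_equal(rates, vapply(0:80, function(n) mean(prof$depth >= n), numeric(1)))
    })
  }
})

test_that("fold80 is mean over 20th-percentile depth, undefined at zero", {
  expect_equal(fold80(coverage_profile(rep(7, 1000))), 1.0)
  expect_equal(fold80(coverage_profile(c(10, 10, 10, 10, 50))), 1.8)
  expect_warning(
    f <- fold80(coverage_profile(c(0, 0, 0, 0, 10))),
    "undefined"
  )
  expect_true(is.na(f))
})

test_that("evenness is 100 iff uniform, bounded by 100, and agrees with the hand case", {
  expect_equal(evenness(coverage_profile(rep(50, 1000))), 100)
  expect_equal(evenness(coverage_profile(rep(50, 1000)), "discrete"), 100)
  expect_equal(
    evenness(coverage_profile(c(10, 10, 10, 10, 50))),
    100 * 58 / (18 * 5)
  )
  for (seed in 1:10) {
    withr::with_seed(seed, {
      prof <- coverage_profile(rpois(200, 20))
      e <- evenness(prof)
      expect_lte(e, 100)
      expect_gt(e, 0)
      if (length(unique(prof$depth)) > 1) {
        expect_lt(e, 100)
        expect_gt(fold80(prof), 1)
      }
    })
  }
  expect_error(evenness(coverage_profile(rep(0, 10))), "mean depth is zero")
})

test_that("uniformity metrics are invariant to depth scaling", {
  withr::with_seed(4, {
    d <- rpois(300, 25) + 1
    p1 <- coverage_profile(d)
    p3 <- coverage_profile(3 * d)
    expect_equal(fold80(p1), fold80(p3))
    expect_equal(evenness(p1), evenness(p3))
  })
})

test_that("concentrating a fixed read mass onto fewer bases lowers evenness", {
  spread <- coverage_profile(rep(10, 100))
  lumpy <- coverage_profile(c(rep(20, 50), rep(0, 50)))
  spikier <- coverage_profile(c(rep(100, 10), rep(0, 90)))
  expect_gt(evenness(spread), evenness(lumpy))
  expect_gt(evenness(lumpy), evenness(spikier))
})

test_that("downsampling is seeded, exact, and keeps mates together", {
  sim <- simulate_experiment(sim_config(seed = 3, n_pairs = 100))
  reads <- sim$reads
  s1 <- downsample_pairs(reads, 10, seed = 42)
  s2 <- downsample_pairs(reads, 10, seed = 42)
  expect_identical(s1, s2)
  expect_equal(length(unique(s1$qname)), 10)
  expect_true(all(table(s1$qname) == 2)) # mates never separated

  expect_identical(
    dplyr::arrange(downsample_pairs(reads, 100, seed = 1), qname),
    dplyr::arrange(reads, qname)
  )
  expect_error(downsample_pairs(reads, 101, seed = 1), "available")
})

test_that("per-pair inclusion is uniform across seeds", {
  sim <- simulate_experiment(sim_config(seed = 9, n_pairs = 200))
  ids <- unique(sim$reads$qname)
  hits <- setNames(numeric(length(ids)), ids)
  n_seeds <- 200
  for (s in seq_len(n_seeds)) {
    kept <- unique(downsample_pairs(sim$reads, 100, seed = s)$qname)
    hits[kept] <- hits[kept] + 1
  }
  freq <- hits / n_seeds
  # binomial(200, .5) per pair: all inclusion frequencies inside a generous CI
  expect_true(all(abs(freq - 0.5) < 4 * sqrt(0.25 / n_seeds)))
  expect_lt(abs(mean(freq) - 0.5), 1e-9)
})

test_that("a single-effort grid equals one coverage_rate call", {
  sim <- simulate_experiment(sim_config(seed = 2, n_pairs = 2000))
  grid <- effort_curves(
    sim$reads, sim$design,
    efforts = 2000, thresholds = c(5, 15), seed = 1
  )
  marked <- mark_duplicates(sim$reads)
  prof <- depth_profile(marked, sim$design, include_duplicates = FALSE)
  direct <- coverage_rate(prof, c(5, 15), effort = 2000)
  expect_equal(grid, direct)
})

test_that("minimal effort is looked up from tabulated per-effort rates", {
  medex <- effort_grid(c(40, 60, 80, 100), c(0.66, 0.83, 0.90, 0.92), 30)
  crev2 <- effort_grid(c(40, 60, 80, 100), c(0.51, 0.75, 0.86, 0.90), 30)
  expect_equal(minimal_effort(medex, 30, 0.90), 80)
  expect_equal(minimal_effort(crev2, 30, 0.90), 100)
  expect_message(
    nr <- minimal_effort(effort_grid(c(40, 60), c(0.5, 0.6), 30), 30, 0.90),
    "not reached"
  )
  expect_true(is.na(nr))
  expect_error(minimal_effort(medex[0, ], 30, 0.9), "empty")
})

test_that("panel restriction equals brute-force restriction of the full profile", {
  sim <- simulate_experiment(sim_config(seed = 6, n_pairs = 3000))
  # panel = the full design is the identity case
  full <- effort_curves(sim$reads, sim$design, c(1000, 3000), seed = 5)
  panel_full <- panel_coverage_report(sim$reads, sim$design, c(1000, 3000), seed = 5)
  expect_equal(panel_full, full)

  # a strict sub-panel: depth restricted to the panel bases
  sub <- sim$design[seq(1, nrow(sim$design), by = 3), ]
  marked <- mark_duplicates(sim$reads)
  prof_sub <- depth_profile(marked, sub, include_duplicates = FALSE)
  grid_sub <- panel_coverage_report(
    sim$reads, sub,
    efforts = length(unique(sim$reads$qname)), seed = 5
  )
  expect_equal(grid_sub$rate, coverage_rate(prof_sub)$rate)

  expect_error(
    panel_coverage_report(sim$reads, sim$design[0, ], 100, seed = 1),
    "empty panel"
  )
})
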