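kit_fixture <- function() {
  km <- example_kit_metrics()
  lapply(split(km, km$kit), function(d) d[order(d$effort), names(d) != "kit"])
}

test_that("threshold boundaries follow the printed operators", {
  config <- threshold_config()
  row <- function(m, value) {
    x <- tibble::as_tibble(setNames(list(value), m))
    evaluate_sample(x, config = config[config$metric == m, ])
  }
  expect_true(row("duplicate_pct", 12.09)$pass)
  expect_false(row("duplicate_pct", 21.93)$pass)
  expect_false(row("duplicate_pct", 20)$pass) # "under 20%" is strict
  expect_false(row("tstv", 2.4)$pass) # "> 2.4" is strict
  expect_true(row("tstv", 2.5)$pass)
  expect_true(row("target_at_30x_pct", 90)$pass) # "at least 90%" inclusive
  expect_false(row("target_at_30x_pct", 89.9)$pass)
  expect_true(row("mean_cov_dup", 100)$pass)
  expect_false(row("on_target_pct", 80)$pass)
  expect_true(row("on_target_pct", 80.1)$pass)
})

test_that("the verdict ledger covers all seven sample parameters", {
  m <- example_kit_metrics()[1, ]
  v <- evaluate_sample(m)
  expect_equal(nrow(v), 8) # uniformity contributes two advisory rows
  expect_equal(sum(is.na(v$pass)), 3) # insert, fold80, evenness advisory
  expect_true(all(nzchar(v$note[is.na(v$pass)])))
  # a failing metric carries its corrective note
  expect_match(
    v$note[v$metric == "mean_cov_dup" & !v$pass],
    "fewer samples", all = FALSE
  )
  expect_error(
    evaluate_sample(dplyr::select(m, -tstv)),
    "missing and not advisory"
  )
})

test_that("kit comparison marks best cells only where merit has a direction", {
  cmp <- compare_kits(kit_fixture())
  tab <- tidy(cmp)
  expect_false(any(tab$best[tab$metric == "median_insert"]))

  best_by <- function(metric) {
    unique(tab$kit[tab$best & tab$metric == metric])
  }
  # reproduces the published bolding pattern of the example matrix
  expect_equal(best_by("on_target_pct"), "Medexome")
  expect_equal(best_by("mean_cov_nodup"), "SSV7")
  expect_equal(best_by("target_at_30x_pct"), "SSV7")
  expect_equal(best_by("evenness"), "SSV7")
  expect_equal(best_by("duplicate_pct"), "CREV2")
})

test_that("identical kits tie with no distinguishing marks", {
  one <- kit_fixture()[[1]]
  cmp <- compare_kits(list(X = one, Y = one))
  expect_false(any(tidy(cmp)$best))
  expect_equal(sort(unique(glance(cmp)$n_fail)), unique(glance(cmp)$n_fail))
})

test_that("a kit with fewer duplicates wins the duplicate cells", {
  a <- kit_fixture()[[1]]
  b <- dplyr::mutate(a, duplicate_pct = duplicate_pct + 7)
  cmp <- compare_kits(list(A = a, B = b))
  tab <- tidy(cmp)
  expect_equal(unique(tab$kit[tab$best & tab$metric == "duplicate_pct"]), "A")
})

test_that("kit order does not change the comparison content", {
  kits <- kit_fixture()
  c1 <- compare_kits(kits)
  c2 <- compare_kits(rev(kits))
  expect_equal(
    dplyr::arrange(tidy(c1), kit, effort, metric),
    dplyr::arrange(tidy(c2), kit, effort, metric)
  )
  expect_equal(glance(c1)$kit, glance(c2)$kit)
})

test_that("mismatched effort grids are rejected", {
  kits <- kit_fixture()
  kits[[2]] <- kits[[2]][kits[[2]]$effort != 100, ]
  expect_error(compare_kits(kits), "mismatched effort")
})

test_that("reports are complete, traceable and byte-stable", {
  cmp <- compare_kits(kit_fixture())
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- render_report(cmp, dir = d1)
  p2 <- render_report(cmp, dir = d2)
  expect_true(all(file.exists(p1)))
  for (i in seq_along(p1)) {
    expect_identical(readLines(p1[i]), readLines(p2[i]))
  }
  rep <- jsonlite::read_json(p1[1], simplifyVector = TRUE)
  expect_equal(rep$design_partition, "not evaluated")
  expect_equal(rep$panel_coverage, "not evaluated")
  # every reported number traces back to the comparison object
  got <- dplyr::arrange(
    tibble::as_tibble(rep$metrics), kit, effort, metric
  )
  want <- dplyr::arrange(tidy(cmp), kit, effort, metric)
  expect_equal(got$value, want$value)

  # optional sections carry through
  part <- partition_design(
    tibble::tibble(chrom = "chr1", start = 0, end = 100),
    tibble::tibble(
      gene = "G", transcript = "T", chrom = "chr1", strand = "+",
      feature = "exon", start = 0, end = 100
    )
  )
  p3 <- render_report(cmp, design_partition = part, dir = withr::local_tempdir())
  rep3 <- jsonlite::read_json(p3[1], simplifyVector = TRUE)
  expect_equal(rep3$design_partition$total_bases, 100)
})

test_that("sample_metrics assembles a consistent row from alignments", {
  sim <- simulate_experiment(sim_config(seed = 23, n_pairs = 4000))
  m <- sample_metrics(
    sim$reads, sim$design,
    variants = sim$variants, label = "simkit"
  )
  expect_equal(nrow(m), 1)
  expect_lte(m$mean_cov_nodup, m$mean_cov_dup)
  expect_true(m$on_target_pct >= 0 && m$on_target_pct <= 100)
  expect_true(m$duplicate_pct >= 0 && m$duplicate_pct <= 100)
  expect_lte(m$evenness, 100)
  expect_gte(m$fold80, 1)
  # the row can be evaluated against the full rule set
  v <- evaluate_sample(m)
  expect_equal(nrow(v), 8)
})
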