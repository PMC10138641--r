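test_that("insert-size statistics use each proper pair once and drop outliers", {
  reads <- dplyr::bind_rows(
    pair_records("a", "chr1", 0, 200),
    pair_records("b", "chr1", 300, 206),
    pair_records("c", "chr1", 600, 210)
  )
  s <- insert_size_stats(reads)
  expect_equal(s$median_insert, 206)
  expect_equal(s$n_pairs, 3)

  with_outlier <- dplyr::bind_rows(
    pair_records("a", "chr1", 0, 206),
    pair_records("b", "chr1", 300, 206),
    pair_records("c", "chr1", 600, 3000)
  )
  expect_equal(insert_size_stats(with_outlier)$median_insert, 206)
  expect_equal(insert_size_stats(with_outlier)$n_pairs, 2)

  none <- dplyr::mutate(reads, proper_pair = FALSE)
  expect_error(insert_size_stats(none), "no proper pairs")
})

test_that("mate overlap arithmetic", {
  expect_equal(read_overlap(150, 400), 0)
  expect_equal(read_overlap(100, 150), 50)
  expect_error(read_overlap(0, 100))
})

test_that("duplicate marking flags all but one pair per coordinate key", {
  # 3 pairs sharing one key + 1 unique pair -> 4 of 8 reads flagged
  reads <- dplyr::bind_rows(
    pair_records("d1", "chr1", 100, 200, qual_sum = c(10, 10)),
    pair_records("d2", "chr1", 100, 200, qual_sum = c(30, 30)),
    pair_records("d3", "chr1", 100, 200, qual_sum = c(20, 20)),
    pair_records("u1", "chr1", 500, 200)
  )
  marked <- mark_duplicates(reads)
  expect_equal(sum(marked$duplicate), 4)
  expect_equal(duplicate_rate(marked), 0.5)
  # the highest-quality pair is the group representative
  expect_false(any(marked$duplicate[marked$qname == "d2"]))
  expect_false(any(marked$duplicate[marked$qname == "u1"]))
})

test_that("unique keys give duplicate rate 0 and ties break by input order", {
  uniq <- dplyr::bind_rows(
    pair_records("a", "chr1", 0, 200),
    pair_records("b", "chr1", 400, 200),
    pair_records("c", "chr2", 0, 200)
  )
  expect_equal(duplicate_rate(mark_duplicates(uniq)), 0)

  tie <- dplyr::bind_rows(
    pair_records("first", "chr1", 0, 200, qual_sum = c(10, 10)),
    pair_records("second", "chr1", 0, 200, qual_sum = c(10, 10))
  )
  marked <- mark_duplicates(tie)
  expect_false(any(marked$duplicate[marked$qname == "first"]))
  expect_true(all(marked$duplicate[marked$qname == "second"]))
})

test_that("unpaired mapped reads deduplicate on single-end keys", {
  single <- function(q, start, qs) {
    tibble::tibble(
      qname = q, flag = 0L, chrom = "chr1", start = start, end = start + 50,
      strand = "+", cigar = "50M", mate_chrom = "chr1", tlen = 0,
      qual_sum = qs, paired = FALSE, proper_pair = FALSE, is_first = TRUE,
      secondary = FALSE, mate_mapped = FALSE, duplicate = FALSE,
      unclipped_5p = start
    )
  }
  reads <- dplyr::bind_rows(
    single("s1", 100, 5), single("s2", 100, 9), single("s3", 200, 5)
  )
  marked <- mark_duplicates(reads)
  expect_equal(marked$duplicate[marked$qname == "s1"], TRUE)
  expect_equal(sum(marked$duplicate), 1)
})

test_that("clipped reads share a duplicate key through the unclipped 5' end", {
  a <- pair_records("a", "chr1", 100, 200, read_length = 50)
  b <- pair_records("b", "chr1", 100, 200, read_length = 50)
  # clip 10 leading bases of b's forward read: alignment starts 10 later but
  # the unclipped 5' end is unchanged
  b$start[1] <- b$start[1] + 10
  b$cigar[1] <- "10S40M"
  b$unclipped_5p[1] <- b$start[1] - 10
  marked <- mark_duplicates(dplyr::bind_rows(a, b))
  expect_equal(sum(marked$duplicate), 2)
})

test_that("on-target rate counts aligned bases inside the target", {
  target <- tibble::tibble(chrom = "chr1", start = 0, end = 1000)
  on <- pair_records("on", "chr1", 100, 200, read_length = 50)
  off <- pair_records("off", "chr2", 100, 200, read_length = 50)
  expect_equal(on_target_rate(dplyr::bind_rows(on, off), target), 0.5)

  # one read, 40 of 100 aligned bases inside the target
  part <- pair_records("p", "chr1", 960, 200, read_length = 100)[1, ]
  expect_equal(on_target_rate(part, tibble::tibble(
    chrom = "chr1", start = 0, end = 1000
  )), 0.4)

  expect_equal(on_target_rate(on, target), 1)
  expect_error(on_target_rate(on, target[0, ]), "empty target")
})

test_that("on-target rate matches the per-base oracle on random toy data", {
  genome <- c(chr1 = 5000, chr2 = 3000)
  for (seed in 1:5) {
    withr::with_seed(seed, {
      reads <- rand_reads(100, genome)
      target <- rand_intervals(20, genome, max_len = 200)
      expect_equal(
        on_target_rate(reads, target),
        oracle_on_target(reads, merge_intervals(target), genome)
      )
    })
  }
})

test_that("depth profiles equal the brute-force pileup", {
  target <- tibble::tibble(chrom = "chr1", start = 100, end = 110)
  one <- pair_records("a", "chr1", 100, 200, read_length = 10)[1, ]
  prof <- depth_profile(one, target)
  expect_equal(prof$depth, rep(1, 10))
  expect_equal(mean_depth(prof), 1)

  # excluding a duplicate-flagged pair halves a two-pair pileup
  pile <- dplyr::bind_rows(
    pair_records("a", "chr1", 100, 200, read_length = 10),
    pair_records("b", "chr1", 100, 200, read_length = 10)
  )
  pile <- mark_duplicates(pile)
  with_dup <- depth_profile(pile, target, include_duplicates = TRUE)
  no_dup <- depth_profile(pile, target, include_duplicates = FALSE)
  expect_equal(mean_depth(with_dup), 2 * mean_depth(no_dup))

  genome <- c(chr1 = 5000)
  withr::with_seed(3, {
    reads <- rand_reads(500, genome)
    tgt <- merge_intervals(rand_intervals(10, genome, max_len = 400))
    prof <- depth_profile(reads, tgt)
    expect_equal(prof$depth, oracle_depth_over(reads, tgt, genome))
    # conservation: total depth equals summed per-read on-target bases
    expect_equal(
      sum(prof$depth),
      oracle_on_target(reads, tgt, genome) * nrow(reads) * 50
    )
  })
})

test_that("deletions and soft clips add no depth", {
  read <- pair_records("a", "chr1", 100, 200, read_length = 50)[1, ]
  read$cigar <- "10M5D10M30S"
  read$end <- read$start + 25
  target <- tibble::tibble(chrom = "chr1", start = 100, end = 130)
  prof <- depth_profile(read, target)
  expect_equal(sum(prof$depth), 20)
  expect_equal(prof$depth[11:15], rep(0, 5)) # the deletion gap
})

test_that("simulated records survive a SAM round trip", {
  sim <- simulate_experiment(sim_config(seed = 5, n_pairs = 400))
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(sim$reads, path, sim$genome)
  back <- read_alignments(path)
  cols <- c(
    "qname", "flag", "chrom", "start", "end", "strand", "cigar",
    "mate_chrom", "tlen", "qual_sum", "paired", "proper_pair", "is_first",
    "secondary", "mate_mapped", "duplicate", "qual", "unclipped_5p"
  )
  orig <- dplyr::arrange(sim$reads[, cols], qname, is_first)
  got <- dplyr::arrange(back[, cols], qname, is_first)
  expect_equal(got, orig)
})
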