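#' Read alignments into a tidy record table
#'
#' Loads a coordinate-sorted SAM or BAM file into the per-read tibble all
#' sample-level metrics operate on. SAM positions (1-based) are converted to
#' 0-based half-open coordinates at ingestion. Unmapped records are not
#' loaded; secondary and supplementary alignments are loaded but excluded
#' from every metric.
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @return A tibble with one row per alignment record: `qname`, `flag`,
#'   `chrom`, `start`, `end` (0-based half-open), `strand`, `cigar`,
#'   `mate_chrom`, `tlen`, `qual_sum` (sum of base qualities), `unclipped_5p`
#'   (5' alignment start adjusted for clipping), and logicals `paired`,
#'   `proper_pair`, `is_first`, `secondary`, `mate_mapped`, `duplicate`.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = ".bam")
    path <- Rsamtools::asBam(path, sub("\\.bam$", "", dest),
      overwrite = TRUE, indexDestination = FALSE
    )
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "mrnm", "isize", "qual")
  )
  ga <- GenomicAlignments::readGAlignments(path, param = param)
  meta <- S4Vectors::mcols(ga)
  qual_sum <- vapply(
    as(meta$qual, "IntegerList"),
    function(q) sum(q, na.rm = TRUE),
    numeric(1)
  )
  flag <- meta$flag
  reads <- tibble::tibble(
    qname = meta$qname,
    flag = flag,
    chrom = as.character(GenomicRanges::seqnames(ga)),
    start = as.numeric(GenomicAlignments::start(ga)) - 1,
    end = as.numeric(GenomicAlignments::end(ga)),
    strand = as.character(GenomicAlignments::strand(ga)),
    cigar = GenomicAlignments::cigar(ga),
    mate_chrom = as.character(meta$mrnm),
    tlen = as.numeric(meta$isize),
    qual_sum = qual_sum,
    paired = bitwAnd(flag, 1L) > 0,
    proper_pair = bitwAnd(flag, 2L) > 0,
    is_first = bitwAnd(flag, 64L) > 0,
    secondary = bitwAnd(flag, bitwOr(256L, 2048L)) > 0,
    mate_mapped = bitwAnd(flag, 8L) == 0,
    duplicate = bitwAnd(flag, 1024L) > 0,
    qual = as.character(meta$qual)
  )
  reads$unclipped_5p <- unclipped_5p(reads)
  reads
}

# 5' unclipped alignment start: leading soft/hard clips extend the start on
# the forward strand, trailing clips extend the end on the reverse strand.
unclipped_5p <- function(reads) {
  lead <- stringr::str_match(reads$cigar, "^(\\d+)[SH]")[, 2]
  trail <- stringr::str_match(reads$cigar, "(\\d+)[SH]$")[, 2]
  lead <- ifelse(is.na(lead), 0, as.numeric(lead))
  trail <- ifelse(is.na(trail), 0, as.numeric(trail))
  ifelse(reads$strand == "-", reads$end + trail, reads$start - lead)
}

# records that contribute to sample metrics
primary_mapped <- function(reads) {
  reads[!reads$secondary, , drop = FALSE]
}

# GRanges of aligned reference blocks (CIGAR M/=/X); soft clips, insertions
# and deletions add no covered bases.
aligned_blocks <- function(reads) {
  rl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    reads$cigar,
    pos = as.integer(reads$start + 1),
    ops = c("M", "=", "X"),
    drop.empty.ranges = TRUE,
    reduce.ranges = TRUE
  )
  n <- S4Vectors::elementNROWS(rl)
  GenomicRanges::GRanges(
    seqnames = rep(reads$chrom, n),
    ranges = unlist(rl, use.names = FALSE)
  )
}

aligned_base_count <- function(reads) {
  rl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    reads$cigar,
    ops = c("M", "=", "X"),
    drop.empty.ranges = TRUE
  )
  sum(sum(GenomicRanges::width(rl)))
}

#' Insert-size statistics from proper pairs
#'
#' Median and mean template length over properly paired reads, each pair
#' counted once (via its positive-`tlen` mate). Templates longer than
#' `max_insert` are treated as outliers and excluded so the median stays
#' robust; libraries here are expected around 200--250 bp.
#'
#' @param reads An alignment tibble (see [read_alignments()]).
#' @param max_insert Outlier cutoff in bp (default 2000).
#' @return A one-row tibble: `median_insert`, `mean_insert`, `n_pairs`.
#' @export
insert_size_stats <- function(reads, max_insert = 2000) {
  reads <- primary_mapped(reads)
  tl <- reads$tlen[reads$proper_pair & !is.na(reads$tlen) & reads$tlen > 0]
  tl <- tl[tl <= max_insert]
  if (length(tl) == 0) stop("no proper pairs with usable template length")
  tibble::tibble(
    median_insert = stats::median(tl),
    mean_insert = mean(tl),
    n_pairs = length(tl)
  )
}

#' Expected mate overlap for a paired-end run
#'
#' For 2 x `read_length` sequencing of fragments of length `insert_size`,
#' the two mates overlap by `max(0, 2 * read_length - insert_size)` bases:
#' e.g. 2 x 150 bp reads of a 206 bp fragment overlap by 94 bp.
#'
#' @param read_length Read length in bp.
#' @param insert_size Fragment (insert) length in bp.
#' @return Overlap in bp (vectorised).
#' @export
read_overlap <- function(read_length, insert_size) {
  stopifnot(all(read_length > 0), all(insert_size > 0))
  pmax(0, 2 * read_length - insert_size)
}

#' Mark PCR duplicates by alignment coordinates
#'
#' Groups read pairs by the coordinate key (chrom, unclipped 5' start, strand)
#' of both mates -- the library-standard criterion for PCR duplicates -- and
#' flags every pair in a group except the one with the highest summed base
#' quality (ties broken by first-encountered order, so output is
#' deterministic). Unpaired mapped reads form single-end keys. Secondary and
#' supplementary alignments are ignored.
#'
#' @param reads An alignment tibble.
#' @return The tibble with its `duplicate` column set.
#' @seealso [duplicate_rate()]
#' @export
mark_duplicates <- function(reads) {
  reads$duplicate <- FALSE
  prim <- which(!reads$secondary)
  r <- reads[prim, , drop = FALSE]
  triple <- paste(r$chrom, r$unclipped_5p, r$strand, sep = ":")

  is_pairable <- r$paired & r$mate_mapped
  first <- which(is_pairable & r$is_first)
  second <- which(is_pairable & !r$is_first)
  m <- match(r$qname[first], r$qname[second])
  first_ok <- first[!is.na(m)]
  second_ok <- second[m[!is.na(m)]]

  flag_group <- function(key, score, order_in) {
    o <- order(key, -score, order_in)
    dup_sorted <- duplicated(key[o])
    dup <- logical(length(key))
    dup[o] <- dup_sorted
    dup
  }

  dup_rows <- integer(0)
  if (length(first_ok) > 0) {
    t1 <- triple[first_ok]
    t2 <- triple[second_ok]
    key <- paste(pmin(t1, t2), pmax(t1, t2))
    score <- r$qual_sum[first_ok] + r$qual_sum[second_ok]
    dup <- flag_group(key, score, seq_along(key))
    dup_rows <- c(dup_rows, first_ok[dup], second_ok[dup])
  }
  singles <- setdiff(seq_len(nrow(r)), c(first_ok, second_ok))
  if (length(singles) > 0) {
    dup <- flag_group(triple[singles], r$qual_sum[singles], seq_along(singles))
    dup_rows <- c(dup_rows, singles[dup])
  }
  reads$duplicate[prim[dup_rows]] <- TRUE
  reads
}

#' Duplicate rate of a marked alignment set
#'
#' Fraction of mapped primary reads flagged as duplicates; the Table-style
#' "duplicate reads (%)" is `100 * duplicate_rate()`.
#'
#' @param reads An alignment tibble with duplicates marked
#'   (see [mark_duplicates()]).
#' @return Fraction in `[0, 1]`.
#' @export
duplicate_rate <- function(reads) {
  r <- primary_mapped(reads)
  if (nrow(r) == 0) stop("no mapped reads")
  mean(r$duplicate)
}

#' On-target rate
#'
#' Ratio of sequenced (aligned) bases falling inside the target regions to
#' the total aligned bases of all mapped reads. Duplicates are included
#' (the rate describes the capture, before deduplication); soft-clipped bases
#' and deletion gaps never count as sequenced bases.
#'
#' @param reads An alignment tibble.
#' @param target An interval tibble of target regions.
#' @param padding Bases of slack added around each target interval before
#'   counting (default 0, i.e. strict target boundaries).
#' @return Fraction in `[0, 1]`.
#' @export
on_target_rate <- function(reads, target, padding = 0) {
  target <- merge_intervals(target)
  if (nrow(target) == 0) stop("empty target")
  if (padding > 0) {
    target <- merge_intervals(dplyr::mutate(
      target,
      start = pmax(0, .data$start - padding), end = .data$end + padding
    ))
  }
  r <- primary_mapped(reads)
  denom <- aligned_base_count(r)
  if (denom == 0) stop("zero mapped bases")
  cov <- GenomicRanges::coverage(aligned_blocks(r))
  numer <- sum(depth_over_target(cov, target))
  numer / denom
}

# Integer depth vector over every target base (row order of `target`,
# left to right within each interval), from an RleList coverage.
depth_over_target <- function(cov, target) {
  chroms <- unique(target$chrom)
  out <- vector("list", nrow(target))
  for (ch in chroms) {
    rows <- which(target$chrom == ch)
    rle <- if (ch %in% names(cov)) cov[[ch]] else S4Vectors::Rle(0L, 0)
    need <- max(target$end[rows])
    if (length(rle) < need) {
      rle <- c(rle, S4Vectors::Rle(0L, need - length(rle)))
    }
    v <- IRanges::Views(
      rle,
      IRanges::IRanges(start = target$start[rows] + 1, end = target$end[rows])
    )
    vals <- lapply(seq_along(v), function(i) as.integer(v[[i]]))
    for (i in seq_along(rows)) out[[rows[i]]] <- vals[[i]]
  }
  unlist(out)
}

#' Per-base depth of coverage over a target
#'
#' Pileup depth at every target base from mapped primary reads: the number of
#' aligned read bases overlapping each position (deletion gaps excluded).
#' With `include_duplicates = FALSE`, reads flagged as duplicates (run
#' [mark_duplicates()] first) are left out.
#'
#' @param reads An alignment tibble.
#' @param target An interval tibble.
#' @param include_duplicates Count duplicate-flagged reads (default `TRUE`).
#' @return A `coverage_profile` object; see [coverage_profile()].
#' @export
depth_profile <- function(reads, target, include_duplicates = TRUE) {
  target <- merge_intervals(target)
  r <- primary_mapped(reads)
  if (!include_duplicates) r <- r[!r$duplicate, , drop = FALSE]
  cov <- GenomicRanges::coverage(aligned_blocks(r))
  coverage_profile(
    depth = depth_over_target(cov, target),
    target = target,
    include_duplicates = include_duplicates
  )
}

#' Coverage profile objects
#'
#' A `coverage_profile` holds the per-base depth over a target interval set;
#' it is the input to [coverage_rate()], [fold80()] and [evenness()].
#' Construct one directly (e.g. a perfectly uniform profile for calibration)
#' or via [depth_profile()].
#'
#' @param depth Non-negative integer vector, one value per target base.
#' @param target Optional interval tibble; defaults to a single toy interval
#'   `[0, length(depth))` on `"chr1"`.
#' @param include_duplicates Whether duplicate reads were counted.
#' @return An object of class `coverage_profile`.
#' @examples
#' uniform <- coverage_profile(rep(50, 1000))
#' fold80(uniform) # 1
#' @export
coverage_profile <- function(depth, target = NULL, include_duplicates = TRUE) {
  depth <- as.numeric(depth)
  if (any(depth < 0) || any(is.na(depth))) stop("depth must be non-negative")
  if (is.null(target)) {
    target <- tibble::tibble(chrom = "chr1", start = 0, end = length(depth))
  }
  target <- merge_intervals(target)
  if (sum(target$end - target$start) != length(depth)) {
    stop("depth length must equal total target bases")
  }
  structure(
    list(
      target = target,
      depth = depth,
      include_duplicates = include_duplicates
    ),
    class = "coverage_profile"
  )
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(
    "<coverage_profile> ", length(x$depth), " target bases",
    if (x$include_duplicates) " (duplicates included)" else " (deduplicated)",
    "\n  mean depth ", round(mean(x$depth), 2),
    ", median ", stats::median(x$depth), "\n",
    sep = ""
  )
  invisible(x)
}

#' Mean and median depth of a coverage profile
#'
#' Computed over all target bases, zeros included.
#'
#' @param profile A `coverage_profile`.
#' @return A single number.
#' @export
mean_depth <- function(profile) mean(profile$depth)

#' @rdname mean_depth
#' @export
median_depth <- function(profile) stats::median(profile$depth)

#' @method tidy coverage_profile
#' @export
tidy.coverage_profile <- function(x, ...) {
  n <- x$target$end - x$target$start
  tibble::tibble(
    chrom = rep(x$target$chrom, n),
    pos = unlist(lapply(seq_len(nrow(x$target)), function(i) {
      seq(x$target$start[i], x$target$end[i] - 1)
    })),
    depth = x$depth
  )
}

#' @method glance coverage_profile
#' @export
glance.coverage_profile <- function(x, ...) {
  tibble::tibble(
    n_bases = length(x$depth),
    mean_depth = mean(x$depth),
    median_depth = stats::median(x$depth),
    fold80 = suppressWarnings(fold80(x)),
    evenness = if (mean(x$depth) > 0) evenness(x) else NA_real_
  )
}
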