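#' Genomic interval tables
#'
#' Capture designs, gene panels and every other set of genomic regions in
#' kiteval are plain tibbles with columns `chrom` (character), `start` and
#' `end` (0-based, half-open, as in BED). `interval_set()` validates a data
#' frame of raw intervals and returns its canonical form: sorted by
#' `(chrom, start)` with overlapping or abutting intervals merged, so that
#' `total_bases()` is the size of the union of the input bases.
#'
#' @param x A data frame with columns `chrom`, `start`, `end`. Intervals may
#'   overlap, abut, or be unsorted.
#' @param label Optional design or panel name, stored in a `label` column.
#' @return A tibble of disjoint, sorted intervals (plus `label` if given).
#' @examples
#' interval_set(data.frame(chrom = "chr1", start = c(0, 5), end = c(10, 15)))
#' @export
interval_set <- function(x, label = NULL) {
  x <- validate_intervals(x)
  out <- merge_intervals(x)
  if (!is.null(label)) out$label <- label
  out
}

validate_intervals <- function(x) {
  stopifnot(is.data.frame(x))
  missing <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(missing) > 0) {
    stop("interval table lacks column(s): ", paste(missing, collapse = ", "))
  }
  x <- tibble::as_tibble(x)
  x$chrom <- as.character(x$chrom)
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)
  bad <- which(!(x$end > x$start) | x$start < 0 | is.na(x$start) | is.na(x$end))
  if (length(bad) > 0) {
    stop(
      "malformed interval(s) (end <= start or start < 0) at row(s): ",
      paste(utils::head(bad, 10), collapse = ", "),
      if (length(bad) > 10) " ..." else ""
    )
  }
  x
}

# tibble (0-based half-open) <-> GRanges (1-based closed)
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

as_interval_tbl <- function(gr) {
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = as.numeric(GenomicRanges::start(gr)) - 1,
    end = as.numeric(GenomicRanges::end(gr))
  )
}

#' Merge genomic intervals
#'
#' Collapses overlapping and abutting intervals into a canonical disjoint set,
#' sorted by `(chrom, start)`. Idempotent.
#'
#' @param x An interval tibble (`chrom`, `start`, `end`).
#' @return A tibble of merged intervals.
#' @export
merge_intervals <- function(x) {
  x <- validate_intervals(x)
  gr <- GenomicRanges::reduce(GenomicRanges::sort(as_granges(x)))
  as_interval_tbl(gr)
}

#' Total bases covered by an interval set
#'
#' @param x An interval tibble. Merged first, so overlapping input does not
#'   double count.
#' @return Number of distinct genomic bases covered.
#' @export
total_bases <- function(x) {
  x <- merge_intervals(x)
  sum(x$end - x$start)
}

#' Exclusive-region table for several capture designs
#'
#' For 2--4 designs, computes for every non-empty subset of designs the number
#' of bases covered by exactly the designs in that subset (the multi-way
#' intersection bedtools' `multiIntersectBed` tabulates). The subset counts sum
#' exactly to the size of the union of all designs.
#'
#' @param designs A named list of 2--4 interval tibbles sharing one coordinate
#'   system. Unnamed lists get names `design1`, `design2`, ...
#' @return A tibble with one logical column per design, a `designs` label
#'   column (`"A+B"`-style) and a `bases` count, covering all `2^k - 1`
#'   non-empty subsets (zero-base subsets included).
#' @examples
#' a <- interval_set(data.frame(chrom = "chr1", start = 0, end = 10))
#' b <- interval_set(data.frame(chrom = "chr1", start = 5, end = 15))
#' multi_intersect(list(A = a, B = b))
#' @export
multi_intersect <- function(designs) {
  if (!is.list(designs) || length(designs) < 2) {
    stop("multi_intersect() needs a list of at least 2 designs")
  }
  if (length(designs) > 4) {
    stop("multi_intersect() supports at most 4 designs")
  }
  if (is.null(names(designs)) || any(names(designs) == "")) {
    names(designs) <- paste0("design", seq_along(designs))
  }
  if (anyDuplicated(names(designs))) stop("design names must be unique")
  grs <- lapply(designs, function(d) as_granges(merge_intervals(d)))
  bins <- GenomicRanges::disjoin(Reduce(c, grs))
  member <- vapply(
    grs,
    function(g) IRanges::overlapsAny(bins, g),
    logical(length(bins))
  )
  member <- matrix(member, nrow = length(bins), dimnames = list(NULL, names(designs)))
  keep <- rowSums(member) > 0
  widths <- GenomicRanges::width(bins)[keep]
  member <- member[keep, , drop = FALSE]
  pattern <- apply(member, 1, paste, collapse = "/")

  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(designs)))
  names(combos) <- names(designs)
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  combo_pattern <- apply(combos, 1, paste, collapse = "/")
  bases <- vapply(
    combo_pattern,
    function(p) sum(widths[pattern == p]),
    numeric(1)
  )
  out <- tibble::as_tibble(combos)
  out$designs <- vapply(
    seq_len(nrow(combos)),
    function(i) paste(names(designs)[unlist(combos[i, ])], collapse = "+"),
    character(1)
  )
  out$bases <- unname(bases)
  dplyr::arrange(out, dplyr::desc(rowSums(dplyr::across(dplyr::all_of(names(designs))))), .data$designs)
}

#' Read and write BED interval files
#'
#' BED3+ (tab-separated, 0-based half-open). `track`/`browser` lines and `#`
#' comments are skipped on read; columns beyond the third are ignored.
#'
#' @param path File path.
#' @param merge Merge intervals after reading (default `TRUE`).
#' @return `read_bed()`: an interval tibble. `write_bed()`: `path`, invisibly.
#' @export
read_bed <- function(path, merge = TRUE) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  # BED3+: columns beyond the third vary per line; keep the first three
  lines <- sub("^((?:[^\t]*\t){2}[^\t]*).*", "\\1", lines)
  x <- readr::read_tsv(
    I(lines),
    col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  x <- tibble::tibble(
    chrom = x[[1]],
    start = as.numeric(x[[2]]),
    end = as.numeric(x[[3]])
  )
  if (merge) merge_intervals(x) else validate_intervals(x)
}

#' @param x An interval tibble.
#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  x <- validate_intervals(x)
  readr::write_tsv(
    dplyr::mutate(
      x[, c("chrom", "start", "end")],
      start = format(.data$start, scientific = FALSE, trim = TRUE),
      end = format(.data$end, scientific = FALSE, trim = TRUE)
    ),
    path,
    col_names = FALSE
  )
  invisible(path)
}

# set operations used by the partition/panel code ---------------------------

intersect_intervals <- function(x, y) {
  gr <- GenomicRanges::intersect(
    as_granges(merge_intervals(x)),
    as_granges(merge_intervals(y))
  )
  as_interval_tbl(gr)
}

setdiff_intervals <- function(x, y) {
  gr <- GenomicRanges::setdiff(
    as_granges(merge_intervals(x)),
    as_granges(merge_intervals(y))
  )
  as_interval_tbl(gr)
}

empty_intervals <- function() {
  tibble::tibble(chrom = character(), start = numeric(), end = numeric())
}
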