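#' Read a VCF into a tidy variant table
#'
#' Loads the fixed columns of a VCF (v4.x, optionally bgzipped) via vcfR.
#'
#' @param path Path to a `.vcf` or `.vcf.gz` file.
#' @return A tibble with `chrom`, `pos` (1-based), `ref`, `alt`
#'   (comma-separated for multiallelic records), `filter`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble::tibble(
      chrom = character(), pos = numeric(), ref = character(),
      alt = character(), filter = character()
    ))
  }
  tibble::tibble(
    chrom = fix$CHROM,
    pos = as.numeric(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    filter = ifelse(is.na(fix$FILTER), ".", fix$FILTER)
  )
}

#' Classify a single-nucleotide substitution
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine changes
#' (A<->G, C<->T); the eight other changes are transversions.
#'
#' @param ref,alt Single distinct bases in `A`, `C`, `G`, `T` (vectorised).
#' @return Character vector of `"transition"` / `"transversion"`.
#' @examples
#' classify_substitution("A", "G") # transition
#' classify_substitution("G", "C") # transversion
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
  if (!all(ok)) stop("classify_substitution() requires distinct single bases")
  purine <- c("A", "G")
  ifelse(
    (ref %in% purine) == (alt %in% purine),
    "transition", "transversion"
  )
}

#' Transition/transversion ratio of a variant set
#'
#' Counts transitions and transversions over biallelic SNVs (multiallelic SNV
#' records are decomposed per alt allele; indels and MNVs are ignored) and
#' returns Ts/Tv -- an aggregate variant-calling quality indicator, typically
#' around 2 genome-wide and a little above 3 in protein-coding regions.
#' Filter-failed records are excluded unless `include_filtered = TRUE`.
#'
#' @param variants A variant tibble (see [read_vcf()]).
#' @param region Optional interval tibble restricting the count to variants
#'   whose position falls inside it (e.g. a CDS BED).
#' @param include_filtered Keep records whose FILTER is not PASS/`.`
#'   (default `FALSE`).
#' @return The Ts/Tv ratio, with attribute `counts` (named vector of
#'   transitions and transversions); `NA` with a warning if there are no
#'   transversions.
#' @export
tstv_ratio <- function(variants, region = NULL, include_filtered = FALSE) {
  v <- tibble::as_tibble(variants)
  if (!include_filtered) {
    v <- v[is.na(v$filter) | v$filter %in% c("PASS", "."), , drop = FALSE]
  }
  v <- tidyr::separate_rows(v, "alt", sep = ",")
  snv <- toupper(v$ref) %in% c("A", "C", "G", "T") &
    toupper(v$alt) %in% c("A", "C", "G", "T") &
    toupper(v$ref) != toupper(v$alt)
  v <- v[snv, , drop = FALSE]
  if (!is.null(region)) {
    region <- merge_intervals(region)
    pos_gr <- GenomicRanges::GRanges(
      v$chrom, IRanges::IRanges(start = v$pos, end = v$pos)
    )
    v <- v[IRanges::overlapsAny(pos_gr, as_granges(region)), , drop = FALSE]
  }
  if (nrow(v) == 0) stop("no qualifying SNVs")
  cls <- classify_substitution(v$ref, v$alt)
  ts <- sum(cls == "transition")
  tv <- sum(cls == "transversion")
  if (tv == 0) {
    warning("Ts/Tv undefined: no transversions among qualifying SNVs")
    ratio <- NA_real_
  } else {
    ratio <- ts / tv
  }
  structure(ratio, counts = c(transitions = ts, transversions = tv))
}
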