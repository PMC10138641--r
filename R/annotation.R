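#' Gene annotation tables
#'
#' Gene models are tidy tibbles with one row per exon or CDS segment:
#' columns `gene`, `transcript`, `chrom`, `strand`, `feature` (`"exon"` or
#' `"CDS"`), `start`, `end` (0-based half-open). Within a transcript, CDS
#' segments lie inside exons and exons do not overlap.
#'
#' `read_annotation()` accepts a GTF/GFF file (via rtracklayer; `gene_name`
#' preferred over `gene_id` for the symbol) or a refFlat-style TSV already in
#' the tidy layout above.
#'
#' @param path Path to a `.gtf`/`.gff`/`.gff3` file or a TSV with the tidy
#'   columns.
#' @return An annotation tibble.
#' @export
read_annotation <- function(path) {
  if (grepl("\\.g[tf]f3?(\\.gz)?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path)
    keep <- tolower(as.character(gr$type)) %in% c("exon", "cds")
    gr <- gr[keep]
    meta <- S4Vectors::mcols(gr)
    gene <- if (!is.null(meta$gene_name) && !all(is.na(meta$gene_name))) {
      as.character(meta$gene_name)
    } else {
      as.character(meta$gene_id)
    }
    ann <- tibble::tibble(
      gene = gene,
      transcript = as.character(meta$transcript_id),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      feature = ifelse(tolower(as.character(meta$type)) == "cds", "CDS", "exon"),
      start = as.numeric(GenomicRanges::start(gr)) - 1,
      end = as.numeric(GenomicRanges::end(gr))
    )
  } else {
    ann <- readr::read_tsv(
      path,
      col_types = readr::cols(
        gene = readr::col_character(),
        transcript = readr::col_character(),
        chrom = readr::col_character(),
        strand = readr::col_character(),
        feature = readr::col_character(),
        start = readr::col_double(),
        end = readr::col_double()
      ),
      progress = FALSE
    )
  }
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  ann <- tibble::as_tibble(ann)
  needed <- c("gene", "transcript", "chrom", "strand", "feature", "start", "end")
  missing <- setdiff(needed, names(ann))
  if (length(missing) > 0) {
    stop("annotation lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (!all(ann$feature %in% c("exon", "CDS"))) {
    stop("annotation feature column must be 'exon' or 'CDS'")
  }
  if (any(ann$end <= ann$start)) stop("annotation has intervals with end <= start")
  ann
}

#' @rdname read_annotation
#' @param ann An annotation tibble.
#' @export
write_annotation <- function(ann, path) {
  readr::write_tsv(validate_annotation(ann), path)
  invisible(path)
}

# Disjoint CDS / UTR / intron / (implicit intergenic) interval sets from an
# annotation, with fixed precedence CDS > UTR > intron across genes.
annotation_categories <- function(ann, transcripts = NULL) {
  ann <- validate_annotation(ann)
  if (!is.null(transcripts)) ann <- ann[ann$transcript %in% transcripts, ]
  exon <- ann[ann$feature == "exon", c("chrom", "start", "end")]
  cds <- ann[ann$feature == "CDS", c("chrom", "start", "end")]
  spans <- ann |>
    dplyr::group_by(.data$transcript, .data$chrom) |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end), .groups = "drop"
    )
  spans <- spans[, c("chrom", "start", "end")]
  if (nrow(exon) == 0) exon <- empty_intervals()
  if (nrow(cds) == 0) cds <- empty_intervals()
  cds_m <- merge_intervals(cds)
  exon_m <- merge_intervals(exon)
  list(
    coding = cds_m,
    utr = setdiff_intervals(exon_m, cds_m),
    intron = setdiff_intervals(merge_intervals(spans), exon_m)
  )
}

#' Partition a capture design into coding, UTR, intron and intergenic bases
#'
#' Every targeted base is assigned to exactly one category; categories sum to
#' the design's total bases. When annotations overlap (a base that is CDS in
#' one transcript and UTR or intron in another), the fixed precedence
#' CDS > UTR > intron > intergenic applies, so category totals are disjoint.
#' UTR here means exonic bases outside any CDS. The non-coding total
#' (UTR + intron) is reported both merged and split.
#'
#' @param design An interval tibble (the kit's target regions).
#' @param annotation An annotation tibble (see [read_annotation()]).
#' @param transcripts Optional character vector of transcript ids to restrict
#'   the annotation to; default uses all transcripts.
#' @param label Design name for the output row.
#' @return A one-row tibble: `label`, `coding_bases`, `utr_bases`,
#'   `intron_bases`, `intergenic_bases`, `noncoding_bases` (UTR + intron) and
#'   `total_bases`.
#' @export
partition_design <- function(design, annotation, transcripts = NULL,
                             label = "design") {
  design <- merge_intervals(design)
  cats <- annotation_categories(annotation, transcripts)
  coding <- total_bases(intersect_intervals(design, cats$coding))
  utr <- total_bases(intersect_intervals(design, cats$utr))
  intron <- total_bases(intersect_intervals(design, cats$intron))
  total <- sum(design$end - design$start)
  tibble::tibble(
    label = label,
    coding_bases = coding,
    utr_bases = utr,
    intron_bases = intron,
    intergenic_bases = total - coding - utr - intron,
    noncoding_bases = utr + intron,
    total_bases = total
  )
}

#' Build a padded gene-panel BED from gene symbols
#'
#' Takes the union of all exons of all transcripts of the listed genes,
#' extends each exon by `padding` bases on both sides (to keep nearby
#' canonical splice sites), clamps at position 0, and merges. Unknown symbols
#' are reported in a warning and in the `skipped_symbols` attribute of the
#' result, never silently dropped.
#'
#' @param genes Character vector of gene symbols.
#' @param annotation An annotation tibble.
#' @param padding Bases added on each side of every exon (default 25).
#' @return A merged interval tibble; attribute `skipped_symbols` lists symbols
#'   absent from the annotation.
#' @examples
#' ann <- tibble::tibble(
#'   gene = "G1", transcript = "T1", chrom = "chr1", strand = "+",
#'   feature = "exon", start = 100, end = 200
#' )
#' build_panel_bed("G1", ann) # [75, 225)
#' @export
build_panel_bed <- function(genes, annotation, padding = 25) {
  stopifnot(padding >= 0)
  ann <- validate_annotation(annotation)
  known <- unique(ann$gene)
  skipped <- setdiff(genes, known)
  if (length(skipped) > 0) {
    warning(
      "symbols not found in annotation, skipped: ",
      paste(skipped, collapse = ", ")
    )
  }
  found <- intersect(genes, known)
  if (length(found) == 0) stop("no panel gene symbol resolved in annotation")
  exons <- ann[ann$gene %in% found & ann$feature == "exon", ]
  panel <- merge_intervals(tibble::tibble(
    chrom = exons$chrom,
    start = pmax(0, exons$start - padding),
    end = exons$end + padding
  ))
  attr(panel, "skipped_symbols") <- skipped
  panel
}
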