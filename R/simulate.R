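#' Simulation configuration
#'
#' Bundles every knob of the synthetic sequencing experiment. Defaults mirror
#' a realistic exome-capture library on a 2 x 150 bp paired-end run:
#' fragments around 206 +/- 30 bp, a 12% duplicate rate, a 74% on-target
#' rate, and 90% of bases at Q30. The toy genome is two 150 kb chromosomes
#' with roughly 30% of bases under the capture design.
#'
#' @param seed Integer seed (mandatory; the same config always yields
#'   byte-identical outputs).
#' @param n_pairs Number of read pairs to emit (duplicates included).
#' @param read_length Read length in bp.
#' @param insert_mean,insert_sd Fragment-length distribution (normal,
#'   truncated to positive sizes at 4 sd).
#' @param duplicate_fraction Target fraction of emitted pairs that are PCR
#'   duplicates of an already-placed fragment.
#' @param off_target_fraction Fraction of fragments placed entirely outside
#'   the capture design.
#' @param nonuniformity_shape Shape `k` of the gamma distribution of
#'   per-target-interval capture-rate multipliers (mean 1). `Inf` gives
#'   uniform capture; small `k` concentrates coverage on few intervals.
#' @param q30_target Probability that a base call is high quality (Q35 vs
#'   Q20), i.e. the expected Q30 fraction.
#' @param genome Named vector of chromosome lengths (bp).
#' @param design_fraction Fraction of the genome under the capture design.
#' @param n_genes Number of toy gene models in the annotation.
#' @param n_variants,tstv_target Size and transition/transversion balance of
#'   the simulated variant set.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_pairs = 50000,
                       read_length = 150,
                       insert_mean = 206,
                       insert_sd = 30,
                       duplicate_fraction = 0.12,
                       off_target_fraction = 0.26,
                       nonuniformity_shape = Inf,
                       q30_target = 0.90,
                       genome = c(chr1 = 150000, chr2 = 150000),
                       design_fraction = 0.30,
                       n_genes = 12,
                       n_variants = 20000,
                       tstv_target = 2.7) {
  if (missing(seed)) stop("sim_config() requires a seed")
  stopifnot(
    n_pairs > 0, read_length > 0, insert_mean > 0, insert_sd >= 0,
    duplicate_fraction >= 0, duplicate_fraction < 1,
    off_target_fraction >= 0, off_target_fraction <= 1,
    nonuniformity_shape > 0, q30_target >= 0, q30_target <= 1,
    all(genome > 0), design_fraction > 0, design_fraction < 1
  )
  structure(
    list(
      seed = as.integer(seed), n_pairs = n_pairs, read_length = read_length,
      insert_mean = insert_mean, insert_sd = insert_sd,
      duplicate_fraction = duplicate_fraction,
      off_target_fraction = off_target_fraction,
      nonuniformity_shape = nonuniformity_shape, q30_target = q30_target,
      genome = genome, design_fraction = design_fraction, n_genes = n_genes,
      n_variants = n_variants, tstv_target = tstv_target
    ),
    class = "sim_config"
  )
}

# largest fragment footprint the generator may produce (overlapping mates
# extend the footprint to 2*rl - insert when the insert is short)
max_span_of <- function(config) {
  lo <- max(1, config$insert_mean - 4 * config$insert_sd)
  hi <- config$insert_mean + 4 * config$insert_sd
  ceiling(max(hi, 2 * config$read_length - lo))
}

# non-overlapping design intervals covering ~design_fraction of each
# chromosome, every interval and every gap wide enough for any fragment
sim_design <- function(config) {
  span <- max_span_of(config)
  w_min <- span + 20
  w_max <- span + 1500
  gap_min <- span + 100
  out <- list()
  for (ch in names(config$genome)) {
    len <- config$genome[[ch]]
    if (w_min + 2 * gap_min > len) {
      stop(
        "infeasible geometry: fragments of up to ", span,
        " bp cannot fit on chromosome ", ch, " (", len, " bp)"
      )
    }
    quota <- config$design_fraction * len
    covered <- 0
    cur <- 0
    rows <- list()
    while (covered < quota) {
      gap <- sample(gap_min:(gap_min + 800), 1)
      w <- sample(w_min:w_max, 1)
      if (cur + gap + w + gap_min > len) break
      rows[[length(rows) + 1]] <- tibble::tibble(
        chrom = ch, start = cur + gap, end = cur + gap + w
      )
      cur <- cur + gap + w
      covered <- covered + w
    }
    out[[ch]] <- dplyr::bind_rows(rows)
  }
  merge_intervals(dplyr::bind_rows(out))
}

# toy gene models (UTR-CDS-intron structure), laid head to tail per chromosome
sim_annotation <- function(config) {
  genes <- list()
  chroms <- names(config$genome)
  for (g in seq_len(config$n_genes)) {
    ch <- chroms[1 + (g - 1) %% length(chroms)]
    len <- config$genome[[ch]]
    n_ex <- sample(2:5, 1)
    ex_w <- sample(120:400, n_ex, replace = TRUE)
    in_w <- sample(200:800, max(0, n_ex - 1), replace = TRUE)
    span <- sum(ex_w) + sum(in_w)
    start <- sample.int(max(1, len - span - 1), 1)
    pos <- start
    ex <- list()
    for (i in seq_len(n_ex)) {
      ex[[i]] <- c(pos, pos + ex_w[i])
      pos <- pos + ex_w[i] + if (i < n_ex) in_w[i] else 0
    }
    strand <- sample(c("+", "-"), 1)
    utr5 <- min(100, ex_w[1] - 20)
    utr3 <- min(100, ex_w[n_ex] - 20)
    rows <- list()
    for (i in seq_len(n_ex)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene = sprintf("GENE%03d", g),
        transcript = sprintf("TX%03d.1", g),
        chrom = ch, strand = strand, feature = "exon",
        start = ex[[i]][1], end = ex[[i]][2]
      )
      cds_s <- if (i == 1) ex[[i]][1] + utr5 else ex[[i]][1]
      cds_e <- if (i == n_ex) ex[[i]][2] - utr3 else ex[[i]][2]
      if (cds_e > cds_s) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          gene = sprintf("GENE%03d", g),
          transcript = sprintf("TX%03d.1", g),
          chrom = ch, strand = strand, feature = "CDS",
          start = cds_s, end = cds_e
        )
      }
    }
    genes[[g]] <- dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(genes)
}

qual_string <- function(k_hi, read_length) {
  paste0(
    strrep(rawToChar(as.raw(35 + 33)), k_hi),
    strrep(rawToChar(as.raw(20 + 33)), read_length - k_hi)
  )
}

#' Simulate a capture-sequencing experiment with known truth
#'
#' Generates coordinate-sorted paired-end alignment records over a toy
#' genome, together with the capture design, a toy gene annotation and a
#' truth ledger holding every injected parameter. Fragments land fully
#' inside a design interval with probability `1 - off_target_fraction`
#' (interval choice weighted by length times a gamma multiplier controlling
#' coverage non-uniformity) and fully outside otherwise. Duplicate pairs
#' re-emit an already-placed fragment at identical coordinates with fresh
#' base qualities, matching the coordinate criterion [mark_duplicates()]
#' uses. No mapper is involved: records carry consistent CIGAR and template
#' lengths by construction.
#'
#' @param config A [sim_config()].
#' @return A list: `reads` (alignment tibble as from [read_alignments()],
#'   plus a `qual` string column), `design`, `annotation`, `variants`,
#'   `truth` (ledger: per-pair origin/duplicate/on-target labels and realized
#'   parameter values), `genome`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    design <- sim_design(config)
    annotation <- sim_annotation(config)
    rl <- config$read_length

    n_dup <- round(config$n_pairs * config$duplicate_fraction)
    n_unique <- config$n_pairs - n_dup

    lo <- max(1, config$insert_mean - 4 * config$insert_sd)
    hi <- config$insert_mean + 4 * config$insert_sd
    insert <- pmin(pmax(round(
      stats::rnorm(n_unique, config$insert_mean, config$insert_sd)
    ), lo), hi)
    span <- pmax(insert, 2 * rl - insert)

    on_target <- stats::runif(n_unique) >= config$off_target_fraction

    iv_w <- design$end - design$start
    mult <- if (is.finite(config$nonuniformity_shape)) {
      stats::rgamma(
        nrow(design),
        shape = config$nonuniformity_shape,
        rate = config$nonuniformity_shape
      )
    } else {
      rep(1, nrow(design))
    }
    gaps <- setdiff_intervals(
      tibble::tibble(
        chrom = names(config$genome),
        start = 0, end = as.numeric(config$genome)
      ),
      design
    )
    gap_w <- gaps$end - gaps$start

    frag_chrom <- character(n_unique)
    frag_start <- numeric(n_unique) # placement of the read-span block
    idx_on <- which(on_target)
    if (length(idx_on) > 0) {
      pick <- sample.int(
        nrow(design), length(idx_on),
        replace = TRUE, prob = iv_w * mult
      )
      frag_chrom[idx_on] <- design$chrom[pick]
      frag_start[idx_on] <- design$start[pick] +
        floor(stats::runif(length(idx_on)) * (iv_w[pick] - span[idx_on] + 1))
    }
    idx_off <- which(!on_target)
    if (length(idx_off) > 0) {
      eligible <- which(gap_w > max(span) + 2)
      pick <- eligible[sample.int(
        length(eligible), length(idx_off),
        replace = TRUE, prob = gap_w[eligible]
      )]
      frag_chrom[idx_off] <- gaps$chrom[pick]
      frag_start[idx_off] <- gaps$start[pick] + 1 +
        floor(stats::runif(length(idx_off)) * (gap_w[pick] - span[idx_off] - 2))
    }

    origin <- c(seq_len(n_unique), sample.int(n_unique, n_dup, replace = TRUE))
    pair_insert <- insert[origin]
    pair_span_start <- frag_start[origin]
    pair_chrom <- frag_chrom[origin]
    pair_on <- on_target[origin]
    is_dup_pair <- c(rep(FALSE, n_unique), rep(TRUE, n_dup))
    n_pairs <- length(origin)
    qname <- sprintf("sim%07d", seq_len(n_pairs))

    # fragment start: span block left edge plus the mate-overlap shift
    fs <- pair_span_start + pmax(0, rl - pair_insert)
    r1_start <- fs
    r2_start <- fs + pair_insert - rl

    k_hi <- matrix(
      stats::rbinom(2 * n_pairs, rl, config$q30_target),
      ncol = 2
    )
    cigar <- paste0(rl, "M")
    mk_read <- function(start, strand, tlen, is_first, k) {
      tibble::tibble(
        qname = qname,
        flag = bitwOr(
          bitwOr(1L + 2L, ifelse(strand == "-", 16L, 32L)),
          ifelse(is_first, 64L, 128L)
        ),
        chrom = pair_chrom,
        start = start,
        end = start + rl,
        strand = strand,
        cigar = cigar,
        mate_chrom = pair_chrom,
        tlen = tlen,
        qual_sum = 35 * k + 20 * (rl - k),
        paired = TRUE,
        proper_pair = TRUE,
        is_first = is_first,
        secondary = FALSE,
        mate_mapped = TRUE,
        duplicate = FALSE,
        qual = qual_string(k, rl)
      )
    }
    reads <- dplyr::bind_rows(
      mk_read(r1_start, "+", pair_insert, TRUE, k_hi[, 1]),
      mk_read(r2_start, "-", -pair_insert, FALSE, k_hi[, 2])
    )
    reads$unclipped_5p <- unclipped_5p(reads)
    reads <- dplyr::arrange(reads, .data$chrom, .data$start, .data$qname)

    variants <- simulate_variants(
      n = config$n_variants, tstv_target = config$tstv_target,
      region = design, seed = config$seed + 1L
    )

    truth <- list(
      config = config,
      pairs = tibble::tibble(
        qname = qname, origin = origin, is_duplicate = is_dup_pair,
        on_target = pair_on, insert = pair_insert, chrom = pair_chrom,
        frag_start = fs
      ),
      duplicate_fraction = n_dup / n_pairs,
      off_target_fraction = mean(!pair_on),
      median_insert = stats::median(pair_insert),
      q30 = mean(k_hi) / rl,
      tstv_target = config$tstv_target
    )
    list(
      reads = reads, design = design, annotation = annotation,
      variants = variants, truth = truth, genome = config$genome
    )
  })
}

#' Simulate a SNV set with a controlled Ts/Tv ratio
#'
#' Draws `n` SNVs at distinct positions inside `region`; each is a transition
#' with probability `tstv_target / (1 + tstv_target)`, so the measured Ts/Tv
#' converges to the target.
#'
#' @param n Number of SNVs.
#' @param tstv_target Target transition/transversion ratio (> 0).
#' @param region An interval tibble positions are drawn from.
#' @param seed Integer seed.
#' @return A variant tibble (`chrom`, `pos`, `ref`, `alt`, `filter`).
#' @export
simulate_variants <- function(n, tstv_target, region, seed) {
  stopifnot(tstv_target > 0, n >= 0)
  region <- merge_intervals(region)
  total <- sum(region$end - region$start)
  if (n > total) {
    stop("n (", n, ") exceeds region size (", total, " bases)")
  }
  if (n == 0) {
    return(tibble::tibble(
      chrom = character(), pos = numeric(), ref = character(),
      alt = character(), filter = character()
    ))
  }
  withr::with_seed(seed, {
    base_idx <- sort(sample.int(total, n))
    cum <- cumsum(region$end - region$start)
    row <- findInterval(base_idx - 1, c(0, cum), rightmost.closed = FALSE)
    offset <- base_idx - c(0, cum)[row] - 1
    pos <- region$start[row] + offset + 1 # 1-based VCF position
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    is_ts <- stats::runif(n) < tstv_target / (1 + tstv_target)
    ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
    tv_partners <- list(
      A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G")
    )
    alt <- ifelse(
      is_ts,
      ts_partner[ref],
      vapply(ref, function(b) sample(tv_partners[[b]], 1), character(1))
    )
    tibble::tibble(
      chrom = region$chrom[row], pos = pos, ref = ref,
      alt = unname(alt), filter = "PASS"
    )
  })
}

# ---------------------------------------------------------------------------
# plain-text writers for the simulated records

#' Write alignment records as a headered, coordinate-sorted SAM file
#'
#' @param reads An alignment tibble carrying a `qual` column (as produced by
#'   [simulate_experiment()]).
#' @param path Output `.sam` path.
#' @param genome Named vector of chromosome lengths for the `@SQ` header.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, genome) {
  reads <- dplyr::arrange(reads, .data$chrom, .data$start, .data$qname)
  qwidth <- GenomicAlignments::cigarWidthAlongQuerySpace(reads$cigar)
  mate_key <- paste(reads$qname, !reads$is_first)
  self_key <- paste(reads$qname, reads$is_first)
  mate_pos <- reads$start[match(mate_key, self_key)]
  mate_pos[is.na(mate_pos)] <- reads$start[is.na(mate_pos)]
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(genome), as.integer(genome))
  )
  body <- sprintf(
    "%s\t%d\t%s\t%d\t60\t%s\t%s\t%d\t%d\t%s\t%s",
    reads$qname,
    reads$flag,
    reads$chrom,
    as.integer(reads$start + 1),
    reads$cigar,
    ifelse(reads$mate_chrom == reads$chrom, "=", reads$mate_chrom),
    as.integer(mate_pos + 1),
    as.integer(reads$tlen),
    strrep("A", qwidth),
    reads$qual
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write paired FASTQ (Phred+33) from alignment records
#'
#' First and second mates go to separate files; `.gz` paths are compressed.
#'
#' @param reads An alignment tibble with a `qual` column.
#' @param path_r1,path_r2 Output FASTQ paths.
#' @return The two paths, invisibly.
#' @export
write_fastq <- function(reads, path_r1, path_r2) {
  emit <- function(r, path) {
    qwidth <- GenomicAlignments::cigarWidthAlongQuerySpace(r$cigar)
    lines <- as.vector(rbind(
      paste0("@", r$qname), strrep("A", qwidth), "+", r$qual
    ))
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    writeLines(lines, con)
  }
  r <- dplyr::arrange(reads, .data$qname)
  emit(r[r$is_first, ], path_r1)
  emit(r[!r$is_first, ], path_r2)
  invisible(c(path_r1, path_r2))
}

#' Write a variant tibble as VCF v4.2
#'
#' @param variants A variant tibble (`chrom`, `pos`, `ref`, `alt`, `filter`).
#' @param path Output `.vcf` path.
#' @param genome Optional named chromosome lengths for `##contig` lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, genome = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(genome)) {
      sprintf("##contig=<ID=%s,length=%d>", names(genome), as.integer(genome))
    },
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  v <- dplyr::arrange(tibble::as_tibble(variants), .data$chrom, .data$pos)
  body <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\t%s\t.",
    v$chrom, as.integer(v$pos), v$ref, v$alt, v$filter
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a toy annotation as GTF
#'
#' @param ann An annotation tibble (see [read_annotation()]).
#' @param path Output `.gtf` path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  ann <- validate_annotation(ann)
  body <- sprintf(
    "%s\tkiteval\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\"; gene_name \"%s\";",
    ann$chrom, ann$feature, as.integer(ann$start + 1), as.integer(ann$end),
    ann$strand, ann$gene, ann$transcript, ann$gene
  )
  writeLines(body, path)
  invisible(path)
}
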