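# Brute-force per-base oracles over toy genomes (<= 10 kb) plus small random
# fixture generators. The oracles work on plain boolean/integer arrays and
# never call the interval or coverage code they are used to check.

# boolean membership array per chromosome
oracle_bases <- function(intervals, genome) {
  out <- lapply(genome, function(len) logical(len))
  for (i in seq_len(nrow(intervals))) {
    ch <- intervals$chrom[i]
    idx <- seq(intervals$start[i] + 1, intervals$end[i])
    out[[ch]][idx] <- TRUE
  }
  out
}

oracle_union_count <- function(intervals, genome) {
  sum(vapply(oracle_bases(intervals, genome), sum, numeric(1)))
}

# per exact-subset base counts for a named list of designs
oracle_multi_intersect <- function(designs, genome) {
  arrays <- lapply(designs, oracle_bases, genome = genome)
  counts <- list()
  for (ch in names(genome)) {
    mat <- vapply(arrays, function(a) a[[ch]], logical(genome[[ch]]))
    pattern <- apply(mat, 1, paste, collapse = "/")
    tab <- table(pattern[rowSums(mat) > 0])
    for (p in names(tab)) {
      counts[[p]] <- (counts[[p]] %||% 0) + as.numeric(tab[[p]])
    }
  }
  counts
}

# per-base category with precedence CDS > UTR > intron > intergenic
oracle_partition <- function(design, annotation, genome) {
  in_design <- oracle_bases(design, genome)
  cds <- oracle_bases(
    annotation[annotation$feature == "CDS", c("chrom", "start", "end")],
    genome
  )
  exon <- oracle_bases(
    annotation[annotation$feature == "exon", c("chrom", "start", "end")],
    genome
  )
  spans <- do.call(rbind, lapply(
    split(annotation, annotation$transcript),
    function(tx) data.frame(
      chrom = tx$chrom[1], start = min(tx$start), end = max(tx$end)
    )
  ))
  span <- oracle_bases(spans, genome)
  tot <- c(coding = 0, utr = 0, intron = 0, intergenic = 0)
  for (ch in names(genome)) {
    d <- in_design[[ch]]
    tot["coding"] <- tot["coding"] + sum(d & cds[[ch]])
    tot["utr"] <- tot["utr"] + sum(d & !cds[[ch]] & exon[[ch]])
    tot["intron"] <- tot["intron"] + sum(d & !exon[[ch]] & span[[ch]])
    tot["intergenic"] <- tot["intergenic"] + sum(d & !span[[ch]])
  }
  tot
}

# pileup oracle for reads whose CIGAR is a single match block
oracle_depth <- function(reads, genome, exclude_duplicates = FALSE) {
  out <- lapply(genome, function(len) integer(len))
  r <- reads[!reads$secondary, , drop = FALSE]
  if (exclude_duplicates) r <- r[!r$duplicate, , drop = FALSE]
  for (i in seq_len(nrow(r))) {
    ch <- r$chrom[i]
    idx <- seq(r$start[i] + 1, r$end[i])
    out[[ch]][idx] <- out[[ch]][idx] + 1L
  }
  out
}

oracle_depth_over <- function(reads, target, genome, exclude_duplicates = FALSE) {
  pile <- oracle_depth(reads, genome, exclude_duplicates)
  unlist(lapply(seq_len(nrow(target)), function(i) {
    pile[[target$chrom[i]]][seq(target$start[i] + 1, target$end[i])]
  }), use.names = FALSE)
}

oracle_on_target <- function(reads, target, genome) {
  member <- oracle_bases(target, genome)
  r <- reads[!reads$secondary, , drop = FALSE]
  on <- 0
  tot <- 0
  for (i in seq_len(nrow(r))) {
    idx <- seq(r$start[i] + 1, r$end[i])
    on <- on + sum(member[[r$chrom[i]]][idx])
    tot <- tot + length(idx)
  }
  on / tot
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# random fixture generators (toy scale)

rand_intervals <- function(n, genome, max_len = 60) {
  chrom <- sample(names(genome), n, replace = TRUE)
  len <- sample(max_len, n, replace = TRUE)
  start <- vapply(
    seq_len(n),
    function(i) sample.int(genome[[chrom[i]]] - len[i], 1) - 1,
    numeric(1)
  )
  tibble::tibble(chrom = chrom, start = start, end = start + len)
}

rand_annotation <- function(n_genes, genome) {
  rows <- list()
  for (g in seq_len(n_genes)) {
    ch <- sample(names(genome), 1)
    len <- genome[[ch]]
    n_ex <- sample(1:3, 1)
    span_len <- sample(200:min(800, len - 2), 1)
    span_start <- sample.int(len - span_len, 1) - 1
    cuts <- sort(sample(seq(span_start, span_start + span_len - 20, by = 10), 2 * n_ex))
    for (i in seq_len(n_ex)) {
      s <- cuts[2 * i - 1]
      e <- max(cuts[2 * i], s + 10)
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene = sprintf("G%02d", g), transcript = sprintf("T%02d", g),
        chrom = ch, strand = "+", feature = "exon", start = s, end = e
      )
      if (stats::runif(1) < 0.7) {
        mid <- floor((s + e) / 2)
        rows[[length(rows) + 1]] <- tibble::tibble(
          gene = sprintf("G%02d", g), transcript = sprintf("T%02d", g),
          chrom = ch, strand = "+", feature = "CDS",
          start = s, end = max(mid, s + 1)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

# minimal alignment tibble with the columns the metric functions use;
# one properly-paired template per call, single-block CIGAR
pair_records <- function(qname, chrom, frag_start, insert, read_length = 50,
                         qual_sum = c(1000, 1000)) {
  r1_start <- frag_start
  r2_start <- frag_start + insert - read_length
  tibble::tibble(
    qname = qname,
    flag = c(99L, 147L),
    chrom = chrom,
    start = c(r1_start, r2_start),
    end = c(r1_start, r2_start) + read_length,
    strand = c("+", "-"),
    cigar = paste0(read_length, "M"),
    mate_chrom = chrom,
    tlen = c(insert, -insert),
    qual_sum = qual_sum,
    paired = TRUE,
    proper_pair = TRUE,
    is_first = c(TRUE, FALSE),
    secondary = FALSE,
    mate_mapped = TRUE,
    duplicate = FALSE,
    unclipped_5p = c(r1_start, r2_start + read_length)
  )
}

rand_reads <- function(n_pairs, genome, read_length = 50, insert = 120) {
  dplyr::bind_rows(lapply(seq_len(n_pairs), function(i) {
    ch <- sample(names(genome), 1)
    fs <- sample.int(genome[[ch]] - insert - 1, 1) - 1
    pair_records(sprintf("p%04d", i), ch, fs, insert, read_length)
  }))
}

# one shared 50k-pair simulation reused by recovery and monotonicity tests
cached_sim <- local({
  env <- new.env()
  function() {
    if (is.null(env$sim)) {
      env$sim <- simulate_experiment(sim_config(seed = 7))
    }
    env$sim
  }
})
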