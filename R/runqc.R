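#' Phred quality scores and error rates
#'
#' `phred_from_error()` converts a per-base error probability to a Q-score,
#' `Q = -10 * log10(e)`; `error_from_phred()` inverts it. Q30 corresponds to
#' a 1-in-1000 base-call error.
#'
#' @param error_rate Error probability in `(0, 1]` (vectorised).
#' @param q Q-score (vectorised).
#' @return Numeric vector.
#' @examples
#' phred_from_error(0.001) # 30
#' @export
phred_from_error <- function(error_rate) {
  if (any(error_rate <= 0) || any(error_rate > 1)) {
    stop("error_rate must be in (0, 1]")
  }
  -10 * log10(error_rate)
}

#' @rdname phred_from_error
#' @export
error_from_phred <- function(q) 10^(-q / 10)

#' Chastity of a base call
#'
#' Ratio of the brightest base intensity to the sum of the brightest and
#' second-brightest intensities, `Ia / (Ia + Ib)`. Illumina's cluster filter
#' fails a read if any base call in the first 25 cycles has chastity below
#' 0.6; `passes_chastity()` applies that rule to a vector of per-cycle
#' chastity values.
#'
#' @param intensity_brightest,intensity_second Non-negative signal
#'   intensities (vectorised; not both zero).
#' @return Chastity ratio in `[0.5, 1]` for `Ia >= Ib`.
#' @examples
#' chastity(60, 40) # 0.6, boundary pass
#' @export
chastity <- function(intensity_brightest, intensity_second) {
  if (any(intensity_brightest < 0) || any(intensity_second < 0)) {
    stop("intensities must be non-negative")
  }
  tot <- intensity_brightest + intensity_second
  if (any(tot == 0)) stop("both intensities are zero")
  intensity_brightest / tot
}

#' @rdname chastity
#' @param chastity_by_cycle Per-cycle chastity values of one read.
#' @param n_cycles Number of leading cycles the filter inspects (default 25).
#' @export
passes_chastity <- function(chastity_by_cycle, n_cycles = 25) {
  all(utils::head(chastity_by_cycle, n_cycles) >= 0.6)
}

#' Percentage of Q30 bases in FASTQ reads
#'
#' Share of base calls with Phred quality >= 30 across one or more FASTQ
#' files (plain or gzipped, Phred+33).
#'
#' @param paths Character vector of FASTQ paths.
#' @return Percentage in `[0, 100]`.
#' @export
q30_from_fastq <- function(paths) {
  qs <- lapply(paths, function(p) {
    x <- Biostrings::readDNAStringSet(p, format = "fastq", with.qualities = TRUE)
    if (length(x) == 0) {
      return(integer(0))
    }
    unlist(as(
      Biostrings::PhredQuality(S4Vectors::mcols(x)$qualities),
      "IntegerList"
    ), use.names = FALSE)
  })
  qs <- unlist(qs, use.names = FALSE)
  if (length(qs) == 0) stop("no bases found in FASTQ input")
  100 * mean(qs >= 30)
}

#' Acceptable cluster-density ranges by instrument and chemistry
#'
#' Reference table of acceptable raw cluster densities (K/mm^2) for common
#' Illumina instrument/chemistry combinations.
#'
#' @return A tibble with `instrument`, `density_min`, `density_max`.
#' @export
instrument_density_table <- function() {
  tibble::tribble(
    ~instrument, ~density_min, ~density_max,
    "miniseq-high", 170, 220,
    "miniseq-mid", 170, 220,
    "miseq-v2", 1000, 1200,
    "miseq-v3", 1200, 1400,
    "nextseq-v2-high", 170, 220,
    "nextseq-v2-mid", 170, 220,
    "hiseq2500-v1", 850, 1000,
    "hiseq2500-v2", 850, 1000,
    "hiseq2500-v3", 750, 850,
    "hiseq2500-v4", 950, 1050
  )
}

#' Read a run summary of sequencer-reported metrics
#'
#' Accepts JSON (a flat object) or a one-row TSV with keys/columns
#' `instrument`, `cluster_density` (K/mm^2), `percent_pf`, `percent_q30`,
#' `percent_phix`.
#'
#' @param path File path (`.json` or `.tsv`).
#' @return A one-row tibble with those columns.
#' @export
read_run_summary <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    out <- tibble::as_tibble(x[c(
      "instrument", "cluster_density", "percent_pf", "percent_q30",
      "percent_phix"
    )])
  } else {
    out <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  }
  needed <- c(
    "instrument", "cluster_density", "percent_pf", "percent_q30",
    "percent_phix"
  )
  missing <- setdiff(needed, names(out))
  if (length(missing) > 0) {
    stop("run summary lacks: ", paste(missing, collapse = ", "))
  }
  out
}

#' Evaluate run-level sequencing quality
#'
#' Applies the four raw-sequencing acceptability rules to a run summary:
#' cluster density within the instrument's range, clusters passing filter
#' >= 65%, Q30 >= 80% (override for degraded/FFPE DNA via `q30_threshold`),
#' and PhiX alignment strictly above 0.3% (around 1% is the usual aim, which
#' is reported informationally, not enforced). Failures carry the common
#' cause to investigate.
#'
#' @param summary A one-row tibble or named list with `instrument`,
#'   `cluster_density`, `percent_pf`, `percent_q30`, `percent_phix`.
#' @param density_table Instrument density ranges
#'   (default [instrument_density_table()]).
#' @param pf_threshold,q30_threshold,phix_threshold Override thresholds.
#' @return A verdict tibble: `metric`, `value`, `rule`, `pass`, `note`.
#' @examples
#' evaluate_run(list(
#'   instrument = "nextseq-v2-high", cluster_density = 200,
#'   percent_pf = 70, percent_q30 = 85, percent_phix = 0.5
#' ))
#' @export
evaluate_run <- function(summary, density_table = instrument_density_table(),
                         pf_threshold = 65, q30_threshold = 80,
                         phix_threshold = 0.3) {
  s <- as.list(summary)
  row <- density_table[density_table$instrument == s$instrument, , drop = FALSE]
  if (nrow(row) != 1) {
    stop(
      "unknown instrument '", s$instrument, "'; known: ",
      paste(density_table$instrument, collapse = ", ")
    )
  }
  density_ok <- s$cluster_density >= row$density_min &&
    s$cluster_density <= row$density_max
  tibble::tibble(
    metric = c(
      "cluster_density", "percent_pf", "percent_q30", "percent_phix"
    ),
    value = as.numeric(c(
      s$cluster_density, s$percent_pf, s$percent_q30, s$percent_phix
    )),
    rule = c(
      sprintf("within %g-%g K/mm^2", row$density_min, row$density_max),
      sprintf(">= %g%%", pf_threshold),
      sprintf(">= %g%%", q30_threshold),
      sprintf("> %g%%", phix_threshold)
    ),
    pass = c(
      density_ok,
      s$percent_pf >= pf_threshold,
      s$percent_q30 >= q30_threshold,
      s$percent_phix > phix_threshold
    ),
    note = c(
      if (density_ok) {
        ""
      } else {
        "inaccurate library quantification causes over/under-clustering"
      },
      if (s$percent_pf >= pf_threshold) {
        ""
      } else {
        "%PF under 65% is most often due to over-clustering"
      },
      if (s$percent_q30 >= q30_threshold) {
        ""
      } else {
        "low Q30 usually reflects poor DNA quality or aging reagents"
      },
      "around 1% PhiX is the usual aim"
    )
  )
}
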