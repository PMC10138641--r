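#' Compute the per-sample quality metric row
#'
#' Runs the whole sample-level pipeline on an alignment table: insert size,
#' duplicate marking, on-target rate, depth of coverage with and without
#' duplicates, coverage rate at 30X, the two uniformity metrics (on the
#' deduplicated profile) and, if variants are supplied, the Ts/Tv ratio.
#' Percentages are on the 0--100 scale.
#'
#' @param reads An alignment tibble.
#' @param target An interval tibble (the kit target).
#' @param variants Optional variant tibble for Ts/Tv.
#' @param label Sample or kit label.
#' @param effort Optional sequencing-effort label.
#' @return A one-row tibble: `label`, (`effort`,) `median_insert`,
#'   `on_target_pct`, `mean_cov_dup`, `duplicate_pct`, `mean_cov_nodup`,
#'   `target_at_30x_pct`, `fold80`, `evenness`, `tstv`.
#' @export
sample_metrics <- function(reads, target, variants = NULL, label = "sample",
                           effort = NULL) {
  reads <- mark_duplicates(reads)
  ins <- insert_size_stats(reads)
  prof_dup <- depth_profile(reads, target, include_duplicates = TRUE)
  prof_nodup <- depth_profile(reads, target, include_duplicates = FALSE)
  out <- tibble::tibble(
    label = label,
    median_insert = ins$median_insert,
    on_target_pct = 100 * on_target_rate(reads, target),
    mean_cov_dup = mean_depth(prof_dup),
    duplicate_pct = 100 * duplicate_rate(reads),
    mean_cov_nodup = mean_depth(prof_nodup),
    target_at_30x_pct = 100 * coverage_rate(prof_nodup, 30)$rate,
    fold80 = suppressWarnings(fold80(prof_nodup)),
    evenness = evenness(prof_nodup),
    tstv = if (is.null(variants)) NA_real_ else as.numeric(tstv_ratio(variants))
  )
  if (!is.null(effort)) out <- dplyr::mutate(out, effort = effort, .after = "label")
  out
}

#' Acceptability rules for sample metrics
#'
#' The default clinical-diagnostic rule set: duplicate rate strictly under
#' 20%, on-target rate above 80%, mean on-target coverage of at least 100X
#' (applied to the duplicate-inclusive mean), at least 90% of target bases
#' covered at 30X, and Ts/Tv above 2.4 for CDS-dominated captures. Median
#' insert size and the two uniformity metrics carry no hard bound and are
#' advisory: they are reported with their expectation but never fail a
#' sample. Boundary semantics follow each rule's operator: `<` and `>` are
#' strict, `>=` inclusive.
#'
#' @return A tibble with `metric`, `direction` (`"<"`, `">"`, `">="`,
#'   `"advisory"`), `bound` and `note`.
#' @export
threshold_config <- function() {
  tibble::tribble(
    ~metric, ~direction, ~bound, ~note,
    "median_insert", "advisory", NA,
    "expected around 200-250 bp, library dependent; adjust fragmentation",
    "duplicate_pct", "<", 20,
    "reduce PCR cycles or increase input material",
    "on_target_pct", ">", 80,
    paste(
      "strongly influenced by insert size; whole-exome captures",
      "commonly sit in the low 70s and are still usable"
    ),
    "mean_cov_dup", ">=", 100,
    "fewer samples per run raises coverage",
    "target_at_30x_pct", ">=", 90,
    "a change of capture design or added effort raises the rate",
    "fold80", "advisory", NA,
    "lower is more uniform; 1 means perfect uniformity",
    "evenness", "advisory", NA,
    "higher is more uniform; 100% means perfect uniformity",
    "tstv", ">", 2.4,
    "around 2 genome-wide, a little above 3 in coding regions"
  )
}

rule_string <- function(direction, bound) {
  ifelse(direction == "advisory", "advisory", paste(direction, bound))
}

#' Evaluate one sample against the acceptability rules
#'
#' Applies [threshold_config()] (or an override) to a metric row, yielding a
#' per-metric pass/fail/advisory ledger. A metric missing from the row fails
#' loudly unless its rule is advisory.
#'
#' @param metrics A one-row tibble from [sample_metrics()] (or with the same
#'   columns).
#' @param config A rules tibble (default [threshold_config()]).
#' @return A tibble: `metric`, `value`, `rule`, `pass` (`NA` for advisory),
#'   `note`.
#' @examples
#' m <- tibble::tibble(duplicate_pct = 12.09)
#' evaluate_sample(m, config = dplyr::filter(
#'   threshold_config(), metric == "duplicate_pct"
#' ))
#' @export
evaluate_sample <- function(metrics, config = threshold_config()) {
  metrics <- tibble::as_tibble(metrics)
  stopifnot(nrow(metrics) == 1)
  rows <- lapply(seq_len(nrow(config)), function(i) {
    rule <- config[i, ]
    has <- rule$metric %in% names(metrics) && !is.na(metrics[[rule$metric]])
    if (!has && rule$direction != "advisory") {
      stop("metric '", rule$metric, "' missing and not advisory")
    }
    value <- if (has) as.numeric(metrics[[rule$metric]]) else NA_real_
    pass <- switch(rule$direction,
      "advisory" = NA,
      "<" = value < rule$bound,
      ">" = value > rule$bound,
      ">=" = value >= rule$bound,
      "<=" = value <= rule$bound,
      stop("unknown direction ", rule$direction)
    )
    note <- if (isFALSE(pass) || is.na(pass)) rule$note else ""
    tibble::tibble(
      metric = rule$metric,
      value = value,
      rule = rule_string(rule$direction, rule$bound),
      pass = pass,
      note = note
    )
  })
  dplyr::bind_rows(rows)
}

# merit direction per comparable metric; NA = no direction, never marked
merit_directions <- function() {
  c(
    median_insert = NA,
    on_target_pct = "higher",
    mean_cov_dup = "higher",
    duplicate_pct = "lower",
    mean_cov_nodup = "higher",
    target_at_30x_pct = "higher",
    fold80 = "lower",
    evenness = "higher",
    tstv = "higher"
  )
}

#' Compare capture kits across sequencing efforts
#'
#' Assembles the kit-comparison matrix: per kit and effort, every sample
#' metric, with the best kit marked per cell wherever the metric has a stated
#' direction of merit (higher coverage better, lower duplicate rate better,
#' lower fold-80 better; insert size has none and is never marked). Exact
#' ties are reported unmarked. Kits are ranked by (a) number of threshold
#' failures, (b) duplicate rate, (c) minimal effort to reach 90% of target
#' bases at 30X; the order is configurable.
#'
#' @param kits A named list (>= 2) of per-kit metric tibbles, each with an
#'   `effort` column plus [sample_metrics()] columns, over matching efforts.
#' @param config Threshold rules used for the verdict ledger.
#' @param rank_by Ranking criteria in priority order; any ordering of
#'   `"failures"`, `"duplicates"`, `"minimal_effort"`.
#' @return A `kit_comparison` object with elements `table` (long tibble:
#'   `kit`, `effort`, `metric`, `value`, `best`), `verdicts`, `ranking`.
#' @export
compare_kits <- function(kits, config = threshold_config(),
                         rank_by = c("failures", "duplicates", "minimal_effort")) {
  if (!is.list(kits) || length(kits) < 2 || is.null(names(kits))) {
    stop("compare_kits() needs a named list of at least 2 kits")
  }
  rank_by <- match.arg(
    rank_by, c("failures", "duplicates", "minimal_effort"),
    several.ok = TRUE
  )
  efforts <- lapply(kits, function(k) sort(unique(k$effort)))
  if (length(unique(efforts)) != 1) {
    stop("kits have mismatched effort grids")
  }
  wide <- dplyr::bind_rows(
    lapply(names(kits), function(nm) {
      dplyr::mutate(tibble::as_tibble(kits[[nm]]), kit = nm, .before = 1)
    })
  )
  dirs <- merit_directions()
  metric_cols <- intersect(names(dirs), names(wide))
  long <- tidyr::pivot_longer(
    wide[, c("kit", "effort", metric_cols)],
    dplyr::all_of(metric_cols),
    names_to = "metric", values_to = "value"
  )
  long <- long |>
    dplyr::group_by(.data$effort, .data$metric) |>
    dplyr::mutate(
      best = {
        dir <- dirs[[unique(.data$metric)]]
        if (is.na(dir) || dplyr::n_distinct(.data$value) <= 1) {
          rep(FALSE, dplyr::n())
        } else if (dir == "higher") {
          .data$value == max(.data$value)
        } else {
          .data$value == min(.data$value)
        }
      }
    ) |>
    dplyr::ungroup()

  verdicts <- dplyr::bind_rows(lapply(seq_len(nrow(wide)), function(i) {
    dplyr::mutate(
      evaluate_sample(wide[i, ], config),
      kit = wide$kit[i], effort = wide$effort[i], .before = 1
    )
  }))

  ranking <- wide |>
    dplyr::group_by(.data$kit) |>
    dplyr::summarise(
      mean_duplicate_pct = mean(.data$duplicate_pct),
      effort_90_at_30x = suppressMessages(minimal_effort(
        effort_grid(.data$effort, .data$target_at_30x_pct / 100, 30),
        depth = 30, required_rate = 0.90
      )),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      verdicts |>
        dplyr::group_by(.data$kit) |>
        dplyr::summarise(
          n_fail = sum(!.data$pass, na.rm = TRUE), .groups = "drop"
        ),
      by = "kit"
    )
  keys <- list(
    failures = ranking$n_fail,
    duplicates = ranking$mean_duplicate_pct,
    minimal_effort = ifelse(
      is.na(ranking$effort_90_at_30x), Inf, ranking$effort_90_at_30x
    )
  )
  ranking$rank <- do.call(order, keys[rank_by]) |> order()
  ranking <- dplyr::arrange(ranking, .data$rank)

  structure(
    list(table = long, verdicts = verdicts, ranking = ranking),
    class = "kit_comparison"
  )
}

#' @export
print.kit_comparison <- function(x, ...) {
  cat("<kit_comparison> ", dplyr::n_distinct(x$table$kit), " kits x ",
    dplyr::n_distinct(x$table$effort), " efforts\n",
    sep = ""
  )
  print(x$ranking)
  invisible(x)
}

#' @method tidy kit_comparison
#' @export
tidy.kit_comparison <- function(x, ...) x$table

#' @method glance kit_comparison
#' @export
glance.kit_comparison <- function(x, ...) x$ranking

fmt_num <- function(x, digits = 2) {
  ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "f"), x))
}

#' Write the kit-evaluation report
#'
#' Emits the final comparison as machine-readable JSON, TSV tables and a
#' human-readable summary. Every number is taken verbatim from the upstream
#' comparison object; absent sections (design partition, panel coverage) are
#' marked "not evaluated". Regeneration from the same inputs is
#' byte-identical (fixed ordering and float formatting).
#'
#' @param comparison A `kit_comparison` from [compare_kits()].
#' @param design_partition Optional partition tibble from
#'   [partition_design()] (one row per design).
#' @param panel_results Optional named list of panel effort grids from
#'   [panel_coverage_report()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written: `report.json`, `kit_metrics.tsv`,
#'   `verdicts.tsv`, `summary.txt`.
#' @export
render_report <- function(comparison, design_partition = NULL,
                          panel_results = NULL, dir = ".") {
  stopifnot(inherits(comparison, "kit_comparison"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab <- dplyr::arrange(
    comparison$table, .data$kit, .data$effort, .data$metric
  )
  verd <- dplyr::arrange(
    comparison$verdicts, .data$kit, .data$effort, .data$metric
  )

  report <- list(
    kits = sort(unique(tab$kit)),
    metrics = tab,
    verdicts = verd,
    ranking = comparison$ranking,
    design_partition = if (is.null(design_partition)) {
      "not evaluated"
    } else {
      design_partition
    },
    panel_coverage = if (is.null(panel_results)) {
      "not evaluated"
    } else {
      panel_results
    }
  )
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(
    report, json_path,
    auto_unbox = TRUE, digits = 6, pretty = TRUE
  )

  metrics_path <- file.path(dir, "kit_metrics.tsv")
  readr::write_tsv(
    dplyr::mutate(tab, value = fmt_num(.data$value)), metrics_path
  )
  verdicts_path <- file.path(dir, "verdicts.tsv")
  readr::write_tsv(
    dplyr::mutate(verd, value = fmt_num(.data$value)), verdicts_path
  )

  summary_path <- file.path(dir, "summary.txt")
  lines <- c(
    "Capture-kit evaluation summary",
    "==============================",
    "",
    "Ranking (1 = preferred):",
    sprintf(
      "  %d. %s  (threshold failures: %d, mean duplicate rate: %s%%, effort to 90%% at 30X: %s)",
      comparison$ranking$rank,
      comparison$ranking$kit,
      comparison$ranking$n_fail,
      fmt_num(comparison$ranking$mean_duplicate_pct),
      ifelse(
        is.na(comparison$ranking$effort_90_at_30x),
        "not reached",
        format(comparison$ranking$effort_90_at_30x, trim = TRUE)
      )
    ),
    "",
    paste0(
      "Design partition: ",
      if (is.null(design_partition)) "not evaluated" else "see report.json"
    ),
    paste0(
      "Panel coverage: ",
      if (is.null(panel_results)) "not evaluated" else "see report.json"
    )
  )
  writeLines(lines, summary_path)
  invisible(c(json_path, metrics_path, verdicts_path, summary_path))
}

#' Example kit-comparison measurements
#'
#' A small built-in dataset of sample sequencing metrics from a benchmark of
#' three commercial whole-exome capture kits (nine blood-DNA libraries per
#' kit on a NextSeq 500, 2 x 150 bp), tabulated at four downsampled
#' sequencing efforts. Useful for demonstrating [compare_kits()],
#' [minimal_effort()] and [render_report()] without alignments at hand.
#'
#' @return A tibble with columns `kit`, `effort` (million reads),
#'   `median_insert`, `on_target_pct`, `mean_cov_dup`, `duplicate_pct`,
#'   `mean_cov_nodup`, `target_at_30x_pct`, `fold80`, `evenness`, `tstv`.
#' @export
example_kit_metrics <- function() {
  tibble::tribble(
    ~kit, ~effort, ~median_insert, ~on_target_pct, ~mean_cov_dup,
    ~duplicate_pct, ~mean_cov_nodup, ~target_at_30x_pct, ~fold80, ~evenness,
    ~tstv,
    "Medexome", 40, 206, 74.26, 61.3, 12.09, 42.1, 66, 1.9, 77.25, 2.8,
    "SSV7", 40, 215, 72.04, 66.1, 5.16, 45.5, 73, 1.8, 79.46, 2.7,
    "CREV2", 40, 204, 72.14, 48.8, 4.26, 33.3, 51, 2.0, 77.62, 2.5,
    "Medexome", 60, 206, 74.26, 86.4, 17.25, 59.5, 83, 1.9, 77.03, 2.7,
    "SSV7", 60, 218, 72.04, 96.32, 7.54, 66.3, 89, 1.7, 79.52, 2.6,
    "CREV2", 60, 205, 72.14, 71.4, 6.24, 48.8, 75, 1.9, 77.99, 2.4,
    "Medexome", 80, 207, 74.26, 108.4, 21.93, 74.7, 90, 1.9, 77.22, 2.7,
    "SSV7", 80, 218, 72.04, 124.9, 9.79, 86.1, 94, 1.8, 80.01, 2.6,
    "CREV2", 80, 205, 72.14, 93.0, 8.15, 63.6, 86, 1.8, 78.63, 2.4,
    "Medexome", 100, 209, 74.26, 127.8, 26.19, 88.2, 92, 1.8, 77.46, 2.7,
    "SSV7", 100, 218, 72.04, 151.9, 11.94, 104.9, 96, 1.7, 80.22, 2.6,
    "CREV2", 100, 206, 72.14, 113.6, 9.96, 77.7, 90, 1.8, 79.31, 2.4
  )
}
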