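#' Call differentially methylated regions between two groups
#'
#' Runs [test_windows()] over the genome and merges significant windows of
#' the same direction that overlap or abut into DMRs. With the default
#' `"union"` merge policy a DMR spans the union of its windows; with
#' `"cpg_span"` it is trimmed to the first/last covered CpG. A window's
#' direction is `hyper` when the test group's mean methylation exceeds the
#' reference group's (`mean_diff > 0`) and `hypo` otherwise; a window with
#' `mean_diff == 0` can never be significant (it fails the effect-size
#' filter), so merged directions are always uniform.
#'
#' @inheritParams test_windows
#' @param comparison Name recorded on every DMR (default
#'   `"<test>_vs_<ref>"`).
#' @return An object of class `dmr_calls`: a list with
#'   * `dmrs`: tibble of merged regions (`chrom`, `start`, `end` 0-based
#'     half-open, `direction`, `best_p`, `max_abs_mean_diff`,
#'     `n_windows_merged`, `n_cpgs`, `comparison`),
#'   * `windows`: the full window table from [test_windows()],
#'   * `filter_counts`: tally of window fates (`no_cpgs`, `low_coverage`,
#'     `below_min_obs`, `effect_too_small`, `not_significant`,
#'     `significant`),
#'   * `comparison`, `test_group`, `ref_group`, `config`.
#'   Use [tidy()] for the DMR tibble, [glance()] for a one-row summary, and
#'   [autoplot()] for a window-level overview plot.
#' @export
call_dmrs <- function(calls, test_group, ref_group, chrom_lengths = NULL,
                      config = dmr_config(),
                      comparison = paste0(test_group, "_vs_", ref_group)) {
  windows <- test_windows(calls, test_group, ref_group, chrom_lengths, config)

  sig <- filter(windows, .data$significant)
  if (nrow(sig) == 0) {
    dmrs <- tibble(
      chrom = character(), start = integer(), end = integer(),
      direction = character(), best_p = numeric(),
      max_abs_mean_diff = numeric(), n_windows_merged = integer(),
      n_cpgs = integer(), comparison = character()
    )
  } else {
    dmrs <- sig |>
      group_by(.data$chrom, .data$direction) |>
      arrange(.data$start, .by_group = TRUE) |>
      mutate(
        prev_end = lag(cummax(.data$end), default = min(.data$start) - 1L),
        grp = cumsum(.data$start > .data$prev_end)
      ) |>
      group_by(.data$chrom, .data$direction, .data$grp) |>
      summarise(
        start = min(.data$start),
        end = max(.data$end),
        best_p = min(.data$p_used),
        max_abs_mean_diff = max(abs(.data$mean_diff)),
        n_windows_merged = dplyr::n(),
        .groups = "drop"
      ) |>
      select(-"grp")

    sites <- calls |>
      filter(
        .data$group %in% c(test_group, ref_group),
        .data$context == "CG", .data$total_reads > 0
      ) |>
      distinct(.data$chrom, .data$pos) |>
      mutate(pos0 = .data$pos - 1L)
    per_dmr <- map(seq_len(nrow(dmrs)), function(i) {
      p <- sites$pos0[sites$chrom == dmrs$chrom[i] &
        sites$pos0 >= dmrs$start[i] & sites$pos0 < dmrs$end[i]]
      p
    })
    if (config$merge_policy == "cpg_span") {
      dmrs$start <- map_int(per_dmr, ~ as.integer(min(.x)))
      dmrs$end <- map_int(per_dmr, ~ as.integer(max(.x) + 2L))
    }
    dmrs <- dmrs |>
      mutate(
        n_cpgs = map_int(per_dmr, length),
        comparison = comparison
      ) |>
      arrange(.data$chrom, .data$start) |>
      select(
        "chrom", "start", "end", "direction", "best_p",
        "max_abs_mean_diff", "n_windows_merged", "n_cpgs", "comparison"
      )
  }

  filter_counts <- windows |>
    mutate(fate = case_when(
      .data$status != "tested" ~ .data$status,
      .data$significant ~ "significant",
      !is.na(.data$p_used) & .data$p_used < config$alpha ~ "effect_too_small",
      TRUE ~ "not_significant"
    )) |>
    count(.data$fate, name = "n")

  structure(
    list(
      dmrs = dmrs, windows = windows, filter_counts = filter_counts,
      comparison = comparison, test_group = test_group,
      ref_group = ref_group, config = config
    ),
    class = "dmr_calls"
  )
}

#' @export
print.dmr_calls <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<dmr_calls> %s: %d DMRs (%d hyper / %d hypo) from %d significant of %d tested windows\n",
    x$comparison, g$n_dmrs, g$n_hyper, g$n_hypo,
    g$n_significant_windows, g$n_tested
  ))
  invisible(x)
}

#' Tidy the merged DMRs of a comparison
#'
#' @param x A `dmr_calls` object.
#' @param ... Unused.
#' @return The DMR tibble (0-based half-open coordinates; see
#'   [dmr_table()] for the 1-based inclusive human-facing form).
#' @method tidy dmr_calls
#' @export
tidy.dmr_calls <- function(x, ...) x$dmrs

#' One-row summary of a DMR comparison
#'
#' @inheritParams tidy.dmr_calls
#' @method glance dmr_calls
#' @export
glance.dmr_calls <- function(x, ...) {
  tibble(
    comparison = x$comparison,
    n_windows = nrow(x$windows),
    n_tested = sum(x$windows$status == "tested"),
    n_significant_windows = sum(x$windows$significant),
    n_dmrs = nrow(x$dmrs),
    n_hyper = sum(x$dmrs$direction == "hyper"),
    n_hypo = sum(x$dmrs$direction == "hypo")
  )
}

#' Hyper/hypo/total DMR counts per comparison
#'
#' Emits the classic significant-DMR summary table: one row per comparison
#' with hypermethylated, hypomethylated and total counts.
#'
#' @param ... One or more `dmr_calls` objects (or a single list of them).
#' @return Tibble with `comparison`, `hypermethylated`, `hypomethylated`,
#'   `total`.
#' @export
dmr_summary <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && !inherits(xs[[1]], "dmr_calls")) xs <- xs[[1]]
  stopifnot(all(vapply(xs, inherits, TRUE, "dmr_calls")))
  map(xs, function(x) {
    tibble(
      comparison = x$comparison,
      hypermethylated = sum(x$dmrs$direction == "hyper"),
      hypomethylated = sum(x$dmrs$direction == "hypo"),
      total = nrow(x$dmrs)
    )
  }) |>
    list_rbind()
}

#' Human-facing DMR table with 1-based inclusive coordinates
#'
#' @param dmrs DMR tibble (from [tidy()]) or a `dmr_calls` object.
#' @export
dmr_table <- function(dmrs) {
  if (inherits(dmrs, "dmr_calls")) dmrs <- dmrs$dmrs
  dmrs |> mutate(start = .data$start + 1L)
}

#' Write DMRs as BED6+ (name = comparison, score = -10 log10 p)
#'
#' @param dmrs DMR tibble or `dmr_calls` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  if (inherits(dmrs, "dmr_calls")) dmrs <- dmrs$dmrs
  out <- dmrs |>
    transmute(
      .data$chrom, .data$start, .data$end,
      name = .data$comparison,
      score = round(pmin(1000, -10 * log10(pmax(.data$best_p, 1e-100)))),
      strand = ".",
      mean_diff = round(.data$max_abs_mean_diff, 4),
      direction = .data$direction,
      n_cpgs = .data$n_cpgs
    )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Window-level overview plot of a comparison
#'
#' Plots each tested window's group mean methylation difference along the
#' chromosome, highlighting significant windows and shading merged DMRs.
#'
#' @param object A `dmr_calls` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dmr_calls
#' @export
autoplot.dmr_calls <- function(object, ...) {
  win <- filter(object$windows, .data$status == "tested")
  p <- ggplot2::ggplot(
    win,
    ggplot2::aes(x = (.data$start + .data$end) / 2, y = .data$mean_diff)
  ) +
    ggplot2::geom_point(
      ggplot2::aes(colour = .data$significant),
      size = 0.6, alpha = 0.6
    ) +
    ggplot2::geom_hline(
      yintercept = c(-1, 1) * object$config$min_mean_diff,
      linetype = "dashed", linewidth = 0.3
    ) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey60", `TRUE` = "firebrick")
    ) +
    ggplot2::labs(
      x = "position (bp)", y = "methylation difference (test - ref)",
      title = object$comparison
    ) +
    ggplot2::theme_minimal()
  if (nrow(object$dmrs) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$dmrs,
      ggplot2::aes(
        xmin = .data$start, xmax = .data$end,
        ymin = -Inf, ymax = Inf
      ),
      inherit.aes = FALSE, alpha = 0.15, fill = "steelblue"
    )
  }
  p
}
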