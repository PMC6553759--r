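#' Configuration of the sliding-window DMR caller
#'
#' Defaults follow the standard RRBS sliding-window design: 100 bp windows
#' advanced in 50 bp steps, a two-sided Mann-Whitney test on the pooled
#' per-(CpG, replicate) methylation ratios at `alpha = 0.01`, and the two
#' reliability filters — at least 10 reads per group over the window's
#' CpGs and an absolute group mean difference of at least 0.2.
#'
#' @param window_bp Window width in bp.
#' @param step_bp Step between window starts, `0 < step_bp <= window_bp`.
#' @param min_window_reads Minimum summed reads per group over the window.
#' @param min_mean_diff Minimum absolute difference of group mean
#'   methylation for a window to be called, in `(0, 1)`.
#' @param alpha Significance threshold on the (raw or BH-adjusted) p-value.
#' @param min_obs_per_group Minimum number of (CpG, replicate) observations
#'   per group; a U test on fewer observations cannot approach `alpha`.
#' @param exact_test_max_n Pooled sample size up to which the exact
#'   Mann-Whitney permutation distribution is used.
#' @param merge_policy How overlapping/abutting significant windows of one
#'   direction are merged: `"union"` keeps the merged span, `"cpg_span"`
#'   trims it to the first/last covered CpG.
#' @param fdr `"none"` (raw p-values, the default) or `"bh"` for
#'   Benjamini-Hochberg adjustment across tested windows (an extension
#'   beyond the raw-p design).
#' @return A list of class `dmr_config`.
#' @export
dmr_config <- function(window_bp = 100L, step_bp = 50L,
                       min_window_reads = 10L, min_mean_diff = 0.2,
                       alpha = 0.01, min_obs_per_group = 3L,
                       exact_test_max_n = 20L,
                       merge_policy = c("union", "cpg_span"),
                       fdr = c("none", "bh")) {
  assert_scalar_number(window_bp, "window_bp", lower = 0, strict = TRUE)
  assert_scalar_number(step_bp, "step_bp", lower = 0, strict = TRUE)
  if (step_bp > window_bp) stop_config("`step_bp` must not exceed `window_bp`")
  assert_scalar_number(min_window_reads, "min_window_reads", lower = 0)
  if (min_mean_diff <= 0 || min_mean_diff >= 1) {
    stop_config("`min_mean_diff` must lie in (0, 1)")
  }
  if (alpha <= 0 || alpha >= 1) stop_config("`alpha` must lie in (0, 1)")
  assert_scalar_number(min_obs_per_group, "min_obs_per_group", lower = 1)
  assert_scalar_number(exact_test_max_n, "exact_test_max_n", lower = 2)
  structure(
    list(
      window_bp = as.integer(window_bp), step_bp = as.integer(step_bp),
      min_window_reads = as.integer(min_window_reads),
      min_mean_diff = min_mean_diff, alpha = alpha,
      min_obs_per_group = as.integer(min_obs_per_group),
      exact_test_max_n = as.integer(exact_test_max_n),
      merge_policy = match.arg(merge_policy),
      fdr = match.arg(fdr)
    ),
    class = "dmr_config"
  )
}

#' Enumerate sliding windows along a chromosome
#'
#' Windows are `[k * step, k * step + window)` for `k = 0, 1, ...` while the
#' start lies inside the chromosome. A final partial window (clipped at the
#' chromosome end) is kept only when it is longer than half a window.
#'
#' @param chrom_length Chromosome length in bp (`>= 0`).
#' @param window_bp,step_bp Window width and step.
#' @return Tibble with `start`, `end` (0-based half-open).
#' @export
enumerate_windows <- function(chrom_length, window_bp = 100L, step_bp = 50L) {
  assert_scalar_number(chrom_length, "chrom_length", lower = 0)
  L <- as.integer(chrom_length)
  if (L <= 0) return(tibble(start = integer(), end = integer()))
  start <- seq.int(0L, L - 1L, by = as.integer(step_bp))
  end <- pmin(start + as.integer(window_bp), L)
  len <- end - start
  keep <- len == window_bp | len > window_bp / 2
  tibble(start = start[keep], end = end[keep])
}

#' Test every window of a two-group comparison
#'
#' Builds, per window, the pooled observation vectors — one methylation
#' ratio per (covered CpG, replicate) pair in each group — and runs the
#' Mann-Whitney comparison on windows passing the read and observation
#' filters. Windows failing a filter are retained with a machine-readable
#' `status` (`no_cpgs`, `low_coverage`, `below_min_obs`); tested windows
#' carry `u_stat`, `p_value` and the significance call
#' `(p < alpha) & (|mean_diff| >= min_mean_diff)`.
#'
#' @param calls Strand-combined CG-context call tibble covering both groups
#'   (see [combine_strands()]).
#' @param test_group,ref_group Group labels; `mean_diff` is test minus ref.
#' @param chrom_lengths Named vector of chromosome lengths; inferred from
#'   the largest covered position per chromosome when `NULL`.
#' @param config A [dmr_config()].
#' @return Tibble with one row per enumerated window: `chrom`, `start`,
#'   `end`, `n_cpgs`, `n_obs_test`, `n_obs_ref`, `reads_test`, `reads_ref`,
#'   `mean_diff`, `u_stat`, `p_value`, `method`, `status`, `significant`,
#'   `direction`.
#' @export
test_windows <- function(calls, test_group, ref_group, chrom_lengths = NULL,
                         config = dmr_config()) {
  assert_calls(calls)
  stopifnot(inherits(config, "dmr_config"))
  calls <- filter(
    calls,
    .data$group %in% c(test_group, ref_group),
    .data$context == "CG", .data$total_reads > 0
  )
  for (g in c(test_group, ref_group)) {
    n_samp <- length(unique(calls$sample_id[calls$group == g]))
    if (n_samp < 2) {
      stop_data(sprintf("group '%s' needs >= 2 samples with calls", g))
    }
  }
  shared <- intersect(
    unique(calls$chrom[calls$group == test_group]),
    unique(calls$chrom[calls$group == ref_group])
  )
  if (length(shared) == 0) {
    stop_data("the two groups share no chromosome with methylation calls")
  }
  if (is.null(chrom_lengths)) {
    chrom_lengths <- calls |>
      group_by(.data$chrom) |>
      summarise(L = max(.data$pos) + 1L) |>
      (\(d) setNames(d$L, d$chrom))()
  }

  w <- config$window_bp
  st <- config$step_bp
  wins <- purrr::imap(
    as.list(chrom_lengths),
    ~ enumerate_windows(.x, w, st) |> mutate(chrom = .y, .before = 1)
  ) |>
    list_rbind()

  m <- ceiling(w / st)
  obs <- calls |>
    mutate(pos0 = .data$pos - 1L, ratio = .data$meth_reads / .data$total_reads)
  obs <- obs[rep(seq_len(nrow(obs)), each = m), ] |>
    mutate(offset = rep(seq_len(m) - 1L, length.out = dplyr::n())) |>
    mutate(start = (.data$pos0 %/% st - .data$offset) * st) |>
    filter(.data$start >= 0, .data$pos0 < .data$start + w) |>
    semi_join(wins, by = c("chrom", "start"))

  stats <- obs |>
    group_by(.data$chrom, .data$start) |>
    summarise(
      n_cpgs = dplyr::n_distinct(.data$pos0),
      reads_test = sum(.data$total_reads[.data$group == test_group]),
      reads_ref = sum(.data$total_reads[.data$group == ref_group]),
      n_obs_test = sum(.data$group == test_group),
      n_obs_ref = sum(.data$group == ref_group),
      mean_diff = mean(.data$ratio[.data$group == test_group]) -
        mean(.data$ratio[.data$group == ref_group]),
      obs_test = list(.data$ratio[.data$group == test_group]),
      obs_ref = list(.data$ratio[.data$group == ref_group]),
      .groups = "drop"
    )

  res <- wins |>
    left_join(stats, by = c("chrom", "start")) |>
    mutate(
      n_cpgs = tidyr::replace_na(.data$n_cpgs, 0L),
      reads_test = tidyr::replace_na(.data$reads_test, 0L),
      reads_ref = tidyr::replace_na(.data$reads_ref, 0L),
      n_obs_test = tidyr::replace_na(.data$n_obs_test, 0L),
      n_obs_ref = tidyr::replace_na(.data$n_obs_ref, 0L),
      status = case_when(
        n_cpgs == 0 ~ "no_cpgs",
        reads_test < config$min_window_reads |
          reads_ref < config$min_window_reads ~ "low_coverage",
        n_obs_test < config$min_obs_per_group |
          n_obs_ref < config$min_obs_per_group ~ "below_min_obs",
        TRUE ~ "tested"
      )
    )

  tested <- res$status == "tested"
  res$u_stat <- NA_real_
  res$p_value <- NA_real_
  res$method <- NA_character_
  if (any(tested)) {
    mw <- purrr::map2(
      res$obs_test[tested], res$obs_ref[tested],
      ~ mw_test(.x, .y, exact_max_n = config$exact_test_max_n)
    )
    res$u_stat[tested] <- map_dbl(mw, "u_stat")
    res$p_value[tested] <- map_dbl(mw, "p_value")
    res$method[tested] <- purrr::map_chr(mw, "method")
  }
  p_use <- res$p_value
  if (config$fdr == "bh") {
    p_use[tested] <- p.adjust(res$p_value[tested], method = "BH")
  }
  res |>
    mutate(
      p_used = p_use,
      significant = tested & !is.na(p_use) & p_use < config$alpha &
        !is.na(.data$mean_diff) & abs(.data$mean_diff) >= config$min_mean_diff,
      direction = case_when(
        !.data$significant ~ NA_character_,
        .data$mean_diff > 0 ~ "hyper",
        TRUE ~ "hypo"
      )
    ) |>
    select(
      "chrom", "start", "end", "n_cpgs", "n_obs_test", "n_obs_ref",
      "reads_test", "reads_ref", "mean_diff", "u_stat", "p_value", "p_used",
      "method", "status", "significant", "direction"
    )
}
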