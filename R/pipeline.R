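#' Configuration of the end-to-end synthetic RRBS analysis
#'
#' Bundles the stage configurations and the list of group comparisons. The
#' default comparisons mirror the steatosis study design: treatment II vs
#' control I (induction), then each extract-treated group III and IV against
#' II.
#'
#' @param sim A [sim_config()].
#' @param digest A [digest_config()].
#' @param dmr A [dmr_config()].
#' @param comparisons List of length-2 character vectors
#'   `c(test_group, ref_group)`.
#' @param site_min_reads Per-site read filter applied before window testing
#'   (default 10; independent of the per-window read filter).
#' @param out_dir Optional output directory; when given, every stage writes
#'   its files there and a hash manifest is produced.
#' @param seed Optional seed overriding `sim$seed`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), digest = digest_config(),
                            dmr = dmr_config(),
                            comparisons = list(
                              c("II", "I"), c("III", "II"), c("IV", "II")
                            ),
                            site_min_reads = 10L,
                            out_dir = NULL, seed = NULL) {
  stopifnot(
    inherits(sim, "sim_config"), inherits(digest, "digest_config"),
    inherits(dmr, "dmr_config")
  )
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  used <- unique(unlist(comparisons))
  missing <- setdiff(used, sim$groups)
  if (length(missing) > 0) {
    stop_config(sprintf(
      "comparisons reference groups absent from the simulation: %s",
      paste(missing, collapse = ", ")
    ))
  }
  if (any(lengths(comparisons) != 2)) {
    stop_config("each comparison must be c(test_group, ref_group)")
  }
  structure(
    list(
      sim = sim, digest = digest, dmr = dmr, comparisons = comparisons,
      site_min_reads = as.integer(site_min_reads), out_dir = out_dir
    ),
    class = "pipeline_config"
  )
}

#' Run the full synthetic RRBS DMR pipeline
#'
#' Executes simulate -> digest/size-select -> per-comparison DMR calling ->
#' reversal analysis -> annotation -> (optional) file output, and collects
#' everything in one result object. Identical configurations (including the
#' seed) give identical results and, when `out_dir` is set, identical file
#' hashes in the manifest.
#'
#' @param cfg A [pipeline_config()].
#' @return Object of class `pipeline_run`: list with `sim` (genome),
#'   `methylomes`, `capture`, `dmr_calls` (named list of [call_dmrs()]
#'   results), `summary` (hyper/hypo/total per comparison), `reversal`
#'   (a `reversal_result`, when at least two comparisons share the design),
#'   `heatmap`, `annotated`, `distributions`, `recovery`, `manifest`,
#'   `config`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  sim <- simulate_genome(cfg$sim)
  meth <- simulate_methylomes(cfg$sim, sim)
  calls <- filter_coverage(meth$calls, cfg$site_min_reads)

  frags <- digest_genome(sim, cfg$digest)
  selected_frags <- size_select(frags, cfg$digest)
  capture <- capture_report(selected_frags, sim)

  dmr_calls <- list()
  for (cmp in cfg$comparisons) {
    res <- call_dmrs(
      calls, cmp[1], cmp[2],
      chrom_lengths = sim$chrom_lengths, config = cfg$dmr
    )
    dmr_calls[[res$comparison]] <- res
  }
  summary_tbl <- dmr_summary(dmr_calls)

  reversal <- NULL
  heatmap <- NULL
  if (length(dmr_calls) >= 2) {
    treatments <- dmr_calls[-1]
    reversal <- venn_counts(
      dmr_calls[[1]],
      treatments[[1]],
      if (length(treatments) >= 2) treatments[[2]] else NULL
    )
    regions <- distinct(bind_rows(reversal$categories))
    if (nrow(regions) > 0) {
      heatmap <- build_heatmap_matrix(regions, calls)
    }
  }

  tracks <- build_tracks(sim$features, sim$islands)
  annotated <- map(dmr_calls, ~ annotate_dmrs(.x, tracks)) |> list_rbind()
  distributions <- if (nrow(annotated) > 0) {
    annotated |>
      group_by(.data$comparison) |>
      group_modify(~ distribution_report(.x)) |>
      ungroup()
  } else {
    tibble(comparison = character(), category = character(),
           n = integer(), pct = numeric())
  }

  recovery <- NULL
  if (!is.null(meth$truth$planted)) {
    recovery <- map(dmr_calls, function(x) {
      recovery_metrics(x$dmrs, meth$truth$planted, x$test_group, x$ref_group) |>
        mutate(comparison = x$comparison, .before = 1)
    }) |>
      list_rbind()
  }

  run <- structure(
    list(
      sim = sim, methylomes = meth, capture = capture,
      fragments = selected_frags, dmr_calls = dmr_calls,
      summary = summary_tbl, reversal = reversal, heatmap = heatmap,
      annotated = annotated, distributions = distributions,
      recovery = recovery, manifest = NULL, config = cfg
    ),
    class = "pipeline_run"
  )
  if (!is.null(cfg$out_dir)) run$manifest <- write_pipeline_outputs(run, cfg$out_dir)
  run
}

#' Sensitivity, precision and direction accuracy against planted truth
#'
#' A planted region is relevant to a comparison when its group shifts imply
#' a nonzero test-minus-reference difference; it counts as detected when at
#' least one called DMR overlaps it, and as correctly directed when its
#' best-p overlapping DMR matches the implied sign.
#'
#' @param dmrs Called DMR tibble.
#' @param planted Planted-region tibble (`delta_<group>` columns).
#' @param test_group,ref_group The comparison's groups.
#' @return One-row tibble: `n_planted`, `n_detected`, `sensitivity`,
#'   `direction_accuracy`, `precision`.
#' @export
recovery_metrics <- function(dmrs, planted, test_group, ref_group) {
  delta_of <- function(g) {
    col <- paste0("delta_", g)
    if (col %in% names(planted)) planted[[col]] else rep(0, nrow(planted))
  }
  eff <- delta_of(test_group) - delta_of(ref_group)
  rel <- planted[eff != 0, ]
  eff <- eff[eff != 0]
  if (nrow(rel) == 0) {
    return(tibble(
      n_planted = 0L, n_detected = 0L, sensitivity = NA_real_,
      direction_accuracy = NA_real_, precision = NA_real_
    ))
  }
  expected <- ifelse(eff > 0, "hyper", "hypo")
  detected <- logical(nrow(rel))
  dir_ok <- logical(nrow(rel))
  if (nrow(dmrs) > 0) {
    hits <- GenomicRanges::findOverlaps(as_granges0(rel), as_granges0(dmrs))
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    detected[unique(q)] <- TRUE
    for (i in unique(q)) {
      ss <- s[q == i]
      best <- ss[which.min(dmrs$best_p[ss])]
      dir_ok[i] <- dmrs$direction[best] == expected[i]
    }
    dmr_hit <- rep(FALSE, nrow(dmrs))
    dmr_hit[unique(s)] <- TRUE
  } else {
    dmr_hit <- logical(0)
  }
  tibble(
    n_planted = nrow(rel),
    n_detected = sum(detected),
    sensitivity = mean(detected),
    direction_accuracy = if (any(detected)) {
      sum(dir_ok) / sum(detected)
    } else {
      NA_real_
    },
    precision = if (nrow(dmrs) > 0) mean(dmr_hit) else NA_real_
  )
}

# Write every stage output under `dir` and return a (file, md5) manifest.
write_pipeline_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  add <- function(p) paths <<- c(paths, p)

  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(run$sim$genome, fa)
  add(fa)
  write_bed6 <- function(tbl, p, name = ".") {
    out <- tibble(
      chrom = tbl$chrom, start = tbl$start, end = tbl$end,
      name = name, score = 0L,
      strand = if ("strand" %in% names(tbl)) tbl$strand else "."
    )
    readr::write_tsv(out, p, col_names = FALSE)
    add(p)
  }
  write_bed6(run$sim$islands, file.path(dir, "islands.bed"), "CpG_island")
  write_bed6(
    run$sim$features, file.path(dir, "features.bed"),
    name = paste0(run$sim$features$category, ":", run$sim$features$gene_id)
  )
  if (!is.null(run$methylomes$truth$planted)) {
    p <- file.path(dir, "truth_planted.bed")
    write_truth_bed(run$methylomes$truth$planted, p)
    add(p)
  }
  for (sid in unique(run$methylomes$calls$sample_id)) {
    p <- file.path(dir, paste0(sid, ".CGmap"))
    write_cgmap(filter(run$methylomes$calls, .data$sample_id == sid), p)
    add(p)
  }
  p <- file.path(dir, "fragments.tsv")
  readr::write_tsv(run$fragments, p)
  add(p)
  for (nm in names(run$dmr_calls)) {
    p <- file.path(dir, paste0("dmrs_", nm, ".bed"))
    write_dmr_bed(run$dmr_calls[[nm]], p)
    add(p)
  }
  p <- file.path(dir, "dmr_summary.tsv")
  readr::write_tsv(run$summary, p)
  add(p)
  if (!is.null(run$reversal)) {
    p <- file.path(dir, "reversal_counts.tsv")
    readr::write_tsv(run$reversal$counts, p)
    add(p)
  }
  if (!is.null(run$heatmap)) {
    p <- file.path(dir, "heatmap_matrix.tsv")
    readr::write_tsv(as_tibble(run$heatmap$matrix, rownames = "dmr"), p)
    add(p)
  }
  if (nrow(run$annotated) > 0) {
    p <- file.path(dir, "annotated_dmrs.tsv")
    readr::write_tsv(run$annotated, p)
    add(p)
  }
  tibble(file = basename(paths), md5 = unname(tools::md5sum(paths)))
}

#' Summary report of a pipeline run
#'
#' Re-derives the headline tables from the run object: hyper/hypo/total DMR
#' counts per comparison, category distributions, reversal tallies, and —
#' when planted truth is available — recovery metrics. If the run wrote
#' files, their hashes are re-verified against the manifest first and a
#' mismatch raises an integrity error.
#'
#' @param run A `pipeline_run`.
#' @param out_dir Directory holding the run's files (defaults to the
#'   configured one).
#' @return List of tibbles: `dmr_summary`, `distributions`, `reversal`,
#'   `recovery`.
#' @export
pipeline_report <- function(run, out_dir = run$config$out_dir) {
  stopifnot(inherits(run, "pipeline_run"))
  if (!is.null(run$manifest) && !is.null(out_dir)) {
    now <- unname(tools::md5sum(file.path(out_dir, run$manifest$file)))
    if (!identical(now, run$manifest$md5)) {
      stop_data("pipeline output files do not match the run manifest")
    }
  }
  list(
    dmr_summary = run$summary,
    distributions = run$distributions,
    reversal = if (!is.null(run$reversal)) run$reversal$counts else NULL,
    recovery = run$recovery
  )
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  print(x$summary)
  if (!is.null(x$reversal)) {
    cat(sprintf(
      "reversed regions: %d (per-treatment tally), %d unique\n",
      x$reversal$reversed_total, x$reversal$unique_total
    ))
  }
  invisible(x)
}
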