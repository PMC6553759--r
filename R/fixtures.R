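# Packaged worked-example tables: transcriptions of published RRBS DMR
# summaries used as fixed ground truth by the reversal and annotation
# examples. Each file is integrity-checked (md5 + record count) on load.

fixture_registry <- list(
  table2 = list(
    file = "table2_significant_dmrs.tsv",
    md5 = "2302ccf4a7855c9b4e5b4dafbb603968",
    n = 3L
  ),
  table4 = list(
    file = "table4_annotated_dmrs.tsv",
    md5 = "9e5da645516982d2b36138968e6ce7fa",
    n = 77L
  ),
  venn_fig2 = list(
    file = "fig2_venn_counts.tsv",
    md5 = "581dd59c4237da660863c3c2d1220539",
    n = 4L
  )
)

#' Load a packaged worked-example table
#'
#' Three fixed tables ship with the package: `table2` — significant-DMR
#' counts (hyper/hypo/total) of the three treatment comparisons; `table4` —
#' 77 annotated reversed DMRs with per-comparison direction, genomic region
#' label, CpG count and nearest gene (one record per coordinate row; the
#' genes NKX2-2 and STEAP3 contribute two records each); `venn_fig2` — the
#' four reversal-category counts. Coordinates in `table4` are 1-based
#' inclusive, as printed. Files are verified against a packaged checksum
#' and record count before use.
#'
#' @param name One of `"table2"`, `"table4"`, `"venn_fig2"`.
#' @param path Override the packaged file location (for testing).
#' @return A tibble.
#' @export
load_fixture_table <- function(name = c("table2", "table4", "venn_fig2"),
                               path = NULL) {
  name <- match.arg(name)
  reg <- fixture_registry[[name]]
  path <- path %||% system.file("extdata", reg$file, package = "rrbsdmr")
  if (!nzchar(path) || !file.exists(path)) {
    stop_data(sprintf("packaged fixture '%s' not found", reg$file))
  }
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, reg$md5)) {
    stop_data(sprintf(
      "fixture '%s' failed its integrity check (md5 %s, expected %s)",
      reg$file, md5, reg$md5
    ))
  }
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tbl) != reg$n) {
    stop_data(sprintf(
      "fixture '%s' has %d records, expected %d", reg$file, nrow(tbl), reg$n
    ))
  }
  tbl
}

#' Count summaries of the annotated reversed-DMR fixture
#'
#' Tallies the `table4` fixture by induction direction, by
#' treatment-involvement (reversed by exactly one vs both treatments), and
#' by printed genomic region label.
#'
#' @param table4 The tibble returned by `load_fixture_table("table4")`.
#' @return List with `totals` (one-row tibble: `n_records`, `n_oa_hyper`,
#'   `n_oa_hypo`, `n_both_extracts`, `n_single_extract`) and `by_region`
#'   (tibble of region-label counts).
#' @export
fixture_queries <- function(table4) {
  needed <- c("oa_vs_con", "eat_vs_oa", "ecb_vs_oa", "region")
  stopifnot(all(needed %in% names(table4)))
  has_eat <- table4$eat_vs_oa != "-"
  has_ecb <- table4$ecb_vs_oa != "-"
  totals <- tibble(
    n_records = nrow(table4),
    n_oa_hyper = sum(table4$oa_vs_con == "Hypermethylation"),
    n_oa_hypo = sum(table4$oa_vs_con == "Hypomethylation"),
    n_both_extracts = sum(has_eat & has_ecb),
    n_single_extract = sum(xor(has_eat, has_ecb))
  )
  list(
    totals = totals,
    by_region = count(table4, .data$region, name = "n")
  )
}
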