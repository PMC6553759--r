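#' Pair DMRs whose methylation change is reversed between comparisons
#'
#' Finds pairs `(a, b)` of regions — one from each comparison — that
#' overlap by at least `min_overlap_bp` and have opposite directions
#' (hyper vs hypo). A region may appear in several pairs; the output is
#' deterministically ordered by the `a` interval, then the `b` interval.
#'
#' @param dmrs_a,dmrs_b DMR tibbles (as produced by [call_dmrs()]; columns
#'   `chrom`, `start`, `end`, `direction` required).
#' @param min_overlap_bp Minimum genomic overlap in bp (`>= 1`).
#' @return Tibble of pairs with `a_`-/`b_`-prefixed interval columns and
#'   the overlap width `overlap_bp`.
#' @export
intersect_reversed <- function(dmrs_a, dmrs_b, min_overlap_bp = 1L) {
  assert_scalar_number(min_overlap_bp, "min_overlap_bp", lower = 1)
  if (nrow(dmrs_a) == 0 || nrow(dmrs_b) == 0) {
    return(tibble(
      a_chrom = character(), a_start = integer(), a_end = integer(),
      a_direction = character(), b_chrom = character(),
      b_start = integer(), b_end = integer(), b_direction = character(),
      overlap_bp = integer()
    ))
  }
  hits <- GenomicRanges::findOverlaps(
    as_granges0(dmrs_a), as_granges0(dmrs_b),
    minoverlap = as.integer(min_overlap_bp)
  )
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  keep <- dmrs_a$direction[q] != dmrs_b$direction[s]
  q <- q[keep]
  s <- s[keep]
  tibble(
    a_chrom = dmrs_a$chrom[q], a_start = dmrs_a$start[q],
    a_end = dmrs_a$end[q], a_direction = dmrs_a$direction[q],
    b_chrom = dmrs_b$chrom[s], b_start = dmrs_b$start[s],
    b_end = dmrs_b$end[s], b_direction = dmrs_b$direction[s],
    overlap_bp = pmin(dmrs_a$end[q], dmrs_b$end[s]) -
      pmax(dmrs_a$start[q], dmrs_b$start[s])
  ) |>
    arrange(.data$a_chrom, .data$a_start, .data$a_end, .data$b_start, .data$b_end)
}

#' Venn-style reversal categories across an induction and two treatments
#'
#' Classifies induction-comparison DMRs (e.g. OA vs control) by whether a
#' treatment comparison (e.g. OA+extract vs OA) reverses their direction:
#' four categories — induction-hyper/treatment-hypo and the converse, for
#' each of the two treatments. `reversed_total` counts category memberships
#' (a region reversed by both treatments is tallied once per treatment);
#' `unique_total` counts distinct induction regions once.
#'
#' @param oa_dmrs DMR tibble of the induction comparison.
#' @param eat_dmrs,ecb_dmrs DMR tibbles of the two treatment comparisons
#'   (`ecb_dmrs` may be `NULL`).
#' @param min_overlap_bp Minimum overlap for two regions to be "the same".
#' @return Object of class `reversal_result`: list with `categories`
#'   (named list of tibbles of distinct induction regions), `counts`
#'   (tibble `category`, `n`), `reversed_total`, `unique_total`,
#'   `both_extracts` (tibble of induction regions reversed by both
#'   treatments).
#' @export
venn_counts <- function(oa_dmrs, eat_dmrs, ecb_dmrs = NULL, min_overlap_bp = 1L) {
  if (inherits(oa_dmrs, "dmr_calls")) oa_dmrs <- oa_dmrs$dmrs
  if (inherits(eat_dmrs, "dmr_calls")) eat_dmrs <- eat_dmrs$dmrs
  if (inherits(ecb_dmrs, "dmr_calls")) ecb_dmrs <- ecb_dmrs$dmrs
  if (is.null(ecb_dmrs)) {
    ecb_dmrs <- oa_dmrs[0, ]
  }
  region_cols <- c("chrom", "start", "end", "direction")
  cat_regions <- function(pairs, a_dir) {
    pairs |>
      filter(.data$a_direction == a_dir) |>
      distinct(
        chrom = .data$a_chrom, start = .data$a_start,
        end = .data$a_end, direction = .data$a_direction
      )
  }
  eat_pairs <- intersect_reversed(oa_dmrs, eat_dmrs, min_overlap_bp)
  ecb_pairs <- intersect_reversed(oa_dmrs, ecb_dmrs, min_overlap_bp)
  categories <- list(
    oa_hyper_eat_hypo = cat_regions(eat_pairs, "hyper"),
    oa_hypo_eat_hyper = cat_regions(eat_pairs, "hypo"),
    oa_hyper_ecb_hypo = cat_regions(ecb_pairs, "hyper"),
    oa_hypo_ecb_hyper = cat_regions(ecb_pairs, "hypo")
  )
  eat_regions <- bind_rows(categories[1:2])
  ecb_regions <- bind_rows(categories[3:4])
  both <- inner_join(eat_regions, ecb_regions, by = region_cols)
  counts <- tibble(
    category = names(categories),
    n = map_int(categories, nrow)
  )
  structure(
    list(
      categories = categories,
      counts = counts,
      reversed_total = sum(counts$n),
      unique_total = nrow(distinct(bind_rows(eat_regions, ecb_regions))),
      both_extracts = both
    ),
    class = "reversal_result"
  )
}

#' @export
print.reversal_result <- function(x, ...) {
  cat("<reversal_result>\n")
  print(x$counts)
  cat(sprintf(
    "reversed total (per-treatment tally): %d; unique regions: %d; reversed by both: %d\n",
    x$reversed_total, x$unique_total, nrow(x$both_extracts)
  ))
  invisible(x)
}

#' Totals from a table of reversal category counts
#'
#' Sums fixed category counts (e.g. transcribed Venn-diagram figures) into
#' per-treatment and overall tallies without touching interval data.
#'
#' @param venn_tbl Tibble with columns `category` (the four labels used by
#'   [venn_counts()]) and `count`.
#' @return One-row tibble: `eat_total`, `ecb_total`, `reversed_total`.
#' @export
summarise_reversal_counts <- function(venn_tbl) {
  stopifnot(all(c("category", "count") %in% names(venn_tbl)))
  eat <- sum(venn_tbl$count[grepl("eat", venn_tbl$category)])
  ecb <- sum(venn_tbl$count[grepl("ecb", venn_tbl$category)])
  tibble(eat_total = eat, ecb_total = ecb, reversed_total = eat + ecb)
}

#' Methylation-level matrix of selected DMRs across samples
#'
#' Each cell is the coverage-weighted mean methylation ratio (summed
#' methylated reads over summed total reads) of the DMR's CpGs in one
#' sample; cells without coverage are `NA`. Rows (DMRs) and columns
#' (samples) are ordered by average-linkage hierarchical clustering on
#' Euclidean distances, with `NA` cells imputed by the row mean for
#' clustering only (imputed cells are flagged). DMRs with no covered CpG in
#' at least half the samples are dropped with a warning. Leaf orders are
#' made canonical by weight-reordering the dendrograms, so they do not
#' depend on input row/column order (up to exactly tied weights).
#'
#' @param selected DMR tibble (or `dmr_calls`); rows define the matrix rows.
#' @param calls Call tibble covering the samples of interest.
#' @return Object of class `meth_heatmap`: list with `matrix` (rows = DMRs
#'   named `chrom:start-end`, columns = samples), `row_order`, `col_order`,
#'   `imputed` (logical matrix), `dropped` (character vector of dropped
#'   DMR names).
#' @export
build_heatmap_matrix <- function(selected, calls) {
  if (inherits(selected, "dmr_calls")) selected <- selected$dmrs
  stopifnot(nrow(selected) > 0)
  assert_calls(calls)
  calls <- filter(calls, .data$context == "CG", .data$total_reads > 0)
  samples <- sort(unique(calls$sample_id))
  rn <- sprintf("%s:%d-%d", selected$chrom, selected$start, selected$end)
  hits <- GenomicRanges::findOverlaps(
    as_granges0(tibble(
      chrom = calls$chrom, start = calls$pos - 1L, end = calls$pos + 1L
    )),
    as_granges0(selected)
  )
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  cell <- tibble(
    row = rn[s],
    sample_id = calls$sample_id[q],
    meth = calls$meth_reads[q],
    total = calls$total_reads[q]
  ) |>
    group_by(.data$row, .data$sample_id) |>
    summarise(
      value = sum(.data$meth) / sum(.data$total), .groups = "drop"
    )
  mat <- matrix(NA_real_,
    nrow = length(rn), ncol = length(samples),
    dimnames = list(rn, samples)
  )
  mat[cbind(
    match(cell$row, rn), match(cell$sample_id, samples)
  )] <- cell$value

  covered <- rowSums(!is.na(mat))
  drop <- covered < ncol(mat) / 2
  if (any(drop)) {
    warn(sprintf(
      "dropping %d DMR(s) with no covered CpG in >= half the samples: %s",
      sum(drop), paste(rn[drop], collapse = ", ")
    ))
    mat <- mat[!drop, , drop = FALSE]
  }
  if (nrow(mat) == 0) stop_data("no DMR retains coverage in enough samples")

  imputed <- is.na(mat)
  mat_imp <- mat
  if (any(imputed)) {
    rm <- rowMeans(mat, na.rm = TRUE)
    mat_imp[imputed] <- rm[row(mat)[imputed]]
  }
  row_order <- canonical_order(mat_imp)
  col_order <- canonical_order(t(mat_imp))
  structure(
    list(
      matrix = mat, row_order = row_order, col_order = col_order,
      imputed = imputed, dropped = rn[drop]
    ),
    class = "meth_heatmap"
  )
}

# Average-linkage clustering with a canonical (weight-reordered) leaf order,
# invariant to the input ordering of rows when row-mean weights are untied.
canonical_order <- function(m) {
  if (nrow(m) == 1) return(rownames(m))
  hc <- hclust(dist(m), method = "average")
  dend <- stats::reorder(as.dendrogram(hc), rowMeans(m), agglo.FUN = mean)
  rownames(m)[order.dendrogram(dend)]
}

#' @export
print.meth_heatmap <- function(x, ...) {
  cat(sprintf(
    "<meth_heatmap> %d DMRs x %d samples (%d cells imputed for clustering, %d DMRs dropped)\n",
    nrow(x$matrix), ncol(x$matrix), sum(x$imputed), length(x$dropped)
  ))
  invisible(x)
}

#' Heatmap plot of a methylation matrix
#'
#' @param object A `meth_heatmap` from [build_heatmap_matrix()].
#' @param ... Unused.
#' @return A ggplot object (tiles in clustered order).
#' @method autoplot meth_heatmap
#' @export
autoplot.meth_heatmap <- function(object, ...) {
  df <- as_tibble(object$matrix, rownames = "dmr") |>
    tidyr::pivot_longer(-"dmr", names_to = "sample", values_to = "methylation") |>
    mutate(
      dmr = factor(.data$dmr, levels = rev(object$row_order)),
      sample = factor(.data$sample, levels = object$col_order)
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$sample, .data$dmr)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$methylation)) +
    ggplot2::scale_fill_gradient2(
      low = "#2c7bb6", mid = "#ffffbf", high = "#d7191c",
      midpoint = 0.5, limits = c(0, 1), na.value = "grey85"
    ) +
    ggplot2::labs(x = NULL, y = NULL, fill = "methylation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Bar chart of reversal category counts
#'
#' @param x A `reversal_result` or a tibble with `category`/`n` columns.
#' @return A ggplot object.
#' @export
plot_reversal_counts <- function(x) {
  counts <- if (inherits(x, "reversal_result")) x$counts else x
  ggplot2::ggplot(counts, ggplot2::aes(.data$category, .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.3, size = 3) +
    ggplot2::labs(x = NULL, y = "regions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
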