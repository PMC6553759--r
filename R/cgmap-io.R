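#' Read per-cytosine methylation calls in CGmap format
#'
#' CGmap is the per-cytosine output dialect of the BS-seeker2 ecosystem:
#' eight tab-separated columns — chromosome, observed nucleotide (`C` for a
#' plus-strand cytosine, `G` for a minus-strand one), 1-based position,
#' context (`CG`/`CHG`/`CHH`), dinucleotide, methylation level in `[0, 1]`,
#' methylated read count, total read count. When the methylated-count
#' column is missing (`NA`), it is recomputed as `round(level * total)`.
#'
#' @param path Path to a CGmap file (plain text, tab separated).
#' @param sample_id Sample identifier attached to every row; defaults to
#'   the file name without extension.
#' @param group,replicate Optional group label and replicate index.
#' @return Tibble of calls with the package's standard columns
#'   (`sample_id`, `group`, `replicate`, `chrom`, `pos`, `strand`,
#'   `context`, `meth_reads`, `total_reads`).
#' @export
read_cgmap <- function(path, sample_id = NULL, group = NA_character_,
                       replicate = NA_integer_) {
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  has_content <- length(readLines(path, n = 1L, warn = FALSE)) > 0
  raw <- if (has_content) {
    utils::read.delim(
      path,
      header = FALSE, sep = "\t", colClasses = "character",
      blank.lines.skip = TRUE, quote = ""
    )
  } else {
    data.frame()
  }
  if (nrow(raw) == 0) {
    return(tibble(
      sample_id = character(), group = character(), replicate = integer(),
      chrom = character(), pos = integer(), strand = character(),
      context = character(), meth_reads = integer(), total_reads = integer()
    ))
  }
  if (ncol(raw) != 8) {
    stop_data(sprintf("'%s' has %d columns; CGmap needs 8", path, ncol(raw)))
  }
  names(raw) <- c(
    "chrom", "nuc", "pos", "context", "dinuc", "level", "meth", "total"
  )
  nuc <- toupper(raw$nuc)
  bad_nuc <- which(!nuc %in% c("C", "G"))
  if (length(bad_nuc) > 0) {
    stop_data(sprintf(
      "'%s' line %d: nucleotide column must be C or G", path, bad_nuc[1]
    ))
  }
  context <- toupper(raw$context)
  bad_ctx <- which(!context %in% c("CG", "CHG", "CHH"))
  if (length(bad_ctx) > 0) {
    stop_data(sprintf(
      "'%s' line %d: unknown context code '%s'",
      path, bad_ctx[1], raw$context[bad_ctx[1]]
    ))
  }
  pos <- suppressWarnings(as.integer(raw$pos))
  total <- suppressWarnings(as.integer(raw$total))
  level <- suppressWarnings(as.numeric(raw$level))
  meth <- suppressWarnings(as.integer(raw$meth))
  bad_num <- which(is.na(pos) | is.na(total))
  if (length(bad_num) > 0) {
    stop_data(sprintf(
      "'%s' line %d: malformed position or read count", path, bad_num[1]
    ))
  }
  # count column absent/blank: reconstruct from the level
  missing_meth <- is.na(meth)
  meth[missing_meth] <- as.integer(round(level[missing_meth] * total[missing_meth]))
  bad_cnt <- which(is.na(meth) | meth < 0 | total < 0 | meth > total)
  if (length(bad_cnt) > 0) {
    stop_data(sprintf(
      "'%s' line %d: methylated reads exceed total reads", path, bad_cnt[1]
    ))
  }
  tibble(
    sample_id = sample_id,
    group = group,
    replicate = replicate,
    chrom = raw$chrom,
    pos = pos,
    strand = ifelse(nuc == "C", "+", "-"),
    context = context,
    meth_reads = meth,
    total_reads = total
  )
}

#' Write calls of one sample as a CGmap file
#'
#' @param calls Call tibble for a single sample.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cgmap <- function(calls, path) {
  assert_calls(calls)
  if (length(unique(calls$sample_id)) > 1) {
    stop_data("`write_cgmap()` writes one sample per file")
  }
  level <- ifelse(calls$total_reads > 0,
    calls$meth_reads / calls$total_reads, 0
  )
  out <- data.frame(
    chrom = calls$chrom,
    nuc = ifelse(calls$strand == "+", "C", "G"),
    pos = calls$pos,
    context = calls$context,
    dinuc = calls$context,
    level = formatC(level, digits = 6, format = "g"),
    meth = calls$meth_reads,
    total = calls$total_reads
  )
  utils::write.table(out, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read a two-count bedGraph methylation track
#'
#' Expects columns chrom, start (0-based), end, methylation level, and two
#' trailing count columns (methylated, total). Context is assumed CG.
#'
#' @inheritParams read_cgmap
#' @export
read_bedgraph_meth <- function(path, sample_id = NULL, group = NA_character_,
                               replicate = NA_integer_) {
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "")
  if (ncol(raw) < 6) stop_data("bedGraph methylation track needs 6 columns")
  tibble(
    sample_id = sample_id, group = group, replicate = replicate,
    chrom = as.character(raw[[1]]),
    pos = as.integer(raw[[2]]) + 1L,
    strand = "+",
    context = "CG",
    meth_reads = as.integer(raw[[5]]),
    total_reads = as.integer(raw[[6]])
  )
}

#' Keep calls of one cytosine context
#'
#' The DMR analysis uses CpG-context cytosines only; CHG/CHH calls are
#' discarded up front.
#'
#' @param calls Call tibble.
#' @param context Context to retain (default `"CG"`).
#' @export
filter_context <- function(calls, context = "CG") {
  assert_calls(calls)
  filter(calls, .data$context %in% !!context)
}

#' Pool the two strands of each CpG
#'
#' The minus-strand cytosine of a CpG sits one base downstream of the
#' plus-strand cytosine; CpG methylation is symmetric, so both calls are
#' pooled onto the plus-strand coordinate by summing methylated and total
#' reads. A minus-strand call without a plus-strand partner is kept (at its
#' CpG position, i.e. its own position minus one) and flagged via the
#' `unpaired_minus` column.
#'
#' @param calls CG-context call tibble (one or more samples).
#' @return Call tibble with uniformly `+` strand, unique `(sample, chrom,
#'   pos)` and an extra logical column `unpaired_minus`.
#' @export
combine_strands <- function(calls) {
  assert_calls(calls)
  if (any(calls$context != "CG")) {
    stop_data("`combine_strands()` expects CG-context calls; run filter_context() first")
  }
  calls |>
    mutate(
      cpg_pos = ifelse(.data$strand == "-", .data$pos - 1L, .data$pos),
      is_minus = .data$strand == "-"
    ) |>
    group_by(
      .data$sample_id, .data$group, .data$replicate, .data$chrom, .data$cpg_pos
    ) |>
    summarise(
      meth_reads = sum(.data$meth_reads),
      total_reads = sum(.data$total_reads),
      unpaired_minus = all(.data$is_minus),
      .groups = "drop"
    ) |>
    transmute(
      sample_id = .data$sample_id, group = .data$group,
      replicate = .data$replicate, chrom = .data$chrom,
      pos = as.integer(.data$cpg_pos), strand = "+", context = "CG",
      meth_reads = .data$meth_reads, total_reads = .data$total_reads,
      unpaired_minus = .data$unpaired_minus
    ) |>
    arrange(.data$sample_id, .data$chrom, .data$pos)
}

#' Drop sites sequenced below a read-depth threshold
#'
#' Implements the per-site exclusion of lowly covered cytosines (default:
#' fewer than ten sequenced reads). Independent of the per-window read
#' filter applied by the DMR caller.
#'
#' @param calls Call tibble.
#' @param min_reads Minimum total reads per site.
#' @export
filter_coverage <- function(calls, min_reads = 10L) {
  assert_calls(calls)
  assert_scalar_number(min_reads, "min_reads", lower = 0)
  filter(calls, .data$total_reads >= min_reads)
}
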