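# Internal helpers shared across modules.

clamp01 <- function(x, eps = 0) pmin(1 - eps, pmax(eps, x))

# Convert a tibble with chrom/start/end (0-based half-open) to GRanges.
# GRanges is 1-based inclusive, hence the +1 on start.
as_granges0 <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

# Derive a reproducible child seed; keeps results within 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% 2147483629)
}

stop_config <- function(msg) abort(msg, class = "rrbsdmr_config_error")
stop_data <- function(msg) abort(msg, class = "rrbsdmr_data_error")

assert_scalar_number <- function(x, name, lower = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (strict) x > lower else x >= lower)
  if (!ok) {
    stop_config(sprintf(
      "`%s` must be a single finite number %s %s", name,
      if (strict) ">" else ">=", format(lower)
    ))
  }
  invisible(x)
}

# Columns every per-cytosine call table is expected to carry.
call_columns <- c(
  "sample_id", "group", "replicate", "chrom", "pos", "strand",
  "context", "meth_reads", "total_reads"
)

assert_calls <- function(calls, arg = "calls") {
  missing <- setdiff(call_columns, names(calls))
  if (length(missing) > 0) {
    stop_data(sprintf(
      "`%s` is missing methylation-call columns: %s",
      arg, paste(missing, collapse = ", ")
    ))
  }
  invisible(calls)
}
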