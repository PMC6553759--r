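write_cgmap_lines <- function(lines) {
  f <- tempfile(fileext = ".CGmap")
  writeLines(lines, f)
  f
}

test_that("a G-nucleotide row parses as a minus-strand CG site", {
  f <- write_cgmap_lines("chr1\tG\t3541\tCG\tCG\t0.8\t8\t10")
  m <- read_cgmap(f, sample_id = "s")
  expect_equal(m$chrom, "chr1")
  expect_equal(m$pos, 3541L)
  expect_equal(m$strand, "-")
  expect_equal(m$context, "CG")
  expect_equal(m$meth_reads, 8L)
  expect_equal(m$total_reads, 10L)
})

test_that("an empty file gives an empty methylome", {
  f <- write_cgmap_lines(character())
  expect_equal(nrow(read_cgmap(f)), 0L)
})

test_that("context filtering retains exactly the CG rows", {
  f <- write_cgmap_lines(c(
    "chr1\tC\t10\tCHH\tCA\t0.0\t0\t12",
    "chr1\tC\t20\tCG\tCG\t0.5\t6\t12",
    "chr1\tC\t30\tCHG\tCC\t0.1\t1\t10"
  ))
  m <- read_cgmap(f)
  expect_equal(nrow(filter_context(m)), 1L)
  # line-level oracle: count of rows whose 4th field is CG
  raw <- readLines(f)
  expect_equal(
    nrow(filter_context(m)),
    sum(vapply(strsplit(raw, "\t"), function(x) x[4] == "CG", logical(1)))
  )
})

test_that("a missing count column is reconstructed from the level", {
  f <- write_cgmap_lines("chr1\tC\t10\tCG\tCG\t0.75\t\t12")
  expect_equal(read_cgmap(f)$meth_reads, 9L)
})

test_that("malformed rows are rejected with their line number", {
  f <- write_cgmap_lines(c(
    "chr1\tC\t10\tCG\tCG\t0.5\t6\t12",
    "chr1\tC\t20\tCG\tCG\t0.5\t15\t10"
  ))
  expect_error(read_cgmap(f), "line 2", class = "rrbsdmr_data_error")
  f2 <- write_cgmap_lines("chr1\tC\t10\tCpA\tCA\t0.5\t5\t10")
  expect_error(read_cgmap(f2), "context", class = "rrbsdmr_data_error")
})

test_that("write_cgmap/read_cgmap round-trips calls", {
  sm <- small_planted_sim()
  calls <- dplyr::filter(sm$meth$calls, sample_id == "I_r1")
  f <- tempfile(fileext = ".CGmap")
  write_cgmap(calls, f)
  back <- read_cgmap(f, sample_id = "I_r1", group = "I", replicate = 1L)
  expect_equal(
    back[c("chrom", "pos", "strand", "context", "meth_reads", "total_reads")],
    calls[c("chrom", "pos", "strand", "context", "meth_reads", "total_reads")]
  )
})

test_that("strand combination pools paired calls and conserves reads", {
  paired <- tibble::tibble(
    sample_id = "s", group = "I", replicate = 1L, chrom = "chr1",
    pos = c(100L, 101L), strand = c("+", "-"), context = "CG",
    meth_reads = c(3L, 2L), total_reads = c(10L, 10L)
  )
  out <- combine_strands(paired)
  expect_equal(nrow(out), 1L)
  expect_equal(out$pos, 100L)
  expect_equal(out$meth_reads, 5L)
  expect_equal(out$total_reads, 20L)
  expect_false(out$unpaired_minus)

  # plus-only input is the identity on counts
  plus_only <- paired[1, ]
  expect_equal(combine_strands(plus_only)$meth_reads, 3L)

  # unpaired minus call relocates to its CpG position and is flagged
  minus_only <- paired[2, ]
  lone <- combine_strands(minus_only)
  expect_equal(lone$pos, 100L)
  expect_true(lone$unpaired_minus)

  # conservation on random paired input
  set.seed(7)
  cpg <- sort(sample(1000, 50)) * 3L
  rand <- tibble::tibble(
    sample_id = "s", group = "I", replicate = 1L, chrom = "chr1",
    pos = as.integer(c(cpg, cpg + 1L)),
    strand = rep(c("+", "-"), each = length(cpg)), context = "CG",
    meth_reads = as.integer(rbinom(2 * length(cpg), 10, 0.4)),
    total_reads = 10L
  )
  out <- combine_strands(rand)
  expect_equal(sum(out$total_reads), sum(rand$total_reads))
  expect_equal(sum(out$meth_reads), sum(rand$meth_reads))
  expect_true(all(out$strand == "+"))
  expect_equal(anyDuplicated(out[c("chrom", "pos")]), 0L)
})

test_that("coverage filtering is monotone and matches thresholds", {
  calls <- group_calls("I", pos = c(10, 20, 30), meth = 1, total = c(5, 10, 15), n_reps = 1)
  expect_equal(nrow(filter_coverage(calls, 0)), 3L)
  expect_equal(nrow(filter_coverage(calls, 10)), 2L)
  sm <- small_planted_sim()
  sizes <- vapply(
    seq(0, 50, by = 5),
    function(k) nrow(filter_coverage(sm$meth$calls, k)),
    numeric(1)
  )
  expect_true(all(diff(sizes) <= 0))
})

test_that("bedGraph methylation import maps 0-based starts to 1-based C positions", {
  f <- tempfile(fileext = ".bedGraph")
  writeLines("chr2\t99\t101\t0.5\t5\t10", f)
  m <- read_bedgraph_meth(f, sample_id = "s")
  expect_equal(m$pos, 100L)
  expect_equal(m$meth_reads, 5L)
})
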