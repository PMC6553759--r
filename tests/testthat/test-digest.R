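test_that("cut sites match the worked examples", {
  expect_equal(find_cut_sites("AACCGGTT", enzyme("MspI", "CCGG", 1)), 3L)
  expect_equal(find_cut_sites("TTTTTTTT", enzyme("MspI", "CCGG", 1)), integer())
  expect_equal(
    find_cut_sites("TTGCAGCTTGCTGCTT", enzyme("ApeKI", "GCWGC", 1)),
    c(3L, 10L)
  )
})

test_that("invalid motifs and N-containing subjects behave correctly", {
  expect_error(enzyme("bad", "CXGG", 1), class = "rrbsdmr_config_error")
  # ambiguous genome bases never match
  expect_equal(find_cut_sites("AACNGGTT", enzyme("MspI", "CCGG", 1)), integer())
})

test_that("both default motifs are reverse-complement-closed as degenerate sets", {
  for (e in default_enzymes()) {
    lits <- iupac_expand(e$recognition)
    rc <- vapply(
      lits,
      function(l) {
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(l)))
      },
      character(1)
    )
    expect_setequal(unname(rc), lits)
  }
})

test_that("a single internal MspI pair yields the expected fragment", {
  cfg <- digest_config(insilico_min_bp = 1, insilico_max_bp = 500)
  frags <- digest_genome(c(chr1 = "AACCGGTTTTCCGGAA"), cfg)
  expect_equal(nrow(frags), 1L)
  expect_equal(frags$start, 3L)
  expect_equal(frags$end, 11L)
  expect_equal(frags$length_bp, 8L)
  expect_equal(frags$left_enzyme, "MspI")
})

test_that("a genome without cut sites yields no internally bounded fragments", {
  expect_equal(nrow(digest_genome(c(chr1 = strrep("AT", 200)))), 0L)
})

test_that("fragments on random sequence equal the motif-expansion oracle", {
  set.seed(404)
  seq_str <- paste(
    sample(c("A", "C", "G", "T"), 5e4, replace = TRUE, prob = c(.3, .2, .2, .3)),
    collapse = ""
  )
  cfg <- digest_config()
  frags <- digest_genome(c(chr1 = seq_str), cfg)
  orc <- oracle_fragments(seq_str, cfg$enzymes, 30, 500)
  expect_equal(frags$start, orc$start)
  expect_equal(frags$end, orc$end)
  expect_true(all(frags$length_bp >= 30 & frags$length_bp <= 500))
})

test_that("digesting the reverse complement mirrors the fragment set", {
  set.seed(405)
  seq_str <- paste(
    sample(c("A", "C", "G", "T"), 3e4, replace = TRUE),
    collapse = ""
  )
  L <- nchar(seq_str)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_str)))

  # single palindromic-motif enzyme: fragment length multiset is invariant
  msp_only <- digest_config(
    enzymes = list(enzyme("MspI", "CCGG", 1)),
    insilico_min_bp = 1, insilico_max_bp = 1e6
  )
  f_fwd <- digest_genome(c(chr1 = seq_str), msp_only)
  f_rev <- digest_genome(c(chr1 = rc), msp_only)
  expect_equal(sort(f_fwd$length_bp), sort(f_rev$length_bp))

  # double digest: cutting the reverse complement with the mirrored offsets
  # (the bottom-strand cut of each site) maps exactly onto the forward set
  fwd_cfg <- digest_config()
  mir_cfg <- digest_config(enzymes = list(
    enzyme("MspI", "CCGG", 3), enzyme("ApeKI", "GCWGC", 4)
  ))
  f <- digest_genome(c(chr1 = seq_str), fwd_cfg)
  r <- digest_genome(c(chr1 = rc), mir_cfg)
  mapped <- tibble::tibble(start = L - rev(r$end), end = L - rev(r$start))
  expect_equal(f$start, mapped$start)
  expect_equal(f$end, mapped$end)
})

test_that("widening the in-silico length range never removes fragments", {
  set.seed(406)
  seq_str <- paste(sample(c("A", "C", "G", "T"), 2e4, replace = TRUE), collapse = "")
  narrow <- digest_genome(c(chr1 = seq_str), digest_config(insilico_min_bp = 50, insilico_max_bp = 300))
  wide <- digest_genome(c(chr1 = seq_str), digest_config(insilico_min_bp = 30, insilico_max_bp = 500))
  key <- function(d) paste(d$start, d$end)
  expect_true(all(key(narrow) %in% key(wide)))
})

test_that("size selection subtracts adapters and floors at 1", {
  ladder <- tibble::tibble(
    chrom = "chr1", start = 0L, end = seq(10L, 500L, by = 10L),
    left_enzyme = "MspI", right_enzyme = "MspI",
    length_bp = seq(10L, 500L, by = 10L), n_cpgs = 0L
  )
  no_adapter <- size_select(ladder, digest_config(adapter_total_bp = 0))
  expect_equal(range(no_adapter$length_bp), c(160L, 420L))
  with_adapter <- size_select(ladder, digest_config()) # adapter 120
  expect_equal(range(with_adapter$length_bp), c(40L, 300L))
  expect_true(all(with_adapter$length_bp %in% ladder$length_bp))
  expect_equal(nrow(size_select(ladder[0, ], digest_config())), 0L)
  expect_error(
    digest_config(adapter_total_bp = 500),
    class = "rrbsdmr_config_error"
  )
})

test_that("capture report counts CpGs like a direct interval oracle", {
  set.seed(407)
  seq_str <- paste(sample(c("A", "C", "G", "T"), 2e4, replace = TRUE), collapse = "")
  genome <- c(chr1 = seq_str)
  frags <- digest_genome(genome, digest_config())
  rep_ <- capture_report(frags, genome)
  # brute-force per-CpG membership
  s <- strsplit(seq_str, "")[[1]]
  cg0 <- which(s[-length(s)] == "C" & s[-1] == "G") - 1L
  n_in <- sum(vapply(
    cg0,
    function(p) any(p >= frags$start & p + 2 <= frags$end),
    logical(1)
  ))
  expect_equal(rep_$n_cpgs_captured, n_in)
  expect_equal(rep_$n_cpgs_genome, length(cg0))
  expect_gte(rep_$cpg_fraction, 0)
  expect_lte(rep_$cpg_fraction, 1)
  # whole-genome fragment captures every CpG
  whole <- tibble::tibble(
    chrom = "chr1", start = 0L, end = nchar(seq_str),
    left_enzyme = "MspI", right_enzyme = "MspI",
    length_bp = nchar(seq_str), n_cpgs = length(cg0)
  )
  expect_equal(capture_report(whole, genome)$cpg_fraction, 1)
  empty <- capture_report(frags[0, ], genome)
  expect_equal(empty$n_fragments, 0L)
  expect_equal(empty$cpg_fraction, 0)
})
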