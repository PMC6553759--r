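toy_features <- function() {
  tibble::tibble(
    chrom = "chr1",
    start = c(10000L, 10000L, 10200L, 11000L, 12800L),
    end = c(13000L, 10200L, 11000L, 12800L, 13000L),
    strand = "+",
    gene_id = "GENEA",
    category = c("transcript", "5UTR", "Exon", "Intron", "3UTR")
  )
}

test_that("TSS windows follow the configured up/downstream arithmetic", {
  tr <- build_tracks(toy_features())
  tss <- dplyr::filter(tr$tracks, track == "TSS")
  expect_equal(tss$start, 9000L)
  expect_equal(tss$end - 1L, 10100L) # inclusive end

  minus <- toy_features()
  minus$strand <- "-"
  trm <- build_tracks(minus)
  tssm <- dplyr::filter(trm$tracks, track == "TSS")
  # minus-strand TSS sits at the right gene end; the window mirrors
  expect_equal(tssm$end - 1L, 12999L + 1000L)
  expect_equal(tssm$start, 12999L - 100L)
  expect_equal(trm$tss$tss, 12999L)
})

test_that("transcripts with inverted coordinates are rejected", {
  bad <- toy_features()
  bad$end[1] <- bad$start[1]
  expect_error(build_tracks(bad), class = "rrbsdmr_data_error")
})

test_that("priority resolves multi-track overlaps; intergenic is the fallback", {
  tr <- build_tracks(toy_features())
  # inside the TSS window and the 5'UTR/exon: TSS wins
  d1 <- tibble::tibble(chrom = "chr1", start = 10050L, end = 10250L)
  a1 <- annotate_dmrs(d1, tr)
  expect_equal(a1$category, "TSS")
  expect_equal(a1$nearest_gene, "GENEA")
  # overlapping nothing on a known chromosome
  d2 <- tibble::tibble(chrom = "chr1", start = 500000L, end = 500100L)
  expect_equal(annotate_dmrs(d2, tr)$category, "Intergenic")
  # chromosome absent from every track
  d3 <- tibble::tibble(chrom = "chrZ", start = 0L, end = 100L)
  expect_true(is.na(annotate_dmrs(d3, tr)$category))
  # moving Intron to the top of the priority reassigns an intron overlap
  d4 <- tibble::tibble(chrom = "chr1", start = 11050L, end = 11150L)
  expect_equal(annotate_dmrs(d4, tr)$category, "Intron")
})

test_that("an empty repeats track never yields the Repeats category", {
  sm <- small_planted_sim()
  feats <- dplyr::filter(sm$sim$features, category != "Repeats")
  tr <- build_tracks(feats, sm$sim$islands)
  dmrs <- random_dmr_set(100, span = 40000L)
  ann <- annotate_dmrs(dmrs, tr)
  expect_false(any(ann$category == "Repeats", na.rm = TRUE))
})

test_that("category assignment equals the per-category overlap oracle", {
  sm <- small_planted_sim()
  tr <- build_tracks(sm$sim$features, sm$sim$islands)
  set.seed(808)
  dmrs <- random_dmr_set(200, span = 48000L)
  ann <- annotate_dmrs(dmrs, tr)
  for (i in seq_len(nrow(dmrs))) {
    expect_equal(
      ann$category[i],
      oracle_annotate_category(dmrs[i, ], tr$tracks, annotation_priority())
    )
  }
})

test_that("promoting a category in the priority never decreases its count", {
  sm <- small_planted_sim()
  tr <- build_tracks(sm$sim$features, sm$sim$islands)
  set.seed(809)
  dmrs <- random_dmr_set(150, span = 48000L)
  default_n <- sum(annotate_dmrs(dmrs, tr)$category == "Intron", na.rm = TRUE)
  promoted <- c("Intron", setdiff(annotation_priority(), "Intron"))
  promoted_n <- sum(
    annotate_dmrs(dmrs, tr, priority = promoted)$category == "Intron",
    na.rm = TRUE
  )
  expect_gte(promoted_n, default_n)
})

test_that("nearest-gene distances are signed and tie-broken deterministically", {
  feats <- dplyr::bind_rows(
    toy_features(),
    dplyr::mutate(toy_features(),
      gene_id = "GENEB",
      start = start + 20000L, end = end + 20000L
    )
  )
  tr <- build_tracks(feats)
  d <- tibble::tibble(chrom = "chr1", start = 10950L, end = 11050L)
  a <- annotate_dmrs(d, tr)
  expect_equal(a$nearest_gene, "GENEA")
  expect_equal(a$distance_to_tss, 1000L) # midpoint 11000, TSS 10000, downstream
  # equidistant genes resolve lexicographically
  feats_tie <- dplyr::bind_rows(
    toy_features(),
    dplyr::mutate(toy_features(), gene_id = "GENEB", start = start + 2000L, end = end + 2000L)
  )
  tr_tie <- build_tracks(feats_tie)
  d_tie <- tibble::tibble(chrom = "chr1", start = 10950L, end = 11050L)
  # midpoint 11000: GENEA TSS 10000 (d=+1000), GENEB TSS 12000 (d=-1000)
  expect_equal(annotate_dmrs(d_tie, tr_tie)$nearest_gene, "GENEA")
})

test_that("distribution reports conserve counts and recompute percentages", {
  sm <- small_planted_sim()
  tr <- build_tracks(sm$sim$features, sm$sim$islands)
  set.seed(810)
  dmrs <- random_dmr_set(120, span = 48000L)
  ann <- annotate_dmrs(dmrs, tr)
  rep_ <- distribution_report(ann)
  expect_equal(sum(rep_$n), nrow(ann))
  expect_lt(abs(sum(rep_$pct) - 100), 0.2)
  expect_equal(rep_$pct, round(100 * rep_$n / sum(rep_$n), 1))
  one_cat <- tibble::tibble(category = rep("Exon", 5))
  expect_equal(distribution_report(one_cat)$pct, 100)
})
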