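test_that("identical configurations give byte-identical genomes, tracks and calls", {
  cfg <- sim_config(
    seed = 1, chrom_length_bp = 20000, island_fraction = 0.1,
    groups = c("I", "II"), replicates_per_group = 3
  )
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$islands, b$islands)
  expect_identical(a$features, b$features)
  ma <- simulate_methylomes(cfg, a)
  mb <- simulate_methylomes(cfg, b)
  expect_identical(ma$calls, mb$calls)
  # CGmap output is byte-identical on rerun
  f1 <- tempfile()
  f2 <- tempfile()
  write_cgmap(dplyr::filter(ma$calls, sample_id == "I_r1"), f1)
  write_cgmap(dplyr::filter(mb$calls, sample_id == "I_r1"), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("island_fraction = 0 yields an empty island track", {
  cfg <- sim_config(seed = 2, chrom_length_bp = 20000, island_fraction = 0)
  expect_equal(nrow(simulate_genome(cfg)$islands), 0L)
})

test_that("CpG density inside islands is at least twice the background rate", {
  cfg <- sim_config(seed = 1, chrom_length_bp = 1e5, island_fraction = 0.1)
  sim <- simulate_genome(cfg)
  s <- strsplit(as.character(sim$genome[[1]]), "")[[1]]
  cg0 <- which(s[-length(s)] == "C" & s[-1] == "G") - 1L
  in_island <- rep(FALSE, length(s))
  for (k in seq_len(nrow(sim$islands))) {
    in_island[(sim$islands$start[k] + 1):sim$islands$end[k]] <- TRUE
  }
  isl_bp <- sum(in_island)
  bg_bp <- length(s) - isl_bp
  isl_rate <- sum(in_island[cg0 + 1]) / isl_bp
  bg_rate <- sum(!in_island[cg0 + 1]) / bg_bp
  expect_gte(isl_rate / bg_rate, 2)
})

test_that("calls respect count conservation and configured coverage", {
  cfg <- sim_config(
    seed = 5, chrom_length_bp = 6e5, island_fraction = 0.1,
    coverage_mean = 30, coverage_dispersion = 0.05,
    groups = c("I", "II"), replicates_per_group = 2
  )
  sim <- simulate_genome(cfg)
  m <- simulate_methylomes(cfg, sim)
  expect_true(all(m$calls$meth_reads >= 0))
  expect_true(all(m$calls$meth_reads <= m$calls$total_reads))
  expect_true(all(m$calls$total_reads >= 1))
  expect_gt(nrow(m$calls) / 4, 1e4) # >= 10^4 sites per sample
  expect_lt(abs(mean(m$calls$total_reads) - 30) / 30, 0.1)
})

test_that("zero planted shifts leave group means equal at the planted intervals", {
  base <- sim_config(
    seed = 8, chrom_length_bp = 50000, island_fraction = 0.12,
    coverage_mean = 50, groups = c("I", "II"), replicates_per_group = 3
  )
  sim0 <- simulate_genome(base)
  planted <- plant_dmrs_in_islands(sim0, 4, list(c(II = 0)), width = 150, min_cpgs = 10)
  cfg <- sim_config(
    seed = 8, chrom_length_bp = 50000, island_fraction = 0.12,
    coverage_mean = 50, groups = c("I", "II"), replicates_per_group = 3,
    planted_dmrs = planted
  )
  sim <- simulate_genome(cfg)
  m <- simulate_methylomes(cfg, sim)
  for (i in seq_len(nrow(planted))) {
    seg <- dplyr::filter(
      m$calls,
      chrom == planted$chrom[i],
      pos - 1 >= planted$start[i], pos - 1 < planted$end[i]
    )
    diff_i <- mean(seg$meth_reads[seg$group == "II"] / seg$total_reads[seg$group == "II"]) -
      mean(seg$meth_reads[seg$group == "I"] / seg$total_reads[seg$group == "I"])
    expect_lt(abs(diff_i), 0.05)
  }
})

test_that("a planted 0.4 shift is realized within 0.1 at the interval", {
  sm <- small_planted_sim()
  m <- sm$meth
  planted <- sm$planted
  for (i in seq_len(nrow(planted))) {
    seg <- dplyr::filter(
      m$calls,
      chrom == planted$chrom[i],
      pos - 1 >= planted$start[i], pos - 1 < planted$end[i]
    )
    diff_i <- mean(seg$meth_reads[seg$group == "II"] / seg$total_reads[seg$group == "II"]) -
      mean(seg$meth_reads[seg$group == "I"] / seg$total_reads[seg$group == "I"])
    expected <- planted$delta_II[i] - planted$delta_I[i]
    expect_lt(abs(diff_i - expected), 0.1)
  }
})

test_that("true site means follow the configured Beta mixture", {
  cfg <- sim_config(
    seed = 9, chrom_length_bp = 5e5, island_fraction = 0.2,
    groups = c("I", "II"), replicates_per_group = 2
  )
  sim <- simulate_genome(cfg)
  m <- simulate_methylomes(cfg, sim)
  sm <- m$truth$site_means
  expect_gt(nrow(sm), 1e4)
  set.seed(1)
  analytic <- ifelse(
    sm$island,
    rbeta(nrow(sm), cfg$island_meth_beta[1], cfg$island_meth_beta[2]),
    rbeta(nrow(sm), cfg$background_meth_beta[1], cfg$background_meth_beta[2])
  )
  ks <- suppressWarnings(stats::ks.test(sm$mu_I, analytic))
  expect_lt(unname(ks$statistic), 0.05)
  # read-level ratios centre on the same mixture mean
  ratios <- m$calls$meth_reads / m$calls$total_reads
  expect_lt(abs(mean(ratios) - mean(sm$mu_I)), 0.03)
})

test_that("planted intervals outside the genome raise a named error", {
  cfg <- sim_config(
    seed = 3, chrom_length_bp = 10000, island_fraction = 0,
    groups = c("I", "II"),
    planted_dmrs = tibble::tibble(
      chrom = "chr1", start = 9950L, end = 10100L, delta_II = 0.4
    )
  )
  sim <- simulate_genome(cfg)
  expect_error(
    simulate_methylomes(cfg, sim), "chr1:9950-10100",
    class = "rrbsdmr_config_error"
  )
})

test_that("invalid simulator configurations are rejected", {
  expect_error(sim_config(chrom_length_bp = 0), class = "rrbsdmr_config_error")
  expect_error(sim_config(island_meth_beta = c(0, 1)), class = "rrbsdmr_config_error")
  expect_error(sim_config(replicates_per_group = 1), class = "rrbsdmr_config_error")
  expect_error(
    sim_config(planted_dmrs = tibble::tibble(
      chrom = "chr1", start = c(0L, 50L), end = c(100L, 150L), delta_II = 0.4
    )),
    class = "rrbsdmr_config_error"
  )
  expect_error(
    sim_config(planted_dmrs = tibble::tibble(
      chrom = "chr1", start = 0L, end = 100L, delta_V = 0.4
    )),
    class = "rrbsdmr_config_error"
  )
})

test_that("truth sidecars round-trip through files", {
  sm <- small_planted_sim()
  f <- tempfile(fileext = ".bed")
  write_truth_bed(sm$planted, f)
  back <- read_truth_bed(f)
  expect_equal(as.data.frame(back), as.data.frame(sm$planted))
})
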