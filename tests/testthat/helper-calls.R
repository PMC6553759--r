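# Builders for small hand-specified call tables.

# One group's calls: `meth` is a sites x replicates matrix of methylated
# read counts (or a vector recycled across replicates); `total` likewise.
group_calls <- function(group, pos, meth, total, n_reps = 3, chrom = "chr1") {
  meth <- matrix(meth, nrow = length(pos), ncol = n_reps)
  total <- matrix(total, nrow = length(pos), ncol = n_reps)
  purrr::map(seq_len(n_reps), function(r) {
    tibble::tibble(
      sample_id = paste0(group, "_r", r),
      group = group,
      replicate = r,
      chrom = chrom,
      pos = as.integer(pos),
      strand = "+",
      context = "CG",
      meth_reads = as.integer(meth[, r]),
      total_reads = as.integer(total[, r])
    )
  }) |>
    purrr::list_rbind()
}

# A small simulated two-group data set with planted regions, shared by
# several tests (built once per test run).
small_planted_sim <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) {
      return(cache)
    }
    base <- sim_config(
      seed = 11, chrom_length_bp = 50000, island_fraction = 0.12,
      coverage_mean = 50, groups = c("I", "II"), replicates_per_group = 3
    )
    sim <- simulate_genome(base)
    planted <- plant_dmrs_in_islands(
      sim, 4, list(c(II = 0.4), c(I = 0.4)),
      width = 150, min_cpgs = 10
    )
    cfg <- sim_config(
      seed = 11, chrom_length_bp = 50000, island_fraction = 0.12,
      coverage_mean = 50, groups = c("I", "II"), replicates_per_group = 3,
      planted_dmrs = planted
    )
    sim <- simulate_genome(cfg)
    meth <- simulate_methylomes(cfg, sim)
    cache <<- list(cfg = cfg, sim = sim, meth = meth, planted = planted)
    cache
  }
})

random_dmr_set <- function(n, chrom = "chr1", span = 5000L) {
  start <- sample.int(span, n, replace = TRUE)
  width <- sample(50:250, n, replace = TRUE)
  tibble::tibble(
    chrom = chrom,
    start = as.integer(start),
    end = as.integer(start + width),
    direction = sample(c("hyper", "hypo"), n, replace = TRUE)
  )
}
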