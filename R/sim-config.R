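#' Configuration for the bisulfite methylome simulator
#'
#' Bundles every knob of the synthetic-genome and synthetic-methylome
#' generators. The defaults emulate the experimental design the package's
#' DMR caller is aimed at: four treatment groups (I control, II oleic acid,
#' III OA + *Allium tuberosum* extract, IV OA + *Capsella bursa-pastoris*
#' extract) with three biological replicates each, a bimodal per-site
#' methylation landscape (lowly methylated CpG islands against a highly
#' methylated background), and overdispersed sequencing depth.
#'
#' @param seed Integer seed; identical configurations (including the seed)
#'   produce byte-identical genomes and call sets.
#' @param n_chroms Number of simulated chromosomes.
#' @param chrom_length_bp Length of each chromosome in bp.
#' @param island_fraction Fraction of each chromosome covered by CpG islands,
#'   in `[0, 1]`.
#' @param island_meth_beta,background_meth_beta Length-2 numeric
#'   `(alpha, beta)` of the Beta distributions from which true per-site
#'   methylation means are drawn inside and outside islands. Both shape
#'   parameters must be strictly positive.
#' @param coverage_mean Mean per-site read depth (negative-binomial mean,
#'   truncated at 1).
#' @param coverage_dispersion Negative-binomial overdispersion; the depth
#'   variance is `mu + dispersion * mu^2`.
#' @param replicate_noise_kappa Concentration of the Beta distribution from
#'   which replicate-level methylation means are drawn around the group mean
#'   (larger = less replicate-to-replicate noise).
#' @param groups Character vector of group labels.
#' @param replicates_per_group Replicates per group, at least 2 (the
#'   Mann-Whitney comparison needs two groups of observations).
#' @param planted_dmrs Optional tibble of planted differential regions with
#'   columns `chrom`, `start`, `end` (0-based half-open) and one
#'   `delta_<group>` column per shifted group holding signed methylation
#'   shifts in `[-1, 1]`. Intervals must not overlap within a chromosome.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_genome()], [simulate_methylomes()],
#'   [plant_dmrs_in_islands()]
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 1L,
                       chrom_length_bp = 1e6,
                       island_fraction = 0.1,
                       island_meth_beta = c(alpha = 1, beta = 4),
                       background_meth_beta = c(alpha = 6, beta = 1.5),
                       coverage_mean = 60,
                       coverage_dispersion = 0.1,
                       replicate_noise_kappa = 50,
                       groups = c("I", "II", "III", "IV"),
                       replicates_per_group = 3L,
                       planted_dmrs = NULL) {
  assert_scalar_number(seed, "seed")
  assert_scalar_number(n_chroms, "n_chroms", lower = 1)
  assert_scalar_number(chrom_length_bp, "chrom_length_bp", lower = 0, strict = TRUE)
  assert_scalar_number(island_fraction, "island_fraction", lower = 0)
  if (island_fraction > 1) stop_config("`island_fraction` must lie in [0, 1]")
  for (nm in c("island_meth_beta", "background_meth_beta")) {
    par <- get(nm)
    if (length(par) != 2 || any(!is.finite(par)) || any(par <= 0)) {
      stop_config(sprintf("`%s` must be two strictly positive shape parameters", nm))
    }
  }
  assert_scalar_number(coverage_mean, "coverage_mean", lower = 0, strict = TRUE)
  assert_scalar_number(coverage_dispersion, "coverage_dispersion", lower = 0, strict = TRUE)
  assert_scalar_number(replicate_noise_kappa, "replicate_noise_kappa", lower = 0, strict = TRUE)
  groups <- as.character(groups)
  if (length(groups) < 2 || anyDuplicated(groups) > 0) {
    stop_config("`groups` must hold at least two distinct labels")
  }
  assert_scalar_number(replicates_per_group, "replicates_per_group", lower = 2)

  cfg <- structure(
    list(
      seed = as.integer(seed),
      n_chroms = as.integer(n_chroms),
      chrom_length_bp = as.integer(chrom_length_bp),
      island_fraction = island_fraction,
      island_meth_beta = unname(island_meth_beta),
      background_meth_beta = unname(background_meth_beta),
      coverage_mean = coverage_mean,
      coverage_dispersion = coverage_dispersion,
      replicate_noise_kappa = replicate_noise_kappa,
      groups = groups,
      replicates_per_group = as.integer(replicates_per_group),
      planted_dmrs = NULL
    ),
    class = "sim_config"
  )
  if (!is.null(planted_dmrs)) cfg <- set_planted_dmrs(cfg, planted_dmrs)
  cfg
}

# Validate and attach a planted-DMR table to a sim_config.
set_planted_dmrs <- function(cfg, planted) {
  planted <- as_tibble(planted)
  needed <- c("chrom", "start", "end")
  if (!all(needed %in% names(planted))) {
    stop_config("planted DMRs need `chrom`, `start`, `end` columns")
  }
  delta_cols <- grep("^delta_", names(planted), value = TRUE)
  if (length(delta_cols) == 0) {
    stop_config("planted DMRs need at least one `delta_<group>` column")
  }
  unknown <- setdiff(sub("^delta_", "", delta_cols), cfg$groups)
  if (length(unknown) > 0) {
    stop_config(sprintf(
      "planted DMR delta columns name unknown groups: %s",
      paste(unknown, collapse = ", ")
    ))
  }
  if (any(planted$end <= planted$start)) {
    stop_config("planted DMR intervals must satisfy end > start")
  }
  deltas <- as.matrix(planted[delta_cols])
  deltas[is.na(deltas)] <- 0
  if (any(abs(deltas) > 1)) {
    stop_config("planted DMR deltas must lie in [-1, 1]")
  }
  planted[delta_cols] <- as_tibble(deltas)
  overlap <- planted |>
    arrange(.data$chrom, .data$start) |>
    group_by(.data$chrom) |>
    mutate(clash = .data$start < lag(cummax(.data$end), default = -1L)) |>
    ungroup()
  if (any(overlap$clash)) {
    stop_config("planted DMR intervals overlap within a chromosome")
  }
  cfg$planted_dmrs <- planted
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf(
    "  %d chromosome(s) x %s bp, island fraction %.2f\n",
    x$n_chroms, format(x$chrom_length_bp, big.mark = ","), x$island_fraction
  ))
  cat(sprintf(
    "  groups: %s (x%d replicates), coverage ~NB(mean %.0f, dispersion %.2f)\n",
    paste(x$groups, collapse = ", "), x$replicates_per_group,
    x$coverage_mean, x$coverage_dispersion
  ))
  cat(sprintf(
    "  planted DMRs: %d\n",
    if (is.null(x$planted_dmrs)) 0L else nrow(x$planted_dmrs)
  ))
  invisible(x)
}
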