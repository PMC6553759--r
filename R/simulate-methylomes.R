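#' Simulate per-CpG methylation call sets for every sample
#'
#' For every plus-strand CG dinucleotide of the simulated genome, a true
#' site-level methylation mean is drawn from the island or background Beta
#' distribution; planted regional shifts are added to the affected groups
#' (clamped to `[0, 1]`); each replicate then receives a Beta-distributed
#' methylation mean re-parameterised around its group mean with
#' concentration `replicate_noise_kappa`, a truncated negative-binomial
#' read depth, and a binomial methylated-read count.
#'
#' Calls are emitted for the plus-strand C of each CpG only; the strand
#' pooling performed by [combine_strands()] on real data is therefore a
#' no-op on simulated data.
#'
#' @param cfg A [sim_config()].
#' @param sim A `sim_genome` from [simulate_genome()] (the same `cfg`).
#' @return A list of class `sim_methylomes` with
#'   * `calls`: one long tibble of per-cytosine calls for all samples
#'     (columns `sample_id`, `group`, `replicate`, `chrom`, `pos` (1-based
#'     position of the C), `strand`, `context`, `meth_reads`,
#'     `total_reads`),
#'   * `truth`: list with `planted` (the planted-region table) and
#'     `site_means` (per-site true group means, one `mu_<group>` column per
#'     group, plus `island` membership).
#' @export
simulate_methylomes <- function(cfg, sim) {
  stopifnot(inherits(cfg, "sim_config"), inherits(sim, "sim_genome"))
  planted <- cfg$planted_dmrs
  if (!is.null(planted)) {
    bad <- !(planted$chrom %in% names(sim$chrom_lengths)) |
      planted$end > sim$chrom_lengths[planted$chrom] |
      planted$start < 0
    if (any(bad)) {
      b <- planted[which(bad)[1], ]
      stop_config(sprintf(
        "planted DMR %s:%d-%d lies outside the simulated genome",
        b$chrom, b$start, b$end
      ))
    }
  }

  sites <- cpg_positions(sim) |> arrange(.data$chrom, .data$start)
  n <- nrow(sites)
  isl <- sim$islands
  in_island <- rep(FALSE, n)
  if (nrow(isl) > 0 && n > 0) {
    hits <- GenomicRanges::findOverlaps(
      as_granges0(tibble(chrom = sites$chrom, start = sites$start, end = sites$start + 2L)),
      as_granges0(isl)
    )
    in_island[unique(S4Vectors::queryHits(hits))] <- TRUE
  }

  withr::with_seed(child_seed(cfg$seed, 2L), {
    base_mu <- numeric(n)
    base_mu[in_island] <- rbeta(
      sum(in_island), cfg$island_meth_beta[1], cfg$island_meth_beta[2]
    )
    base_mu[!in_island] <- rbeta(
      sum(!in_island), cfg$background_meth_beta[1], cfg$background_meth_beta[2]
    )

    # per-group true site means: baseline plus any planted shift, clamped
    mu_by_group <- matrix(base_mu,
      nrow = n, ncol = length(cfg$groups),
      dimnames = list(NULL, cfg$groups)
    )
    if (!is.null(planted) && n > 0) {
      hits <- GenomicRanges::findOverlaps(
        as_granges0(tibble(chrom = sites$chrom, start = sites$start, end = sites$start + 2L)),
        as_granges0(planted)
      )
      q <- S4Vectors::queryHits(hits)
      s <- S4Vectors::subjectHits(hits)
      for (g in cfg$groups) {
        col <- paste0("delta_", g)
        if (!col %in% names(planted)) next
        mu_by_group[q, g] <- clamp01(mu_by_group[q, g] + planted[[col]][s])
      }
    }

    nb_size <- 1 / cfg$coverage_dispersion
    kappa <- cfg$replicate_noise_kappa
    out <- vector("list", length(cfg$groups) * cfg$replicates_per_group)
    k <- 0L
    for (g in cfg$groups) {
      mu_g <- clamp01(mu_by_group[, g], eps = 1e-4)
      for (r in seq_len(cfg$replicates_per_group)) {
        k <- k + 1L
        rep_mu <- rbeta(n, mu_g * kappa, (1 - mu_g) * kappa)
        cov <- pmax(1L, rnbinom(n, mu = cfg$coverage_mean, size = nb_size))
        meth <- rbinom(n, cov, rep_mu)
        out[[k]] <- tibble(
          sample_id = paste0(g, "_r", r),
          group = g,
          replicate = r,
          chrom = sites$chrom,
          pos = sites$start + 1L,
          strand = "+",
          context = "CG",
          meth_reads = meth,
          total_reads = cov
        )
      }
    }

    site_means <- bind_cols(
      tibble(chrom = sites$chrom, pos = sites$start + 1L, island = in_island),
      as_tibble(mu_by_group) |> rename_with(~ paste0("mu_", .x))
    )
    structure(
      list(
        calls = bind_rows(out),
        truth = list(planted = planted, site_means = site_means)
      ),
      class = "sim_methylomes"
    )
  })
}

#' Write a planted-truth sidecar as BED with delta columns
#'
#' @param planted Planted-region tibble (`chrom`, `start`, `end`,
#'   `delta_<group>` columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(planted, path) {
  readr::write_tsv(planted, path, col_names = TRUE)
  invisible(path)
}

#' @rdname write_truth_bed
#' @export
read_truth_bed <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
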