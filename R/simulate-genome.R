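#' Simulate a toy genome with CpG islands, gene models and repeats
#'
#' Builds random chromosomes over `{A, C, G, T}` in which CpG dinucleotides
#' are depleted in the background (roughly one CG per 100 bp, as in a
#' methylated vertebrate genome) and enriched inside islands (roughly ten
#' per 100 bp), and lays down toy gene models (transcripts with UTRs, exons
#' and introns), non-coding genes and repeat intervals so that the digest
#' and annotation stages can be exercised without any external download.
#'
#' All interval tables use 0-based half-open coordinates.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_genome` with elements
#'   * `genome`: a [Biostrings::DNAStringSet] of the chromosomes,
#'   * `islands`: tibble of CpG-island intervals (`chrom`, `start`, `end`),
#'   * `features`: tibble of gene-model and repeat intervals (`chrom`,
#'     `start`, `end`, `strand`, `gene_id`, `category`), where `category`
#'     is one of `transcript`, `Exon`, `Intron`, `5UTR`, `3UTR`,
#'     `Non-coding`, `Repeats`,
#'   * `chrom_lengths`: named integer vector.
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(child_seed(cfg$seed, 1L), {
    chroms <- paste0("chr", seq_len(cfg$n_chroms))
    L <- cfg$chrom_length_bp
    seqs <- character(cfg$n_chroms)
    islands <- vector("list", cfg$n_chroms)
    features <- vector("list", cfg$n_chroms)
    for (i in seq_len(cfg$n_chroms)) {
      isl <- place_islands(L, cfg$island_fraction)
      seqs[i] <- build_chrom_sequence(L, isl)
      islands[[i]] <- mutate(isl, chrom = chroms[i], .before = 1)
      features[[i]] <- simulate_features(L) |>
        mutate(chrom = chroms[i], .before = 1)
    }
    genome <- Biostrings::DNAStringSet(setNames(seqs, chroms))
    structure(
      list(
        genome = genome,
        islands = bind_rows(islands),
        features = bind_rows(features),
        chrom_lengths = setNames(rep(L, cfg$n_chroms), chroms)
      ),
      class = "sim_genome"
    )
  })
}

# Non-overlapping island intervals covering ~fraction of the chromosome.
# One island per equal-width segment keeps placement collision-free.
place_islands <- function(L, fraction, island_width = 600L) {
  n <- floor(fraction * L / island_width)
  if (fraction <= 0 || n < 1) {
    return(tibble(start = integer(), end = integer()))
  }
  seg <- L / n
  offset <- floor(runif(n, 0, pmax(1, seg - island_width)))
  start <- as.integer(floor((seq_len(n) - 1) * seg) + offset)
  tibble(start = start, end = pmin(start + island_width, L))
}

# Background letters are CpG-depleted (3/4 of random CG dinucleotides are
# broken); island stretches are rewritten with a GC-rich composition.
build_chrom_sequence <- function(L, islands) {
  s <- sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = c(.3, .2, .2, .3))
  cg <- which(s[-L] == "C" & s[-1] == "G")
  if (length(cg) > 0) {
    broken <- cg[runif(length(cg)) < 0.75]
    s[broken + 1] <- "A"
  }
  for (k in seq_len(nrow(islands))) {
    idx <- (islands$start[k] + 1):islands$end[k]
    s[idx] <- sample(c("A", "C", "G", "T"), length(idx),
      replace = TRUE, prob = c(.17, .33, .33, .17)
    )
  }
  paste(s, collapse = "")
}

# Toy gene models: one gene per ~20 kb slot (5'UTR | exon/intron body |
# 3'UTR), ~15% of genes non-coding; repeats every ~5 kb.
simulate_features <- function(L) {
  n_genes <- max(1L, floor(L / 2e4))
  seg <- L / n_genes
  out <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    lo <- min(3000, floor(seg * 0.4))
    hi <- max(lo + 10, min(8000, floor(seg * 0.8)))
    span <- floor(runif(1, lo, hi))
    start <- as.integer(floor((g - 1) * seg) + floor(runif(1, 0, seg - span)))
    end <- start + span
    strand <- sample(c("+", "-"), 1)
    gene_id <- sprintf("GENE%03d", g)
    if (runif(1) < 0.15) {
      out[[g]] <- tibble(
        start = start, end = end, strand = strand, gene_id = gene_id,
        category = c("transcript", "Non-coding")
      )
      next
    }
    utr <- min(200L, span %/% 5L)
    # interior cut points delimiting exon/intron alternation (3 exons)
    body <- sort(as.integer(floor(runif(4, start + utr, end - utr))))
    bounds <- c(start + utr, body, end - utr)
    part_starts <- c(start, bounds[-length(bounds)], end - utr)
    part_ends <- c(start + utr, bounds[-1], end)
    parts <- tibble(
      start = part_starts,
      end = part_ends,
      category = c("5UTR", rep(c("Exon", "Intron"), length.out = 5), "3UTR")
    )
    if (strand == "-") {
      parts$category[parts$category == "5UTR"] <- "tmp"
      parts$category[parts$category == "3UTR"] <- "5UTR"
      parts$category[parts$category == "tmp"] <- "3UTR"
    }
    out[[g]] <- bind_rows(
      tibble(start = start, end = end, category = "transcript"),
      parts
    ) |>
      mutate(strand = strand, gene_id = gene_id)
  }
  genes <- bind_rows(out)
  n_rep <- max(1L, floor(L / 5e3))
  rep_w <- as.integer(floor(runif(n_rep, 100, 300)))
  rep_start <- as.integer(floor(runif(n_rep, 0, L - rep_w)))
  repeats <- tibble(
    start = rep_start, end = rep_start + rep_w, strand = "+",
    gene_id = NA_character_, category = "Repeats"
  )
  bind_rows(genes, repeats) |>
    select("start", "end", "strand", "gene_id", "category") |>
    arrange(.data$start, .data$end, .data$category)
}

#' 0-based start positions of plus-strand CG dinucleotides
#'
#' @param genome A [Biostrings::DNAStringSet] (or `sim_genome`).
#' @return Tibble with columns `chrom`, `start` (0-based position of the C).
#' @export
cpg_positions <- function(genome) {
  if (inherits(genome, "sim_genome")) genome <- genome$genome
  purrr::imap(as.list(genome), function(s, nm) {
    tibble(
      chrom = nm,
      start = Biostrings::start(Biostrings::matchPattern("CG", s)) - 1L
    )
  }) |>
    list_rbind()
}

#' Plant differential regions inside simulated CpG islands
#'
#' Selects islands with enough CpGs and plants fixed-width shifted regions
#' at their centres, cycling through the supplied per-group shift patterns.
#' Planting inside islands guarantees the CpG density the window test needs.
#'
#' @param sim A `sim_genome` from [simulate_genome()].
#' @param n Number of regions to plant.
#' @param deltas List of named numeric vectors, each mapping group labels to
#'   signed methylation shifts; recycled across regions. E.g.
#'   `list(c(II = 0.4), c(I = 0.4))` alternates regions that are hyper- and
#'   hypomethylated in a `II` vs `I` comparison.
#' @param width Width of each planted region in bp.
#' @param min_cpgs Minimum number of CG dinucleotides the planted interval
#'   must contain for the island to qualify.
#' @return Tibble with `chrom`, `start`, `end` and `delta_<group>` columns,
#'   suitable for [sim_config()]'s `planted_dmrs`.
#' @export
plant_dmrs_in_islands <- function(sim, n, deltas, width = 150L, min_cpgs = 10L) {
  stopifnot(inherits(sim, "sim_genome"), is.list(deltas), length(deltas) >= 1)
  cpgs <- cpg_positions(sim)
  cand <- sim$islands |>
    filter(.data$end - .data$start >= width) |>
    mutate(
      p_start = .data$start + ((.data$end - .data$start) - width) %/% 2L,
      p_end = .data$p_start + width
    )
  counts <- map_int(seq_len(nrow(cand)), function(i) {
    sum(cpgs$chrom == cand$chrom[i] &
      cpgs$start >= cand$p_start[i] & cpgs$start + 2L <= cand$p_end[i])
  })
  cand <- cand[counts >= min_cpgs, ]
  if (nrow(cand) < n) {
    stop_config(sprintf(
      "only %d islands hold >= %d CpGs in a %d bp window; %d regions requested",
      nrow(cand), min_cpgs, width, n
    ))
  }
  cand <- head(cand, n)
  groups <- unique(unlist(lapply(deltas, names)))
  delta_tbl <- matrix(0, nrow = n, ncol = length(groups),
    dimnames = list(NULL, paste0("delta_", groups))
  )
  for (i in seq_len(n)) {
    d <- deltas[[(i - 1L) %% length(deltas) + 1L]]
    delta_tbl[i, paste0("delta_", names(d))] <- d
  }
  bind_cols(
    tibble(chrom = cand$chrom, start = cand$p_start, end = cand$p_end),
    as_tibble(delta_tbl)
  )
}
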