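#' Restriction enzymes and digest configuration
#'
#' `enzyme()` describes a restriction enzyme by its IUPAC recognition motif
#' and the 0-based top-strand cut position within the motif.
#' `default_enzymes()` returns the double-enzyme reduced-representation
#' pair MspI (C^CGG) and ApeKI (G^CWGC); both motifs are closed under
#' reverse complement as degenerate sets.
#'
#' @param name Enzyme name.
#' @param recognition IUPAC motif (e.g. `"GCWGC"`, `W = A/T`).
#' @param cut_offset Integer cut position within the motif,
#'   `0 <= cut_offset <= nchar(recognition)`.
#' @return `enzyme()`: a list of class `rrbs_enzyme`; `default_enzymes()`:
#'   a list of two such enzymes.
#' @export
enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  valid <- names(Biostrings::IUPAC_CODE_MAP)
  bad <- setdiff(strsplit(recognition, "")[[1]], valid)
  if (nchar(recognition) == 0 || length(bad) > 0) {
    stop_config(sprintf(
      "recognition motif '%s' contains non-IUPAC characters (%s)",
      recognition, paste(bad, collapse = ", ")
    ))
  }
  assert_scalar_number(cut_offset, "cut_offset", lower = 0)
  if (cut_offset > nchar(recognition)) {
    stop_config("`cut_offset` must not exceed the motif length")
  }
  structure(
    list(name = name, recognition = recognition, cut_offset = as.integer(cut_offset)),
    class = "rrbs_enzyme"
  )
}

#' @rdname enzyme
#' @export
default_enzymes <- function() {
  list(enzyme("MspI", "CCGG", 1L), enzyme("ApeKI", "GCWGC", 1L))
}

#' @param enzymes List of [enzyme()] objects.
#' @param insilico_min_bp,insilico_max_bp Fragment-length range retained by
#'   the in-silico digest (defaults 30-500 bp).
#' @param size_select_min_bp,size_select_max_bp Gel size-selection window on
#'   adapter-ligated library molecules (defaults 160-420 bp).
#' @param adapter_total_bp Total adapter bp ligated to a fragment; converts
#'   the library size-selection window into an insert-length window.
#' @param include_end_fragments Keep chromosome-end fragments (which lack an
#'   enzyme cut on one side)? Default `FALSE`: RRBS fragments need enzyme
#'   ends on both sides.
#' @rdname enzyme
#' @export
digest_config <- function(enzymes = default_enzymes(),
                          insilico_min_bp = 30L, insilico_max_bp = 500L,
                          size_select_min_bp = 160L, size_select_max_bp = 420L,
                          adapter_total_bp = 120L,
                          include_end_fragments = FALSE) {
  stopifnot(length(enzymes) >= 1, all(vapply(enzymes, inherits, TRUE, "rrbs_enzyme")))
  if (insilico_min_bp >= insilico_max_bp) {
    stop_config("`insilico_min_bp` must be < `insilico_max_bp`")
  }
  if (size_select_min_bp >= size_select_max_bp) {
    stop_config("`size_select_min_bp` must be < `size_select_max_bp`")
  }
  assert_scalar_number(adapter_total_bp, "adapter_total_bp", lower = 0)
  if (adapter_total_bp >= size_select_max_bp) {
    stop_config("`adapter_total_bp` must be smaller than `size_select_max_bp`")
  }
  structure(
    list(
      enzymes = enzymes,
      insilico_min_bp = as.integer(insilico_min_bp),
      insilico_max_bp = as.integer(insilico_max_bp),
      size_select_min_bp = as.integer(size_select_min_bp),
      size_select_max_bp = as.integer(size_select_max_bp),
      adapter_total_bp = as.integer(adapter_total_bp),
      include_end_fragments = isTRUE(include_end_fragments)
    ),
    class = "digest_config"
  )
}

#' Locate restriction cut sites on one sequence
#'
#' Finds every (possibly overlapping) occurrence of the enzyme's degenerate
#' recognition motif on the top strand and reports the 0-based coordinate of
#' the cut bond (`motif start + cut_offset`). Ambiguity codes in the motif
#' are expanded (`W = A/T`, ...); `N` in the subject sequence never matches.
#'
#' @param seq A [Biostrings::DNAString] or single character string.
#' @param enz An [enzyme()].
#' @return Sorted unique integer vector of 0-based cut positions.
#' @export
find_cut_sites <- function(seq, enz) {
  stopifnot(inherits(enz, "rrbs_enzyme"))
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  m <- Biostrings::matchPattern(
    enz$recognition, seq,
    fixed = c(pattern = FALSE, subject = TRUE)
  )
  sort(unique(Biostrings::start(m) - 1L + enz$cut_offset))
}

#' In-silico double-enzyme reduced-representation digest
#'
#' Merges the cut maps of all configured enzymes per chromosome, forms the
#' consecutive inter-cut fragments, labels each fragment with its bounding
#' enzymes and plus-strand CpG count, and keeps fragments whose length lies
#' in `[insilico_min_bp, insilico_max_bp]`. Chromosome-end fragments are
#' excluded unless `include_end_fragments` is set; cuts from different
#' enzymes at the same coordinate are deduplicated.
#'
#' @param genome A [Biostrings::DNAStringSet], `sim_genome`, or named
#'   character vector.
#' @param cfg A [digest_config()].
#' @return Tibble of fragments: `chrom`, `start`, `end` (0-based half-open),
#'   `left_enzyme`, `right_enzyme`, `length_bp`, `n_cpgs`.
#' @export
digest_genome <- function(genome, cfg = digest_config()) {
  stopifnot(inherits(cfg, "digest_config"))
  if (inherits(genome, "sim_genome")) genome <- genome$genome
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  out <- vector("list", length(genome))
  for (i in seq_along(genome)) {
    chrom <- names(genome)[i] %||% as.character(i)
    s <- genome[[i]]
    cuts <- tibble(pos = integer(), enzyme = character())
    for (e in cfg$enzymes) {
      p <- find_cut_sites(s, e)
      cuts <- bind_rows(cuts, tibble(pos = p, enzyme = e$name))
    }
    cuts <- cuts |>
      group_by(.data$pos) |>
      summarise(enzyme = paste(sort(unique(.data$enzyme)), collapse = "+")) |>
      arrange(.data$pos)
    L <- length(s)
    if (nrow(cuts) == 0) {
      bounds <- tibble(pos = integer(), enzyme = character())
    } else {
      bounds <- cuts
    }
    pos <- c(0L, bounds$pos, L)
    enzym <- c("chrom_end", bounds$enzyme, "chrom_end")
    if (length(pos) < 2) next
    frag <- tibble(
      chrom = chrom,
      start = pos[-length(pos)],
      end = pos[-1],
      left_enzyme = enzym[-length(enzym)],
      right_enzyme = enzym[-1]
    ) |>
      filter(.data$end > .data$start)
    if (!cfg$include_end_fragments) {
      frag <- filter(
        frag,
        .data$left_enzyme != "chrom_end", .data$right_enzyme != "chrom_end"
      )
    }
    frag <- frag |>
      mutate(length_bp = .data$end - .data$start) |>
      filter(
        .data$length_bp >= cfg$insilico_min_bp,
        .data$length_bp <= cfg$insilico_max_bp
      )
    cg0 <- Biostrings::start(Biostrings::matchPattern("CG", s)) - 1L
    frag$n_cpgs <- count_in_intervals(cg0, frag$start, frag$end - 1L)
    out[[i]] <- frag
  }
  bind_rows(out)
}

# Number of sorted positions p with lo <= p < hi, per interval.
count_in_intervals <- function(pos_sorted, lo, hi) {
  if (length(lo) == 0) return(integer())
  findInterval(hi - 1L, pos_sorted) - findInterval(lo - 1L, pos_sorted)
}

#' Model gel size selection of the sequencing library
#'
#' The excised gel slice bounds apply to adapter-ligated molecules; insert
#' (fragment) lengths therefore must lie in
#' `[max(1, size_select_min_bp - adapter_total_bp),
#'   size_select_max_bp - adapter_total_bp]`.
#'
#' @param frags Fragment tibble from [digest_genome()].
#' @param cfg A [digest_config()].
#' @return The retained subset of `frags` (always a subset of the input).
#' @export
size_select <- function(frags, cfg = digest_config()) {
  stopifnot(inherits(cfg, "digest_config"))
  lo <- max(1L, cfg$size_select_min_bp - cfg$adapter_total_bp)
  hi <- cfg$size_select_max_bp - cfg$adapter_total_bp
  filter(frags, .data$length_bp >= lo, .data$length_bp <= hi)
}

#' Summarise the CpG capture of a fragment set
#'
#' @param frags Fragment tibble.
#' @param genome The digested genome (for genome-wide CpG totals).
#' @return One-row tibble: `n_fragments`, `bp_captured`, `n_cpgs_captured`,
#'   `n_cpgs_genome`, `cpg_fraction` (plus-strand CG dinucleotides).
#' @export
capture_report <- function(frags, genome) {
  if (inherits(genome, "sim_genome")) genome <- genome$genome
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  total_cpgs <- sum(Biostrings::vcountPattern("CG", genome))
  tibble(
    n_fragments = nrow(frags),
    bp_captured = sum(frags$end - frags$start),
    n_cpgs_captured = sum(frags$n_cpgs),
    n_cpgs_genome = total_cpgs,
    cpg_fraction = if (total_cpgs > 0) sum(frags$n_cpgs) / total_cpgs else 0
  )
}
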