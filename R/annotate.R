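#' The mutually exclusive genomic categories and their default priority
#'
#' Every DMR is assigned exactly one category. When several feature tracks
#' overlap a DMR the earliest category in the priority wins; a DMR
#' overlapping nothing is `Intergenic`, and `NA` is reserved for DMRs on
#' chromosomes absent from every track. The default order keeps regulatory
#' categories dominant: TSS > TTS > 5'UTR > 3'UTR > CpG island > Exon >
#' Non-coding > Repeats > Intron > Intergenic.
#'
#' @return Character vector of category names in priority order.
#' @export
annotation_priority <- function() {
  c(
    "TSS", "TTS", "5UTR", "3UTR", "CpG island", "Exon",
    "Non-coding", "Repeats", "Intron", "Intergenic"
  )
}

#' Build annotation feature tracks from gene models, islands and repeats
#'
#' TSS and TTS tracks are strand-aware windows around the transcript ends:
#' `[TSS - tss_upstream, TSS + tss_downstream)` on the plus strand and the
#' mirrored interval on the minus strand (TTS analogous with its own,
#' reversed, defaults). The remaining tracks pass through the supplied
#' part/island/repeat intervals.
#'
#' @param features Feature tibble with `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `gene_id`, `category`; `category = "transcript"`
#'   rows define the TSS/TTS, remaining rows supply `Exon`, `Intron`,
#'   `5UTR`, `3UTR`, `Non-coding` and `Repeats` intervals (the layout
#'   produced by [simulate_genome()]).
#' @param islands CpG-island tibble (`chrom`, `start`, `end`), or `NULL`.
#' @param tss_upstream,tss_downstream Window around the transcription start
#'   site in bp (defaults 1000/100).
#' @param tts_upstream,tts_downstream Window around the transcription
#'   termination site in bp (defaults 100/1000).
#' @return Object of class `feature_tracks`: list with `tracks` (tibble
#'   `track`, `chrom`, `start`, `end`, `strand`, `gene_id`) and `tss`
#'   (tibble `gene_id`, `chrom`, `strand`, `tss`; 0-based TSS positions for
#'   nearest-gene lookup).
#' @export
build_tracks <- function(features, islands = NULL,
                         tss_upstream = 1000L, tss_downstream = 100L,
                         tts_upstream = 100L, tts_downstream = 1000L) {
  stopifnot(all(c("chrom", "start", "end", "strand", "gene_id", "category")
  %in% names(features)))
  if (any(features$end <= features$start)) {
    stop_data("feature intervals must satisfy end > start")
  }
  tx <- filter(features, .data$category == "transcript")
  plus <- tx$strand == "+"
  tss_pos <- ifelse(plus, tx$start, tx$end - 1L)
  tts_pos <- ifelse(plus, tx$end - 1L, tx$start)
  win <- function(center, up, down) {
    tibble(
      start = as.integer(pmax(0L, ifelse(plus, center - up, center - down))),
      end = as.integer(ifelse(plus, center + down, center + up) + 1L)
    )
  }
  tss_tbl <- bind_cols(
    tibble(track = "TSS", chrom = tx$chrom),
    win(tss_pos, tss_upstream, tss_downstream),
    tibble(strand = tx$strand, gene_id = tx$gene_id)
  )
  tts_tbl <- bind_cols(
    tibble(track = "TTS", chrom = tx$chrom),
    win(tts_pos, tts_upstream, tts_downstream),
    tibble(strand = tx$strand, gene_id = tx$gene_id)
  )
  parts <- features |>
    filter(.data$category %in% c("Exon", "Intron", "5UTR", "3UTR", "Non-coding", "Repeats")) |>
    transmute(
      track = .data$category, .data$chrom, .data$start, .data$end,
      .data$strand, .data$gene_id
    )
  isl <- if (!is.null(islands) && nrow(islands) > 0) {
    transmute(islands,
      track = "CpG island", .data$chrom, .data$start, .data$end,
      strand = "+", gene_id = NA_character_
    )
  } else {
    tss_tbl[0, ]
  }
  tracks <- bind_rows(tss_tbl, tts_tbl, parts, isl) |>
    arrange(.data$track, .data$chrom, .data$start)
  structure(
    list(
      tracks = tracks,
      tss = tibble(
        gene_id = tx$gene_id, chrom = tx$chrom,
        strand = tx$strand, tss = as.integer(tss_pos)
      )
    ),
    class = "feature_tracks"
  )
}

#' Assign each DMR one genomic category and its nearest gene
#'
#' The highest-priority category whose track overlaps the DMR by at least
#' one bp wins; DMRs overlapping no track on a known chromosome are
#' `Intergenic`; DMRs on chromosomes no track covers get `NA`. The nearest
#' gene is the transcript whose TSS is closest to the DMR midpoint
#' (ties broken by distance, then lexicographic gene id);
#' `distance_to_tss` is signed, positive downstream of the TSS.
#'
#' @param dmrs DMR tibble (or `dmr_calls`).
#' @param tracks A `feature_tracks` from [build_tracks()].
#' @param priority Permutation of [annotation_priority()].
#' @return `dmrs` with `category`, `nearest_gene`, `distance_to_tss` added.
#' @export
annotate_dmrs <- function(dmrs, tracks, priority = annotation_priority()) {
  if (inherits(dmrs, "dmr_calls")) dmrs <- dmrs$dmrs
  stopifnot(inherits(tracks, "feature_tracks"))
  if (!setequal(priority, annotation_priority())) {
    stop_config("`priority` must be a permutation of annotation_priority()")
  }
  n <- nrow(dmrs)
  category <- rep(NA_character_, n)
  if (n == 0) {
    return(mutate(dmrs,
      category = character(), nearest_gene = character(),
      distance_to_tss = integer()
    ))
  }
  known_chroms <- unique(c(tracks$tracks$chrom, tracks$tss$chrom))
  on_known <- dmrs$chrom %in% known_chroms
  category[on_known] <- "Intergenic"
  dmr_gr <- as_granges0(dmrs)
  overlap_tracks <- setdiff(priority, "Intergenic")
  for (tr in rev(overlap_tracks)) { # low priority first, high overwrites
    tt <- filter(tracks$tracks, .data$track == tr)
    if (nrow(tt) == 0) next
    # disjoint chromosome sets are a legitimate no-overlap case, not a warning
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(dmr_gr, as_granges0(tt))
    )
    category[unique(S4Vectors::queryHits(hits))] <- tr
  }

  nearest_gene <- rep(NA_character_, n)
  distance_to_tss <- rep(NA_integer_, n)
  tss <- tracks$tss
  if (nrow(tss) > 0) {
    mid <- (dmrs$start + dmrs$end) %/% 2L
    for (i in seq_len(n)) {
      cand <- tss[tss$chrom == dmrs$chrom[i], ]
      if (nrow(cand) == 0) next
      d_signed <- ifelse(cand$strand == "+", mid[i] - cand$tss, cand$tss - mid[i])
      ord <- order(abs(d_signed), cand$gene_id)
      nearest_gene[i] <- cand$gene_id[ord[1]]
      distance_to_tss[i] <- as.integer(d_signed[ord[1]])
    }
  }
  mutate(dmrs,
    category = category, nearest_gene = nearest_gene,
    distance_to_tss = distance_to_tss
  )
}

#' Category distribution of annotated DMRs
#'
#' @param annotated Tibble from [annotate_dmrs()] (column `category`), or
#'   any tibble with a category-like column named via `col`.
#' @param col Name of the category column.
#' @return Tibble `category`, `n`, `pct` (percent, 1 decimal); counts sum to
#'   the number of records.
#' @export
distribution_report <- function(annotated, col = "category") {
  stopifnot(nrow(annotated) > 0, col %in% names(annotated))
  annotated |>
    count(category = .data[[col]], name = "n") |>
    mutate(pct = round(100 * .data$n / sum(.data$n), 1)) |>
    arrange(desc(.data$n))
}
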