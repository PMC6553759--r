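# Independent brute-force oracles. These deliberately avoid the package's
# algorithms: the Mann-Whitney oracle enumerates subsets by bitmask and
# computes U by pairwise comparison counts (not rank sums); the digest
# oracle expands degenerate motifs to literal strings and scans by
# character comparison; interval oracles are O(n^2) loops.

# Exact two-sided Mann-Whitney p by enumeration of all C(n, nx) subsets.
oracle_mw_p <- function(x, y) {
  v <- c(x, y)
  nx <- length(x)
  n <- length(v)
  mu <- nx * (n - nx) / 2
  u_of <- function(sel) {
    xs <- v[sel]
    ys <- v[-sel]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(nx))
  sets <- utils::combn(n, nx)
  us <- apply(sets, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

iupac_expand <- function(motif) {
  map <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
    D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
    N = c("A", "C", "G", "T")
  )
  parts <- map[strsplit(motif, "")[[1]]]
  apply(expand.grid(parts, stringsAsFactors = FALSE), 1, paste, collapse = "")
}

# All (overlapping) 0-based cut positions of one enzyme on a sequence.
oracle_cut_sites <- function(seq_str, motif, offset) {
  s <- strsplit(seq_str, "")[[1]]
  L <- length(s)
  cuts <- integer()
  for (lit in iupac_expand(motif)) {
    l <- strsplit(lit, "")[[1]]
    m <- length(l)
    if (L < m) next
    ok <- rep(TRUE, L - m + 1)
    for (j in seq_len(m)) {
      ok <- ok & s[seq_len(L - m + 1) + j - 1] == l[j]
    }
    cuts <- c(cuts, which(ok) - 1L + offset)
  }
  sort(unique(cuts))
}

# Internally bounded fragments between merged cut positions, length-filtered.
oracle_fragments <- function(seq_str, enzymes, min_bp, max_bp) {
  cuts <- sort(unique(unlist(lapply(
    enzymes, function(e) oracle_cut_sites(seq_str, e$recognition, e$cut_offset)
  ))))
  if (length(cuts) < 2) {
    return(data.frame(start = integer(), end = integer()))
  }
  start <- cuts[-length(cuts)]
  end <- cuts[-1]
  keep <- (end - start) >= min_bp & (end - start) <= max_bp
  data.frame(start = start[keep], end = end[keep])
}

# All-pairs reversed-overlap oracle.
oracle_reversed_pairs <- function(a, b, min_ov = 1L) {
  out <- list()
  k <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov >= min_ov && a$direction[i] != b$direction[j]) {
        k <- k + 1L
        out[[k]] <- data.frame(
          a_start = a$start[i], a_end = a$end[i],
          b_start = b$start[j], b_end = b$end[j]
        )
      }
    }
  }
  if (k == 0L) {
    return(data.frame(
      a_start = integer(), a_end = integer(),
      b_start = integer(), b_end = integer()
    ))
  }
  res <- do.call(rbind, out)
  res[order(res$a_start, res$a_end, res$b_start, res$b_end), , drop = FALSE]
}

# Per-category overlap check followed by priority selection.
oracle_annotate_category <- function(dmr, track_tbl, priority) {
  if (!dmr$chrom %in% track_tbl$chrom) {
    return(NA_character_)
  }
  for (cat in setdiff(priority, "Intergenic")) {
    tt <- track_tbl[track_tbl$track == cat & track_tbl$chrom == dmr$chrom, ]
    if (nrow(tt) == 0) next
    hit <- any(pmin(tt$end, dmr$end) - pmax(tt$start, dmr$start) >= 1)
    if (hit) {
      return(cat)
    }
  }
  "Intergenic"
}
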