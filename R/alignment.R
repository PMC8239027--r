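# Minimizer-anchor alignment ---------------------------------------------

#' Alignment parameters
#'
#' Defaults resolve simulated 100 kb-scale contigs: `k = 15`, `window = 10`
#' (minimizer sampling), anchors occurring more than `max_occ` times are
#' dropped as repetitive, chains may jump at most `gap_limit` bp per axis,
#' chains scoring below `min_block_len` matched bases are discarded, and
#' blocks whose base/alternate interval lengths differ by more than a factor
#' `max_indel_ratio` are dropped.
#'
#' @param k k-mer size (11..31).
#' @param window minimizer window (>= 1; 1 keeps every k-mer).
#' @param max_occ repetitive k-mer occurrence cutoff.
#' @param gap_limit maximum per-axis gap between chained anchors (bp).
#' @param diag_limit maximum diagonal drift `|dx - dy|` per chain link (bp);
#'   keeps a stray one-off match from bridging a rearrangement.
#' @param diag_penalty score cost per bp of off-diagonal drift in a chain
#'   link; steers chains onto the flanks' diagonal inside tandem repeats.
#' @param min_block_len minimum chain score (summed matched bp) per block.
#' @param max_indel_ratio maximum base/alt interval length ratio.
#' @param max_lookback chaining DP lookback (anchors).
#' @param stray_gap,min_end_score a chain-end segment separated from the
#'   chain body by more than `stray_gap` bp per axis must carry at least
#'   `min_end_score` matched bases, else it is trimmed as a coincidental
#'   k-mer hit.
#' @return a named list of parameters.
#' @export
align_params <- function(k = 15L, window = 10L, max_occ = 50L,
                         gap_limit = 10000, diag_limit = 2000,
                         min_block_len = 500,
                         max_indel_ratio = 1.25, max_lookback = 64L,
                         stray_gap = 2500, min_end_score = 100,
                         diag_penalty = 0.01) {
  stopifnot(k >= 11, k <= 31, window >= 1)
  list(k = as.integer(k), window = as.integer(window),
       max_occ = as.integer(max_occ), gap_limit = gap_limit,
       diag_limit = diag_limit, diag_penalty = diag_penalty,
       min_block_len = min_block_len,
       max_indel_ratio = max_indel_ratio,
       max_lookback = as.integer(max_lookback),
       stray_gap = stray_gap, min_end_score = min_end_score)
}

# drop weak chain-end segments: a chain end separated from the body by a
# per-axis gap over `stray_gap` must itself carry at least `min_end_score`
# matched bases, else it is a coincidental on-diagonal k-mer hit that would
# extend the block across a rearrangement boundary
trim_chain_ends <- function(a, k, stray_gap, min_end_score) {
  repeat {
    n <- nrow(a)
    if (n < 2) return(a)
    g <- pmax(diff(a$base_pos), diff(a$y))
    big <- which(g > stray_gap)
    if (length(big) == 0) return(a)
    lead <- seq_len(big[1])
    if (chain_score(a$base_pos[lead], a$y[lead], k) < min_end_score) {
      a <- a[-lead, , drop = FALSE]
      next
    }
    tail_idx <- (big[length(big)] + 1L):n
    if (chain_score(a$base_pos[tail_idx], a$y[tail_idx], k) < min_end_score) {
      a <- a[-tail_idx, , drop = FALSE]
      next
    }
    return(a)
  }
}

#' Minimizer sketch of one sequence
#'
#' Returns the sampled k-mer start positions (0-based) with the canonical
#' strand flag (0 = forward, 1 = reverse) and, for k <= 26, the canonical
#' packed k-mer value.
#'
#' @param seq a DNA string.
#' @inheritParams align_params
#' @return a tibble (`pos`, `flag`, `key`).
#' @export
sketch_minimizers <- function(seq, k = 15L, window = 10L) {
  stopifnot(k >= 4, k <= 31, window >= 1)
  tibble::as_tibble(cpp_sketch(toupper(seq), as.integer(k),
                               as.integer(window)))
}

#' Collect exact minimizer anchors between a base and an alternate assembly
#'
#' @param base,alt assemblies (`asm_set` or coercible).
#' @param params see [align_params()].
#' @return a tibble (`base_id`, `alt_id`, `base_pos`, `alt_fwd`, `strand`,
#'   `y`) where `alt_fwd` is the forward-strand alternate position of the
#'   matched k-mer and `y` the strand-transformed alternate coordinate used
#'   for chaining (`alt_len - alt_fwd - k` on `-`).
#' @export
find_anchors <- function(base, alt, params = align_params()) {
  base <- as_assembly(base); alt <- as_assembly(alt)
  alt_lens <- seq_lengths(alt)
  if (all(alt_lens < params$k)) stop("k is larger than every alternate contig")
  idx <- cpp_build_index(as.list(unclass(alt)), params$k, params$window,
                         params$max_occ)
  res <- lapply(seq_along(base), function(i) {
    df <- cpp_query_anchors(idx, unclass(base)[[i]])
    if (nrow(df) == 0) return(NULL)
    alt_id <- names(alt)[df$contig]
    y <- ifelse(df$strand > 0, df$alt_pos,
                unname(alt_lens[df$contig]) - df$alt_pos - params$k)
    tibble::tibble(base_id = names(base)[i], alt_id = alt_id,
                   base_pos = df$base_pos, alt_fwd = df$alt_pos,
                   strand = ifelse(df$strand > 0, "+", "-"), y = y)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble::tibble(base_id = character(), alt_id = character(),
                          base_pos = integer(), alt_fwd = integer(),
                          strand = character(), y = numeric())
  }
  out
}

#' Chain collinear anchors
#'
#' Sparse dynamic programming over anchors sharing one (base scaffold,
#' alternate contig, strand) triple: successive anchors must strictly advance
#' on both coordinates with a per-axis gap of at most `gap_limit`; appending
#' an anchor scores `min(k, dx, dy)` matched bases. Chains are peeled
#' best-first.
#'
#' @param anchors tibble with columns `base_pos` and `y` (strand-transformed
#'   alternate coordinate), one (scaffold, contig, strand) group.
#' @param k anchor length (bp).
#' @inheritParams align_params
#' @return the input tibble with a `chain` id column, ordered by `base_pos`,
#'   plus a `"scores"` attribute (score per chain id).
#' @export
chain_anchors <- function(anchors, k, gap_limit = 10000, diag_limit = 2000,
                          diag_penalty = 0.01, max_lookback = 64L) {
  if (nrow(anchors) == 0) {
    attr(anchors, "scores") <- numeric(0)
    anchors$chain <- integer(0)
    return(anchors)
  }
  ord <- order(anchors$base_pos, anchors$y)
  anchors <- anchors[ord, , drop = FALSE]
  res <- cpp_chain(as.integer(anchors$base_pos), as.integer(anchors$y),
                   as.integer(k), gap_limit, diag_limit, diag_penalty,
                   as.integer(max_lookback))
  anchors$chain <- res$chain
  attr(anchors, "scores") <- res$score
  anchors
}

chain_score <- function(base_pos, y, k) {
  if (length(base_pos) == 0) return(0)
  o <- order(base_pos, y)
  dx <- diff(base_pos[o]); dy <- diff(y[o])
  k + sum(pmin(k, pmin(dx, dy)))
}

#' Align two assemblies into strand-aware blocks
#'
#' Minimizer anchors between each base scaffold and the alternate contigs are
#' chained per (contig, strand); chains become alignment blocks spanning
#' their first to last anchor. Blocks overlapping on the base are resolved by
#' keeping the higher-score block and trimming the other to its non-overlapping
#' anchors (ties: longer block, then lexicographically smaller `alt_id`).
#'
#' @inheritParams find_anchors
#' @param alt_name label recorded in the `alt_assembly_name` column.
#' @return a tibble of blocks sorted by (`base_id`, `base_start`): columns
#'   `base_id`, `base_start`, `base_end`, `alt_assembly_name`, `alt_id`,
#'   `alt_start`, `alt_end`, `strand`, `n_anchors`, `score`, `base_len`,
#'   `alt_len`, and a list-column `anchors` (tibbles of `base_pos`,
#'   `alt_fwd`, `y`).
#' @export
align_assemblies <- function(base, alt, params = align_params(),
                             alt_name = "alt") {
  base <- as_assembly(base); alt <- as_assembly(alt)
  anc <- find_anchors(base, alt, params)
  base_lens <- seq_lengths(base); alt_lens <- seq_lengths(alt)
  blocks <- list()
  grp <- split(anc, list(anc$base_id, anc$alt_id, anc$strand), drop = TRUE)
  for (g in grp) {
    ch <- chain_anchors(g, params$k, params$gap_limit, params$diag_limit,
                        params$diag_penalty, params$max_lookback)
    scores <- attr(ch, "scores")
    for (ci in which(scores >= params$min_block_len)) {
      a <- ch[ch$chain == ci, , drop = FALSE]
      a <- a[order(a$base_pos), , drop = FALSE]
      a <- trim_chain_ends(a, params$k, params$stray_gap,
                           params$min_end_score)
      if (nrow(a) == 0) next
      sc <- chain_score(a$base_pos, a$y, params$k)
      if (sc < params$min_block_len) next
      bs <- min(a$base_pos); be <- max(a$base_pos) + params$k
      as_ <- min(a$alt_fwd); ae <- max(a$alt_fwd) + params$k
      blocks[[length(blocks) + 1L]] <- tibble::tibble(
        base_id = a$base_id[1], base_start = bs, base_end = be,
        alt_assembly_name = alt_name, alt_id = a$alt_id[1],
        alt_start = as_, alt_end = ae, strand = a$strand[1],
        n_anchors = nrow(a), score = sc,
        base_len = unname(base_lens[a$base_id[1]]),
        alt_len = unname(alt_lens[a$alt_id[1]]),
        anchors = list(a[order(a$base_pos),
                         c("base_pos", "alt_fwd", "y")]))
    }
  }
  if (length(blocks) == 0) return(empty_blocks())
  bl <- dplyr::bind_rows(blocks)
  # drop blocks whose interval lengths disagree beyond max_indel_ratio
  rat <- pmax(bl$base_end - bl$base_start, bl$alt_end - bl$alt_start) /
    pmin(bl$base_end - bl$base_start, bl$alt_end - bl$alt_start)
  bl <- bl[rat <= params$max_indel_ratio, , drop = FALSE]
  bl <- dplyr::bind_rows(lapply(split(bl, bl$base_id), resolve_overlaps,
                                params = params))
  if (nrow(bl) == 0) return(empty_blocks())
  dplyr::arrange(bl, .data$base_id, .data$base_start, .data$alt_id)
}

empty_blocks <- function() {
  tibble::tibble(base_id = character(), base_start = numeric(),
                 base_end = numeric(), alt_assembly_name = character(),
                 alt_id = character(), alt_start = numeric(),
                 alt_end = numeric(), strand = character(),
                 n_anchors = integer(), score = numeric(),
                 base_len = numeric(), alt_len = numeric(),
                 anchors = list())
}

# keep higher-score blocks and trim lower-score ones to anchors outside the
# already-kept base intervals
resolve_overlaps <- function(bl, params) {
  k <- params$k
  ord <- order(-bl$score, -(bl$base_end - bl$base_start), bl$alt_id,
               bl$base_start)
  bl <- bl[ord, , drop = FALSE]
  kept <- list()
  ks <- numeric(0); ke <- numeric(0)
  for (i in seq_len(nrow(bl))) {
    b <- bl[i, ]
    if (length(ks) > 0 && any(b$base_start < ke & b$base_end > ks)) {
      a <- b$anchors[[1]]
      ov <- vapply(a$base_pos, function(p)
        any(p < ke & (p + k) > ks), logical(1))
      a <- a[!ov, , drop = FALSE]
      if (nrow(a) == 0) next
      sc <- chain_score(a$base_pos, a$y, k)
      if (sc < params$min_block_len) next
      b$base_start <- min(a$base_pos); b$base_end <- max(a$base_pos) + k
      b$alt_start <- min(a$alt_fwd); b$alt_end <- max(a$alt_fwd) + k
      b$n_anchors <- nrow(a); b$score <- sc
      b$anchors <- list(a)
      if (any(b$base_start < ke & b$base_end > ks)) {
        # residual < k bp overlap at anchor edges is tolerated only if the
        # trimmed block still clears every kept interval by anchor extent
        if (any(pmin(b$base_end, ke) - pmax(b$base_start, ks) >= k)) next
      }
    }
    ks <- c(ks, b$base_start); ke <- c(ke, b$base_end)
    kept[[length(kept) + 1L]] <- b
  }
  dplyr::bind_rows(kept)
}

#' Dot-plot table of alignment blocks
#'
#' One row per block, suitable for automated discrepancy inspection or
#' whole-genome dot-plot rendering.
#'
#' @param blocks a block tibble from [align_assemblies()] or [read_paf()].
#' @return a tibble (`base_id`, `base_start`, `base_end`, `alt_id`,
#'   `alt_start`, `alt_end`, `strand`).
#' @export
dotplot_table <- function(blocks) {
  blocks[, c("base_id", "base_start", "base_end", "alt_id", "alt_start",
             "alt_end", "strand")]
}

#' Write a dot-plot TSV
#'
#' @inheritParams dotplot_table
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dotplot <- function(blocks, path) {
  utils::write.table(dotplot_table(blocks), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Dot plot of alignment blocks
#'
#' @param blocks a block tibble.
#' @return a ggplot: base coordinates on x, alternate on y, faceted by
#'   scaffold/contig, minus-strand blocks drawn as falling segments.
#' @export
plot_dotplot <- function(blocks) {
  df <- dotplot_table(blocks)
  df$y1 <- ifelse(df$strand == "+", df$alt_start, df$alt_end)
  df$y2 <- ifelse(df$strand == "+", df$alt_end, df$alt_start)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$base_start, xend = .data$base_end,
      y = .data$y1, yend = .data$y2, colour = .data$strand)) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$alt_id),
                        cols = ggplot2::vars(.data$base_id),
                        scales = "free") +
    ggplot2::labs(x = "base (bp)", y = "alternate (bp)") +
    ggplot2::theme_minimal()
}
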