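#' Locate N-gap tracts
#'
#' Finds every maximal run of `N` of length at least `min_gap_len` in each
#' scaffold. Coordinates are 0-based half-open.
#'
#' @param assembly an `asm_set` (or coercible).
#' @param min_gap_len minimum tract length to report (default 1; NCBI-style
#'   counting uses 10).
#' @return a tibble with columns `scaffold_id`, `start`, `end`, `length`,
#'   sorted by scaffold then start.
#' @export
find_gaps <- function(assembly, min_gap_len = 1L) {
  assembly <- as_assembly(assembly)
  stopifnot(min_gap_len >= 1)
  res <- purrr::map2(names(assembly), unclass(assembly), function(id, s) {
    m <- gregexpr("N+", s, perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    len <- attr(m, "match.length")
    keep <- len >= min_gap_len
    if (!any(keep)) return(NULL)
    tibble::tibble(scaffold_id = id, start = as.integer(m[keep]) - 1L,
                   end = as.integer(m[keep]) - 1L + len[keep],
                   length = len[keep])
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble::tibble(scaffold_id = character(), start = integer(),
                          end = integer(), length = integer())
  }
  dplyr::arrange(out, .data$scaffold_id, .data$start)
}

#' Split scaffolds into contigs at gap tracts
#'
#' Each scaffold is cut at every N tract of length at least `min_split_gap`.
#' Contigs inherit derived IDs `scaffold.1`, `scaffold.2`, ... in coordinate
#' order; zero-length pieces are dropped and all-N scaffolds emit nothing
#' (with a warning).
#'
#' @inheritParams find_gaps
#' @param min_split_gap minimum N-run length that splits (default 1).
#' @return an `asm_set` of contigs.
#' @export
split_into_contigs <- function(assembly, min_split_gap = 1L) {
  assembly <- as_assembly(assembly)
  stopifnot(min_split_gap >= 1)
  gaps <- find_gaps(assembly, min_gap_len = min_split_gap)
  out <- character(0)
  for (i in seq_along(assembly)) {
    id <- names(assembly)[i]
    s <- assembly[[i]]
    g <- gaps[gaps$scaffold_id == id, , drop = FALSE]
    cuts_start <- c(0L, g$end)
    cuts_end <- c(g$start, nchar(s))
    keep <- cuts_end > cuts_start
    if (!any(keep)) {
      warning("scaffold ", id, " is all N; no contigs emitted")
      next
    }
    pieces <- substring(s, cuts_start[keep] + 1L, cuts_end[keep])
    names(pieces) <- paste0(id, ".", seq_along(pieces))
    out <- c(out, pieces)
  }
  if (length(out) == 0) stop("no contigs left after splitting")
  as_assembly(out)
}

#' NX curve of a length set
#'
#' NX is the length of the shortest sequence in the minimal set of longest
#' sequences whose summed length covers at least X percent of the total
#' (ceiling convention: the sequence that reaches the boundary is included).
#'
#' @param lengths integer vector of sequence lengths.
#' @param X percentages (default 1..100).
#' @return a tibble with columns `X` and `length_bp`.
#' @export
nx_curve <- function(lengths, X = 1:100) {
  stopifnot(length(lengths) > 0, all(lengths > 0))
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  cs <- cumsum(s)
  thr <- X / 100 * cs[length(cs)]
  idx <- findInterval(thr, cs, left.open = TRUE) + 1L
  idx <- pmin(idx, length(s))
  tibble::tibble(X = as.integer(X), length_bp = s[idx])
}

#' Contiguity statistics of an assembly
#'
#' Computes sequence counts, total/max length, the N50 and the full NX curve,
#' gap-tract counts, the number and summed fraction of sequences longer than
#' 10 Mb, and the contig N50 after splitting scaffolds at N tracts.
#'
#' @inheritParams find_gaps
#' @param min_split_gap N-run length at which contigs are split for the
#'   contig N50 (default 1).
#' @return an object of class `asm_stats`; see [glance.asm_stats()] and
#'   [tidy.asm_stats()].
#' @export
compute_stats <- function(assembly, min_gap_len = 1L, min_split_gap = 1L) {
  assembly <- as_assembly(assembly)
  lens <- as.numeric(seq_lengths(assembly))
  gaps <- find_gaps(assembly, min_gap_len = min_gap_len)
  nx <- nx_curve(lens)
  over <- lens > 1e7
  contig_lens <- if (nrow(gaps) > 0) {
    as.numeric(seq_lengths(suppressWarnings(
      split_into_contigs(assembly, min_split_gap = min_split_gap))))
  } else lens
  structure(list(
    n_sequences = length(lens),
    total_length = sum(lens),
    max_length = max(lens),
    n50 = nx$length_bp[nx$X == 50],
    nx_curve = nx,
    n_gaps = nrow(gaps),
    gap_total_length = sum(gaps$length),
    n_over_10mb = sum(over),
    fraction_over_10mb = 100 * sum(lens[over]) / sum(lens),
    contig_n50 = nx_curve(contig_lens, X = 50)$length_bp
  ), class = "asm_stats")
}

#' @export
print.asm_stats <- function(x, ...) {
  cat("<asm_stats>\n")
  print(glance(x))
  invisible(x)
}

#' One-row summary of assembly statistics
#'
#' @param x an `asm_stats` object.
#' @param ... unused.
#' @return a one-row tibble.
#' @export
glance.asm_stats <- function(x, ...) {
  tibble::tibble(
    n_sequences = x$n_sequences, total_length = x$total_length,
    max_length = x$max_length, n50 = x$n50, contig_n50 = x$contig_n50,
    n_gaps = x$n_gaps, gap_total_length = x$gap_total_length,
    n_over_10mb = x$n_over_10mb, fraction_over_10mb = x$fraction_over_10mb
  )
}

#' NX curve of an `asm_stats` object as a tibble
#'
#' @inheritParams glance.asm_stats
#' @return the NX curve tibble (columns `X`, `length_bp`).
#' @export
tidy.asm_stats <- function(x, ...) x$nx_curve

#' Plot an NX contiguity curve
#'
#' @param object an `asm_stats` object.
#' @param ... further `asm_stats` objects to overlay, named.
#' @return a ggplot.
#' @export
autoplot.asm_stats <- function(object, ...) {
  extra <- list(...)
  curves <- c(list(assembly = object), extra)
  df <- dplyr::bind_rows(
    purrr::imap(curves, ~ dplyr::mutate(tidy(.x), assembly = .y)))
  ggplot2::ggplot(df, ggplot2::aes(.data$X, .data$length_bp,
                                   colour = .data$assembly)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "X (%)", y = "N(X) length (bp)") +
    ggplot2::theme_minimal()
}

#' Write assembly statistics to TSV or JSON
#'
#' The TSV holds the one-row summary; `<path>.nx.tsv` holds the NX curve
#' (columns `X`, `length_bp`) for N(X)-style contiguity plots.
#'
#' @param x an `asm_stats` object.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_stats <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      c(as.list(glance(x)), list(nx_curve = x$nx_curve)),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(glance(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(x$nx_curve, paste0(path, ".nx.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
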