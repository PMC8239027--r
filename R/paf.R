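# PAF import/export -------------------------------------------------------

#' Read alignment blocks from PAF
#'
#' The 12 mandatory PAF columns are mapped with the query as the alternate
#' assembly and the target as the base assembly. Records below `min_mapq`
#' are skipped. PAF blocks carry no anchor lists; downstream edits snap to
#' block edges instead of anchor positions.
#'
#' @param path PAF file.
#' @param min_mapq minimum mapping quality to keep (default 0).
#' @param alt_name label recorded in `alt_assembly_name`.
#' @return a block tibble (see [align_assemblies()]), plus columns
#'   `n_match`, `aln_len` and `mapq` preserved for round-tripping.
#' @export
read_paf <- function(path, min_mapq = 0L, alt_name = "alt") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_paf_blocks())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12)) {
    stop("malformed PAF (fewer than 12 columns) at line ", which(nf < 12)[1])
  }
  m <- t(vapply(fields, function(f) f[1:12], character(12)))
  num <- function(j) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) stop("malformed PAF numeric field at line ",
                       which(is.na(v))[1])
    v
  }
  out <- tibble::tibble(
    base_id = m[, 6], base_start = num(8), base_end = num(9),
    alt_assembly_name = alt_name, alt_id = m[, 1],
    alt_start = num(3), alt_end = num(4), strand = m[, 5],
    n_anchors = NA_integer_, score = num(10),
    base_len = num(7), alt_len = num(2),
    n_match = num(10), aln_len = num(11), mapq = num(12),
    anchors = vector("list", length(lines)))
  if (!all(out$strand %in% c("+", "-"))) {
    stop("malformed PAF strand at line ",
         which(!out$strand %in% c("+", "-"))[1])
  }
  out <- out[out$mapq >= min_mapq, , drop = FALSE]
  dplyr::arrange(out, .data$base_id, .data$base_start)
}

empty_paf_blocks <- function() {
  dplyr::mutate(empty_blocks(), n_match = numeric(0), aln_len = numeric(0),
                mapq = numeric(0))
}

#' Write alignment blocks as PAF
#'
#' Emits the 12 mandatory columns (query = alternate, target = base);
#' `write_paf(read_paf(f))` reproduces `f` field-for-field.
#'
#' @param blocks a block tibble; `base_len`/`alt_len` columns are required.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_paf <- function(blocks, path) {
  fmt_int <- function(x) format(x, scientific = FALSE, trim = TRUE)
  n_match <- if ("n_match" %in% names(blocks)) blocks$n_match else
    round(blocks$score)
  aln_len <- if ("aln_len" %in% names(blocks)) blocks$aln_len else
    pmax(blocks$base_end - blocks$base_start,
         blocks$alt_end - blocks$alt_start)
  mapq <- if ("mapq" %in% names(blocks)) blocks$mapq else
    rep(60, nrow(blocks))
  lines <- paste(blocks$alt_id, fmt_int(blocks$alt_len),
                 fmt_int(blocks$alt_start), fmt_int(blocks$alt_end),
                 blocks$strand, blocks$base_id, fmt_int(blocks$base_len),
                 fmt_int(blocks$base_start), fmt_int(blocks$base_end),
                 fmt_int(n_match), fmt_int(aln_len), fmt_int(mapq),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
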