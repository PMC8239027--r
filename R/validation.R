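# BAC-end pair concordance ------------------------------------------------

#' Read paired alignments from the 9-column TSV dialect
#'
#' Columns: `pair_id, id1, pos1, strand1, mapq1, id2, pos2, strand2, mapq2`.
#' An unmapped end has `id = "*"` (or empty) and NA position. Positions are
#' 0-based leftmost-mapped bases.
#'
#' @param path TSV file (with header).
#' @return a pair tibble.
#' @export
read_pairs_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("pair_id", "id1", "pos1", "strand1", "mapq1", "id2", "pos2",
            "strand2", "mapq2")
  if (!all(need %in% names(df))) {
    stop("pair TSV must have columns: ", paste(need, collapse = ", "))
  }
  df <- tibble::as_tibble(df[, need])
  for (col in c("id1", "id2")) df[[col]][df[[col]] %in% "*"] <- NA_character_
  df
}

#' Write a pair tibble as the 9-column TSV dialect
#'
#' @param pairs a pair tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(pairs, path) {
  out <- pairs
  for (col in c("id1", "id2")) out[[col]][is.na(out[[col]])] <- "*"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read primary paired alignments from SAM/BAM
#'
#' Secondary and supplementary records are ignored; each pair must resolve to
#' at most one primary alignment per end. SAM input is converted on the fly.
#'
#' @param path SAM or BAM file.
#' @return a pair tibble as in [read_pairs_tsv()].
#' @export
read_pairs_sam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(
    flag = flag, what = c("qname", "flag", "rname", "pos", "strand", "mapq"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  df <- tibble::tibble(
    qname = b$qname, flag = b$flag, rname = as.character(b$rname),
    pos = as.integer(b$pos) - 1L, strand = as.character(b$strand),
    mapq = as.integer(b$mapq))
  first <- bitwAnd(df$flag, 64L) > 0
  single <- !(bitwAnd(df$flag, 1L) > 0)
  df$end <- ifelse(single | first, 1L, 2L)
  df$unmapped <- bitwAnd(df$flag, 4L) > 0
  df$rname[df$unmapped] <- NA_character_
  df$pos[df$unmapped] <- NA_integer_
  df$strand[df$unmapped] <- NA_character_
  keyed <- paste(df$qname, df$end)
  if (anyDuplicated(keyed)) {
    stop("duplicate primary alignment for pair/end: ",
         keyed[duplicated(keyed)][1])
  }
  e1 <- df[df$end == 1L, ]; e2 <- df[df$end == 2L, ]
  out <- dplyr::full_join(
    dplyr::rename(e1[, c("qname", "rname", "pos", "strand", "mapq")],
                  id1 = "rname", pos1 = "pos", strand1 = "strand",
                  mapq1 = "mapq"),
    dplyr::rename(e2[, c("qname", "rname", "pos", "strand", "mapq")],
                  id2 = "rname", pos2 = "pos", strand2 = "strand",
                  mapq2 = "mapq"),
    by = "qname")
  dplyr::rename(out, pair_id = "qname")
}

#' Classify paired (BAC-end) alignments
#'
#' A pair is `concordant` iff both ends are mapped with mapping quality at
#' least `min_mapq`, on the same scaffold, on opposite strands facing inward
#' (forward-reverse), with outer insert size within `[min_insert,
#' max_insert]`. Pairs failing any condition with both ends mapped are
#' `discordant` (with a reason); otherwise `single_end` or `unaligned`.
#'
#' @param pairs a pair tibble (see [read_pairs_tsv()]).
#' @param min_insert,max_insert outer insert-size bounds in bp (defaults
#'   20 kb and 300 kb bracket the ~100-200 kb BAC insert distribution).
#' @param min_mapq minimum mapping quality per end.
#' @param read_length read length in bp used for the outer insert
#'   (rightmost start + read length - leftmost start).
#' @return a tibble (`pair_id`, `verdict`, `insert_size`, `reason`).
#' @export
classify_pairs <- function(pairs, min_insert = 20000, max_insert = 300000,
                           min_mapq = 0L, read_length = 500L) {
  stopifnot(min_insert < max_insert)
  if (anyDuplicated(pairs$pair_id)) {
    dup <- pairs$pair_id[duplicated(pairs$pair_id)][1]
    conf <- pairs[pairs$pair_id == dup, ]
    if (nrow(unique(conf)) > 1) {
      stop("duplicate pair_id with conflicting records: ", dup)
    }
    pairs <- dplyr::distinct(pairs)
  }
  m1 <- !is.na(pairs$id1) & !is.na(pairs$pos1) & pairs$mapq1 >= min_mapq
  m2 <- !is.na(pairs$id2) & !is.na(pairs$pos2) & pairs$mapq2 >= min_mapq
  n <- nrow(pairs)
  verdict <- rep("unaligned", n)
  reason <- rep(NA_character_, n)
  insert <- rep(NA_real_, n)
  verdict[xor(m1, m2)] <- "single_end"
  both <- m1 & m2
  same <- both & pairs$id1 == pairs$id2
  verdict[both & !same] <- "discordant"
  reason[both & !same] <- "different_scaffold"
  if (any(same)) {
    left_is_1 <- pairs$pos1[same] <= pairs$pos2[same]
    lpos <- ifelse(left_is_1, pairs$pos1[same], pairs$pos2[same])
    rpos <- ifelse(left_is_1, pairs$pos2[same], pairs$pos1[same])
    lstr <- ifelse(left_is_1, pairs$strand1[same], pairs$strand2[same])
    rstr <- ifelse(left_is_1, pairs$strand2[same], pairs$strand1[same])
    ins <- rpos + read_length - lpos
    insert[same] <- ins
    fr <- lstr == "+" & rstr == "-"
    in_range <- ins >= min_insert & ins <= max_insert
    v <- ifelse(!fr, "discordant", ifelse(!in_range, "discordant",
                                          "concordant"))
    r <- ifelse(!fr, "same_strand", ifelse(!in_range, "insert_out_of_range",
                                           "ok"))
    verdict[same] <- v
    reason[same] <- r
  }
  tibble::tibble(pair_id = pairs$pair_id, verdict = verdict,
                 insert_size = insert, reason = reason)
}

#' Compare pair concordance between two assemblies
#'
#' Both class tibbles must cover the same set of pair IDs. Deltas are B minus
#' A, mirroring a before/after reconciliation comparison.
#'
#' @param classes_a,classes_b outputs of [classify_pairs()] against assembly
#'   A and assembly B.
#' @return a list with `counts` (per-verdict `n_a`, `n_b`, `delta`) and
#'   `changed` (pairs whose verdict changed, with both verdicts and reasons).
#' @export
compare_assemblies <- function(classes_a, classes_b) {
  if (!setequal(classes_a$pair_id, classes_b$pair_id) ||
      nrow(classes_a) != nrow(classes_b)) {
    only <- c(setdiff(classes_a$pair_id, classes_b$pair_id),
              setdiff(classes_b$pair_id, classes_a$pair_id))
    stop("pair universes differ between the two class lists: ",
         paste(utils::head(only, 3), collapse = ", "))
  }
  j <- dplyr::inner_join(classes_a, classes_b, by = "pair_id",
                         suffix = c("_a", "_b"))
  lv <- c("concordant", "discordant", "single_end", "unaligned")
  counts <- tibble::tibble(
    verdict = lv,
    n_a = vapply(lv, function(v) sum(j$verdict_a == v), integer(1),
                 USE.NAMES = FALSE),
    n_b = vapply(lv, function(v) sum(j$verdict_b == v), integer(1),
                 USE.NAMES = FALSE))
  counts$delta <- counts$n_b - counts$n_a
  changed <- j[j$verdict_a != j$verdict_b,
               c("pair_id", "verdict_a", "reason_a", "verdict_b", "reason_b")]
  list(counts = counts, changed = tibble::as_tibble(changed))
}

#' Write a concordance delta report
#'
#' @param cmp output of [compare_assemblies()].
#' @param path output path; `.json` writes JSON, anything else TSV (the
#'   changed-pairs list goes to `<path>.changed.tsv`).
#' @return `path`, invisibly.
#' @export
write_compare <- function(cmp, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(cmp, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(cmp$counts, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(cmp$changed, paste0(path, ".changed.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
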