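# Component plans ---------------------------------------------------------
#
# A "plan" describes every output scaffold as an ordered list of components:
# W components (an interval of a named source assembly, possibly reverse
# complemented) and N components (a gap of known length). Plans are how edits
# (block replacements, gap fills, merges) are applied, how the hybrid FASTA is
# spliced together, how AGP provenance is written, and how truth liftovers are
# composed. Coordinates are 0-based half-open; for N components the length is
# src_end with src_start = 0 and source NA.

plan_identity <- function(assembly, source = "base") {
  assembly <- as_assembly(assembly)
  tibble::tibble(
    out_id = names(assembly), part = 1L, type = "W", source = source,
    source_id = names(assembly), src_start = 0L,
    src_end = unname(nchar(unclass(assembly))), strand = "+")
}

plan_comp_lengths <- function(plan) plan$src_end - plan$src_start

plan_lengths <- function(plan) {
  lens <- plan_comp_lengths(plan)
  out <- tapply(lens, factor(plan$out_id, levels = unique(plan$out_id)), sum)
  stats::setNames(as.numeric(out), names(out))
}

# append out_start/out_end columns for one scaffold's components (in order)
plan_offsets <- function(comps) {
  lens <- plan_comp_lengths(comps)
  comps$out_start <- cumsum(c(0, lens[-length(lens)]))
  comps$out_end <- comps$out_start + lens
  comps
}

# split one component row at output offset `off` (0 < off < length)
split_comp <- function(comp, off) {
  len <- comp$src_end - comp$src_start
  stopifnot(off > 0, off < len)
  left <- comp; right <- comp
  if (comp$type == "N") {
    left$src_end <- off
    right$src_end <- len - off
  } else if (comp$strand == "+") {
    left$src_end <- comp$src_start + off
    right$src_start <- comp$src_start + off
  } else {
    left$src_start <- comp$src_end - off
    right$src_end <- comp$src_end - off
  }
  list(left = left, right = right)
}

# keep components of the scaffold-plan `comps` covering output [0, at) only
plan_head <- function(comps, at) {
  comps <- plan_offsets(comps)
  keep <- comps[comps$out_end <= at, , drop = FALSE]
  cut <- comps[comps$out_start < at & comps$out_end > at, , drop = FALSE]
  if (nrow(cut) == 1) {
    keep <- dplyr::bind_rows(keep, split_comp(cut, at - cut$out_start)$left)
  }
  keep[, setdiff(names(keep), c("out_start", "out_end"))]
}

plan_tail <- function(comps, at) {
  comps <- plan_offsets(comps)
  keep <- comps[comps$out_start >= at, , drop = FALSE]
  cut <- comps[comps$out_start < at & comps$out_end > at, , drop = FALSE]
  if (nrow(cut) == 1) {
    keep <- dplyr::bind_rows(split_comp(cut, at - cut$out_start)$right, keep)
  }
  keep[, setdiff(names(keep), c("out_start", "out_end"))]
}

# reverse-complement a whole scaffold plan (flip order and strands)
plan_flip <- function(comps) {
  comps <- comps[rev(seq_len(nrow(comps))), , drop = FALSE]
  w <- comps$type == "W"
  comps$strand[w] <- ifelse(comps$strand[w] == "+", "-", "+")
  comps
}

# Apply edits (coordinates in the plan's CURRENT output coordinates) to a
# plan. Replacement-like edits (kind block_replacement / gap_fill) replace
# out interval [base_start, base_end) of scaffold base_id with the donor
# interval; merge edits join scaffolds base_id and donor_id (with
# orientations base_or / donor_or and a gap of gap_len N) into new_id.
plan_apply_edits <- function(plan, edits) {
  if (is.null(edits) || nrow(edits) == 0) return(plan)
  repl <- edits[edits$kind %in% c("block_replacement", "gap_fill"), ,
                drop = FALSE]
  if (nrow(repl) > 0) {
    lens <- plan_lengths(plan)
    # right-to-left within each scaffold so earlier coordinates stay valid
    repl <- repl[order(repl$base_id, -repl$base_start), , drop = FALSE]
    byid <- split(plan, factor(plan$out_id, levels = unique(plan$out_id)))
    for (i in seq_len(nrow(repl))) {
      e <- repl[i, ]
      comps <- byid[[e$base_id]]
      if (is.null(comps)) stop("edit references unknown scaffold ", e$base_id)
      if (e$base_end > sum(plan_comp_lengths(comps)) || e$base_start < 0 ||
          e$base_end <= e$base_start) {
        stop("edit coordinates out of range on ", e$base_id)
      }
      donor <- tibble::tibble(
        out_id = e$base_id, part = 0L, type = "W",
        source = e$donor_assembly, source_id = e$donor_id,
        src_start = e$donor_start, src_end = e$donor_end,
        strand = e$donor_strand)
      byid[[e$base_id]] <- dplyr::bind_rows(
        plan_head(comps, e$base_start), donor, plan_tail(comps, e$base_end))
    }
    plan <- dplyr::bind_rows(byid)
  }
  mg <- edits[edits$kind == "merge", , drop = FALSE]
  if (nrow(mg) > 0) {
    byid <- split(plan, factor(plan$out_id, levels = unique(plan$out_id)))
    for (i in seq_len(nrow(mg))) {
      e <- mg[i, ]
      a <- byid[[e$base_id]]; b <- byid[[e$donor_id]]
      if (is.null(a) || is.null(b)) {
        stop("merge references unknown scaffold(s) ", e$base_id, "/",
             e$donor_id)
      }
      if (identical(e$base_or, "-")) a <- plan_flip(a)
      if (identical(e$donor_or, "-")) b <- plan_flip(b)
      gap <- tibble::tibble(out_id = e$new_id, part = 0L, type = "N",
                            source = NA_character_, source_id = NA_character_,
                            src_start = 0L, src_end = as.integer(e$gap_len),
                            strand = "+")
      merged <- dplyr::bind_rows(a, gap, b)
      merged$out_id <- e$new_id
      byid[[e$base_id]] <- NULL; byid[[e$donor_id]] <- NULL
      byid[[e$new_id]] <- merged
    }
    plan <- dplyr::bind_rows(byid)
  }
  plan$part <- stats::ave(seq_len(nrow(plan)), plan$out_id,
                          FUN = seq_along)
  plan
}

# splice output sequences from a plan and its named source assemblies
plan_sequence <- function(plan, sources) {
  byid <- split(plan, factor(plan$out_id, levels = unique(plan$out_id)))
  out <- vapply(byid, function(comps) {
    pieces <- character(nrow(comps))
    for (j in seq_len(nrow(comps))) {
      cmp <- comps[j, ]
      if (cmp$type == "N") {
        pieces[j] <- strrep("N", cmp$src_end - cmp$src_start)
      } else {
        src <- sources[[cmp$source]]
        if (is.null(src)) stop("unknown source assembly: ", cmp$source)
        s <- substring(unclass(src)[[cmp$source_id]], cmp$src_start + 1L,
                       cmp$src_end)
        if (cmp$strand == "-") s <- revcomp(s)
        pieces[j] <- s
      }
    }
    paste0(pieces, collapse = "")
  }, character(1))
  as_assembly(out)
}

plan_to_agp <- function(plan) {
  plan <- dplyr::bind_rows(lapply(
    split(plan, factor(plan$out_id, levels = unique(plan$out_id))),
    plan_offsets))
  lens <- plan_comp_lengths(plan)
  if (any(lens <= 0)) stop("zero/negative-length AGP component")
  tibble::tibble(
    object = plan$out_id,
    object_beg = plan$out_start + 1L,
    object_end = plan$out_end,
    part_number = plan$part,
    component_type = plan$type,
    component_id = ifelse(plan$type == "N", as.character(lens),
                          plan$source_id),
    component_beg = ifelse(plan$type == "N", "scaffold",
                           as.character(plan$src_start + 1L)),
    component_end = ifelse(plan$type == "N", "yes",
                           as.character(plan$src_end)),
    orientation = ifelse(plan$type == "N", "align_genus", plan$strand))
}

#' Write AGP v2.1 provenance
#'
#' Describes each output scaffold as an ordered list of components: W rows for
#' base- or donor-assembly segments (1-based inclusive source coordinates) and
#' N rows of gap type `scaffold` with linkage evidence `align_genus` for merge
#' gaps. For a plain assembly each scaffold is one full-length W row.
#'
#' @param x an `asm_reconciliation` (see [reconcile_assemblies()]) or an
#'   `asm_set`.
#' @param path output file.
#' @param ... unused.
#' @return `path`, invisibly.
#' @export
write_agp <- function(x, path, ...) UseMethod("write_agp")

#' @export
write_agp.asm_set <- function(x, path, ...) {
  write_agp_plan(plan_identity(x), path)
}

#' @export
write_agp.asm_reconciliation <- function(x, path, ...) {
  write_agp_plan(x$plan, path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_agp_plan <- function(plan, path) {
  agp <- plan_to_agp(plan)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  utils::write.table(agp, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# Liftovers ---------------------------------------------------------------

#' Compose a plan with source truth-liftovers
#'
#' A liftover is a tibble (`seq_id`, `seg_start`, `seg_end`, `truth_chrom`,
#' `truth_start`, `truth_end`, `strand`) whose segments tile an assembly; a
#' `-` segment means the assembly holds the reverse complement of the truth
#' interval. Given a component plan over source assemblies and one liftover
#' per source, returns the liftover of the planned (output) assembly.
#'
#' @param plan a component plan (internal representation used by
#'   [reconcile_assemblies()] results).
#' @param liftovers named list of liftover tibbles, one per source assembly.
#' @return a liftover tibble for the output assembly.
#' @export
compose_liftover <- function(plan, liftovers) {
  plan <- dplyr::bind_rows(lapply(
    split(plan, factor(plan$out_id, levels = unique(plan$out_id))),
    plan_offsets))
  rows <- vector("list", nrow(plan))
  for (j in seq_len(nrow(plan))) {
    cmp <- plan[j, ]
    clen <- cmp$src_end - cmp$src_start
    if (cmp$type == "N") {
      rows[[j]] <- tibble::tibble(
        seq_id = cmp$out_id, seg_start = cmp$out_start, seg_end = cmp$out_end,
        truth_chrom = NA_character_, truth_start = NA_real_,
        truth_end = NA_real_, strand = "+")
      next
    }
    lo <- liftovers[[cmp$source]]
    if (is.null(lo)) stop("no liftover for source ", cmp$source)
    segs <- lo[lo$seq_id == cmp$source_id &
               lo$seg_end > cmp$src_start & lo$seg_start < cmp$src_end, ,
               drop = FALSE]
    if (nrow(segs) == 0) next
    is <- pmax(segs$seg_start, cmp$src_start)
    ie <- pmin(segs$seg_end, cmp$src_end)
    # truth interval of the clipped piece
    tplus <- segs$strand == "+"
    ts <- ifelse(tplus, segs$truth_start + (is - segs$seg_start),
                 segs$truth_end - (ie - segs$seg_start))
    te <- ifelse(tplus, segs$truth_start + (ie - segs$seg_start),
                 segs$truth_end - (is - segs$seg_start))
    if (cmp$strand == "+") {
      os <- cmp$out_start + (is - cmp$src_start)
      oe <- cmp$out_start + (ie - cmp$src_start)
      st <- segs$strand
    } else {
      os <- cmp$out_start + (cmp$src_end - ie)
      oe <- cmp$out_start + (cmp$src_end - is)
      st <- ifelse(segs$strand == "+", "-", "+")
    }
    rows[[j]] <- tibble::tibble(
      seq_id = cmp$out_id, seg_start = os, seg_end = oe,
      truth_chrom = segs$truth_chrom, truth_start = ts, truth_end = te,
      strand = st)
  }
  out <- dplyr::bind_rows(rows)
  coalesce_liftover(dplyr::arrange(out, .data$seq_id, .data$seg_start))
}

# merge exactly-continuous neighbouring segments (same sequence, chromosome
# and strand, with both assembly and truth coordinates abutting), so that a
# seam between a base component and a donor component that restores the
# truth contiguously does not fragment the liftover
coalesce_liftover <- function(lo) {
  if (nrow(lo) < 2) return(lo)
  keep <- logical(nrow(lo))
  cur <- 1L
  keep[1] <- TRUE
  for (i in 2:nrow(lo)) {
    a <- lo[cur, ]; b <- lo[i, ]
    contiguous <- b$seq_id == a$seq_id && b$seg_start == a$seg_end &&
      ((is.na(a$truth_chrom) && is.na(b$truth_chrom)) ||
       (!is.na(a$truth_chrom) && !is.na(b$truth_chrom) &&
        a$truth_chrom == b$truth_chrom && a$strand == b$strand &&
        ((a$strand == "+" && b$truth_start == a$truth_end) ||
         (a$strand == "-" && b$truth_end == a$truth_start))))
    if (contiguous) {
      lo$seg_end[cur] <- b$seg_end
      if (!is.na(a$truth_chrom)) {
        if (a$strand == "+") lo$truth_end[cur] <- b$truth_end
        else lo$truth_start[cur] <- b$truth_start
      }
    } else {
      cur <- i
      keep[i] <- TRUE
    }
  }
  lo[keep, , drop = FALSE]
}

#' Project truth intervals onto an assembly through a liftover
#'
#' Each query interval `[start, start + width)` on a truth chromosome is
#' mapped to assembly coordinates when it lies entirely inside one liftover
#' segment; otherwise (deleted sequence, or an interval spanning a segment
#' boundary) it is reported unmapped.
#'
#' @param liftover a liftover tibble (see [compose_liftover()]).
#' @param chrom,start,width parallel vectors describing truth intervals
#'   (0-based starts).
#' @return a tibble (`seq_id`, `pos`, `strand`) with NA rows for unmapped
#'   queries; `pos` is the 0-based leftmost assembly base of the interval.
#' @export
liftover_project <- function(liftover, chrom, start, width = 1L) {
  n <- length(start)
  width <- rep_len(width, n)
  seq_id <- rep(NA_character_, n)
  pos <- rep(NA_real_, n)
  strand <- rep(NA_character_, n)
  lo <- liftover[!is.na(liftover$truth_chrom), , drop = FALSE]
  for (ch in unique(chrom)) {
    qi <- which(chrom == ch)
    segs <- lo[lo$truth_chrom == ch, , drop = FALSE]
    if (nrow(segs) == 0) next
    segs <- segs[order(segs$truth_start), , drop = FALSE]
    idx <- findInterval(start[qi], segs$truth_start)
    ok <- idx >= 1
    ok[ok] <- (start[qi][ok] + width[qi][ok]) <= segs$truth_end[idx[ok]]
    hit <- qi[ok]; sidx <- idx[ok]
    if (length(hit) == 0) next
    sp <- segs$strand[sidx] == "+"
    pos[hit] <- ifelse(
      sp, segs$seg_start[sidx] + (start[hit] - segs$truth_start[sidx]),
      segs$seg_start[sidx] +
        (segs$truth_end[sidx] - (start[hit] + width[hit])))
    seq_id[hit] <- segs$seq_id[sidx]
    strand[hit] <- ifelse(sp, "+", "-")
  }
  tibble::tibble(seq_id = seq_id, pos = pos, strand = strand)
}
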