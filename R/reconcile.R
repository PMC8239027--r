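# Consensus reconciliation ------------------------------------------------

#' Reconciliation parameters
#'
#' Defaults, all in bp unless stated: `gap_window` is how close a gap tract
#' must be to a junction for check A ("gaps are present"); `merge_window`
#' clusters junction candidates from different alternates and bounds the
#' agreement distance between their continuation loci; `flank` is the
#' aligned-sequence support required on both sides of a filled gap;
#' `min_agree` is check B's consensus threshold (at least two alternates
#' discrepant with the base and mutually consistent); `min_continuation` is
#' the minimum remaining contig length for a broken alignment to count as a
#' discrepancy rather than a mere contig end; `anchor_search` bounds the
#' search for flanking shared anchors around a junction; `max_span` bounds
#' the base extent of one block replacement. Scaffold merging considers
#' scaffolds of at least `min_merge_len` (10 Mb, as for pseudo-chromosome
#' arms) joined when `min_merge_evidence` alternates each bridge the two
#' termini within `terminal_window`, inserting `join_gap_len` N between them.
#'
#' @param gap_window,merge_window,flank,min_agree,min_continuation
#'   see Description.
#' @param anchor_search,max_span see Description.
#' @param min_merge_len,min_merge_evidence,terminal_window,join_gap_len
#'   see Description.
#' @return a named list of parameters.
#' @export
reconcile_params <- function(gap_window = 20000, merge_window = 20000,
                             flank = 5000, min_agree = 2L,
                             min_continuation = 1000, anchor_search = 50000,
                             max_span = 500000, min_merge_len = 1e7,
                             min_merge_evidence = 2L, terminal_window = 50000,
                             join_gap_len = 100L) {
  list(gap_window = gap_window, merge_window = merge_window, flank = flank,
       min_agree = as.integer(min_agree),
       min_continuation = min_continuation, anchor_search = anchor_search,
       max_span = max_span, min_merge_len = min_merge_len,
       min_merge_evidence = as.integer(min_merge_evidence),
       terminal_window = terminal_window,
       join_gap_len = as.integer(join_gap_len))
}

# innermost anchor on one side of `bound` whose diagonal (y - base_pos)
# agrees with the local consensus diagonal of that side. In a tandem-repeat
# tract an exact k-mer can match a different repeat copy; cutting at such a
# slipped anchor would contract or expand the repeat, so seam anchors must
# sit on the same diagonal as their neighbours (tolerance `tol` bp).
anchor_innermost <- function(a, k, side, bound, tol = 10) {
  if (is.null(a) || nrow(a) == 0) return(NULL)
  idx <- if (side == "left") which(a$base_pos + k <= bound) else
    which(a$base_pos >= bound)
  if (length(idx) == 0) return(NULL)
  dd <- a$y - a$base_pos
  ref <- if (side == "left") stats::median(dd[utils::tail(idx, 30)]) else
    stats::median(dd[utils::head(idx, 30)])
  ok <- idx[abs(dd[idx] - ref) <= tol]
  if (length(ok) == 0) return(NULL)
  a[if (side == "left") max(ok) else min(ok), , drop = FALSE]
}

# base coordinate of alternate (forward) position `apos` under block `b`
block_base_at <- function(b, apos) {
  off <- apos - b$alt_start
  if (b$strand == "+") {
    min(max(b$base_start + off, b$base_start), b$base_end)
  } else {
    min(max(b$base_end - off, b$base_start), b$base_end)
  }
}

# Discrepant junctions contributed by ONE alternate: for each pair of blocks
# adjacent on a base scaffold, the junction is discrepant when the two blocks
# come from the same contig in non-collinear order or opposite strands, or
# from different contigs at least one of which demonstrably continues
# elsewhere (the signature of a broken/rearranged alignment rather than a
# plain contig end).
alt_junctions <- function(blocks, params, k = 15L) {
  out <- list()
  slack <- 2 * k
  for (bid in unique(blocks$base_id)) {
    bb <- blocks[blocks$base_id == bid, , drop = FALSE]
    bb <- bb[order(bb$base_start), , drop = FALSE]
    if (nrow(bb) < 2) next
    for (i in seq_len(nrow(bb) - 1L)) {
      b1 <- bb[i, ]; b2 <- bb[i + 1L, ]
      disc <- FALSE
      loci <- list()
      if (b1$alt_id == b2$alt_id) {
        if (b1$strand != b2$strand) {
          disc <- TRUE
        } else if (b1$strand == "+" && b2$alt_start < b1$alt_end - slack) {
          disc <- TRUE
        } else if (b1$strand == "-" && b2$alt_end > b1$alt_start + slack) {
          disc <- TRUE
        }
        if (disc) {
          loci <- list(c(id = b2$base_id, pos = b2$base_start))
        }
      } else {
        cl <- continuation_locus(blocks, b1, side = "after", slack = slack,
                                 min_cont = params$min_continuation)
        cr <- continuation_locus(blocks, b2, side = "before", slack = slack,
                                 min_cont = params$min_continuation)
        if (!is.null(cl)) { disc <- TRUE; loci <- c(loci, list(cl)) }
        if (!is.null(cr)) { disc <- TRUE; loci <- c(loci, list(cr)) }
      }
      if (disc) {
        jl <- b1$base_end; jr <- max(b2$base_start, jl)
        out[[length(out) + 1L]] <- tibble::tibble(
          base_id = bid, pos = floor((jl + jr) / 2), jl = jl, jr = jr,
          b1 = list(b1), b2 = list(b2), loci = list(loci))
      }
    }
  }
  dplyr::bind_rows(out)
}

# Where does block `b`'s contig continue beyond its junction-side terminus?
# Returns c(id, pos) of the continuation on the base, or NULL if the contig
# is essentially used up there (a plain fragmentation end).
continuation_locus <- function(blocks, b, side, slack, min_cont) {
  if (side == "after") {
    t <- if (b$strand == "+") b$alt_end else b$alt_start
    rem <- if (b$strand == "+") b$alt_len - b$alt_end else b$alt_start
  } else {
    t <- if (b$strand == "+") b$alt_start else b$alt_end
    rem <- if (b$strand == "+") b$alt_start else b$alt_len - b$alt_end
  }
  if (rem < min_cont) return(NULL)
  cand <- blocks[blocks$alt_id == b$alt_id, , drop = FALSE]
  cand <- cand[!(cand$base_id == b$base_id &
                 cand$base_start == b$base_start &
                 cand$strand == b$strand), , drop = FALSE]
  beyond <- if ((side == "after") == (b$strand == "+")) {
    cand[cand$alt_start >= t - slack, , drop = FALSE]
  } else {
    cand[cand$alt_end <= t + slack, , drop = FALSE]
  }
  if (nrow(beyond) == 0) return(NULL)
  if ((side == "after") == (b$strand == "+")) {
    cb <- beyond[which.min(beyond$alt_start), ]
    apos <- cb$alt_start
  } else {
    cb <- beyond[which.max(beyond$alt_end), ]
    apos <- cb$alt_end
  }
  c(id = cb$base_id, pos = block_base_at(cb, apos))
}

#' Call candidate misjoin breakpoints by alternate-assembly consensus
#'
#' For every alternate, junctions between adjacent alignment blocks on the
#' base are screened for discrepancies (same contig rearranged or flipped, or
#' a contig whose alignment breaks and continues elsewhere). Candidates from
#' different alternates within `merge_window` are clustered into one call.
#' Per-alternate verdicts are `consistent_with_base` (a single block spans the
#' junction with `flank` margin), `discrepant`, or `no_coverage`; mutually
#' consistent discrepant alternates are those whose continuation loci agree in
#' place (within `merge_window`) after mapping through base coordinates. A
#' call is actionable iff a gap tract lies within `gap_window` (check A) and
#' at least `min_agree` alternates are discrepant and agreeing (check B).
#'
#' @param base the base assembly (`asm_set` or coercible).
#' @param gaps gap tibble from [find_gaps()] on `base`.
#' @param alignments named list (one per alternate) of block tibbles from
#'   [align_assemblies()] or [read_paf()].
#' @param params see [reconcile_params()].
#' @param k anchor length used by the aligner (boundary slack unit).
#' @return a tibble of calls: `base_id`, `position`, `jmin`, `jmax`,
#'   `gap_nearby`, `n_discrepant_agreeing`, `actionable`, plus list-columns
#'   `evidence` (named per-alternate verdicts), `agreeing` (alternate names)
#'   and `cands` (per-alternate candidate details used for repair).
#' @export
call_breakpoints <- function(base, gaps, alignments, params = reconcile_params(),
                             k = 15L) {
  base <- as_assembly(base)
  stopifnot(is.list(alignments), length(alignments) >= 1,
            !is.null(names(alignments)))
  for (nm in names(alignments)) {
    bad <- setdiff(unique(alignments[[nm]]$base_id), names(base))
    if (length(bad) > 0) {
      stop("alignment '", nm, "' references unknown base scaffold: ", bad[1])
    }
  }
  cand <- dplyr::bind_rows(purrr::imap(alignments, function(bl, nm) {
    j <- alt_junctions(bl, params, k = k)
    if (nrow(j) > 0) j$alt <- nm
    j
  }))
  if (is.null(cand) || nrow(cand) == 0) return(empty_calls())
  calls <- list()
  for (bid in unique(cand$base_id)) {
    cc <- cand[cand$base_id == bid, , drop = FALSE]
    cc <- cc[order(cc$pos), , drop = FALSE]
    grp <- cumsum(c(1, diff(cc$pos) > params$merge_window))
    for (g in unique(grp)) {
      cl <- cc[grp == g, , drop = FALSE]
      calls[[length(calls) + 1L]] <-
        summarise_cluster(cl, bid, base, gaps, alignments, params)
    }
  }
  out <- dplyr::bind_rows(calls)
  dplyr::arrange(out, .data$base_id, .data$position)
}

empty_calls <- function() {
  tibble::tibble(base_id = character(), position = numeric(),
                 jmin = numeric(), jmax = numeric(), gap_nearby = logical(),
                 n_discrepant_agreeing = integer(), actionable = logical(),
                 evidence = list(), agreeing = list(), cands = list())
}

summarise_cluster <- function(cl, bid, base, gaps, alignments, params) {
  jmin <- min(cl$jl); jmax <- max(cl$jr)
  pos <- floor((jmin + jmax) / 2)
  alts <- names(alignments)
  verdict <- stats::setNames(rep("no_coverage", length(alts)), alts)
  disc <- unique(cl$alt)
  verdict[disc] <- "discrepant"
  for (nm in setdiff(alts, disc)) {
    bl <- alignments[[nm]]
    span <- bl$base_id == bid &
      bl$base_start <= jmin - params$flank &
      bl$base_end >= jmax + params$flank
    if (any(span)) verdict[nm] <- "consistent_with_base"
  }
  # mutual consistency: continuation loci agree in place through base coords
  agree <- outer(disc, disc, Vectorize(function(a, b) {
    if (a == b) return(TRUE)
    la <- unlist(cl$loci[cl$alt == a], recursive = FALSE)
    lb <- unlist(cl$loci[cl$alt == b], recursive = FALSE)
    if (length(la) == 0 || length(lb) == 0) return(FALSE)
    for (x in la) for (y in lb) {
      if (x[["id"]] == y[["id"]] &&
          abs(as.numeric(x[["pos"]]) - as.numeric(y[["pos"]])) <=
            params$merge_window) return(TRUE)
    }
    FALSE
  }))
  comp <- components_of(agree)
  sizes <- table(comp)
  best <- names(sizes)[which.max(sizes)]
  agreeing <- sort(disc[comp == as.integer(best)])
  gg <- gaps[gaps$scaffold_id == bid, , drop = FALSE]
  gap_nearby <- nrow(gg) > 0 &&
    any(gg$end >= jmin - params$gap_window &
        gg$start <= jmax + params$gap_window)
  n_agree <- length(agreeing)
  tibble::tibble(
    base_id = bid, position = pos, jmin = jmin, jmax = jmax,
    gap_nearby = gap_nearby, n_discrepant_agreeing = n_agree,
    actionable = gap_nearby && n_agree >= params$min_agree,
    evidence = list(verdict), agreeing = list(agreeing), cands = list(cl))
}

# connected components of a symmetric logical adjacency matrix
components_of <- function(m) {
  n <- nrow(m)
  comp <- rep(0L, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0) next
    cur <- cur + 1L
    queue <- i
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      if (comp[v] > 0) next
      comp[v] <- cur
      queue <- c(queue, which(m[v, ] & comp == 0L))
    }
  }
  comp
}

# find the donor-side repair for one call and one alternate: the upstream
# flanking block U and the first collinear block D of the same contig beyond
# the cluster; boundaries snap to the outermost shared anchors (block edges
# for anchor-less PAF blocks)
donor_repair <- function(bl, call, k, params) {
  bb <- bl[bl$base_id == call$base_id, , drop = FALSE]
  cand_u <- bb[bb$base_end <= call$jmin + 2 * k &
               bb$base_end >= call$jmin - params$anchor_search, , drop = FALSE]
  if (nrow(cand_u) == 0) return(NULL)
  U <- cand_u[which.max(cand_u$base_end), ]
  # first collinear continuation of U's contig beyond the junction cluster:
  # different alternates snap the downstream junction to their own anchors,
  # so the bound is the donor's own upstream block, not the cluster edge
  cand_d <- bb[bb$alt_id == U$alt_id & bb$strand == U$strand &
               bb$base_start >= pmax(U$base_end, call$jmin) - 2 * k &
               bb$base_start - U$base_end <= params$max_span, , drop = FALSE]
  if (U$strand == "+") {
    cand_d <- cand_d[cand_d$alt_start >= U$alt_end - 2 * k, , drop = FALSE]
  } else {
    cand_d <- cand_d[cand_d$alt_end <= U$alt_start + 2 * k, , drop = FALSE]
  }
  if (nrow(cand_d) == 0) return(NULL)
  D <- cand_d[which.min(cand_d$base_start), ]
  au <- U$anchors[[1]]; ad <- D$anchors[[1]]
  if (!is.null(au) && nrow(au) > 0 && !is.null(ad) && nrow(ad) > 0) {
    up <- anchor_innermost(au, k, "left", Inf)
    dn <- anchor_innermost(ad, k, "right", -Inf)
    if (is.null(up) || is.null(dn)) return(NULL)
    base_start <- up$base_pos; base_end <- dn$base_pos + k
    if (U$strand == "+") {
      donor_start <- up$alt_fwd; donor_end <- dn$alt_fwd + k
    } else {
      donor_start <- dn$alt_fwd; donor_end <- up$alt_fwd + k
    }
  } else {
    base_start <- U$base_end; base_end <- D$base_start
    if (U$strand == "+") {
      donor_start <- U$alt_end; donor_end <- D$alt_start
    } else {
      donor_start <- D$alt_end; donor_end <- U$alt_start
    }
  }
  if (base_end <= base_start || donor_end <= donor_start) return(NULL)
  list(base_start = base_start, base_end = base_end, donor_id = U$alt_id,
       donor_start = donor_start, donor_end = donor_end,
       donor_strand = U$strand)
}

empty_edits <- function() {
  tibble::tibble(kind = character(), base_id = character(),
                 base_start = numeric(), base_end = numeric(),
                 donor_assembly = character(), donor_id = character(),
                 donor_start = numeric(), donor_end = numeric(),
                 donor_strand = character(), inserted_length = numeric(),
                 rng_draw = integer(), n_gaps = integer(),
                 base_or = character(), donor_or = character(),
                 new_id = character(), gap_len = integer())
}

#' Replace misjoined blocks with alternate-assembly sequence
#'
#' For each actionable call the base region from the last shared anchor
#' upstream of the junction cluster to the first shared anchor downstream is
#' replaced by the corresponding interval of one agreeing alternate, chosen
#' by seeded RNG among the agreeing set (the draw is recorded). Replacement
#' sequence is reverse-complemented for minus-strand donors. Overlapping
#' actionable calls are processed largest-evidence-first (ties leftmost);
#' calls without a usable flanking-anchor pair are skipped with a warning.
#'
#' @param base the base assembly.
#' @param alternates named list of alternate assemblies (donor sequence).
#' @param alignments named list of block tibbles (same names).
#' @param calls calls tibble from [call_breakpoints()].
#' @param params see [reconcile_params()].
#' @param rng_seed integer seed for donor choice; `NULL` uses the current RNG
#'   stream (as inside [reconcile_assemblies()]).
#' @param k anchor length (bp).
#' @return list with `assembly` (the hybrid), `edits` (EditRecord tibble with
#'   pre-edit coordinates), and `n_skipped`.
#' @export
apply_block_replacements <- function(base, alternates, alignments, calls,
                                     params = reconcile_params(),
                                     rng_seed = NULL, k = 15L) {
  base <- as_assembly(base)
  run <- function() {
    act <- calls[calls$actionable, , drop = FALSE]
    edits <- list()
    n_skipped <- 0L
    if (nrow(act) > 0) {
      act <- act[order(-act$n_discrepant_agreeing, act$position), ,
                 drop = FALSE]
      claimed <- list()
      for (i in seq_len(nrow(act))) {
        call <- act[i, ]
        agreeing <- call$agreeing[[1]]
        ord <- sample.int(length(agreeing))
        rec <- NULL; draw <- NA_integer_
        for (j in ord) {
          nm <- agreeing[j]
          rec <- donor_repair(alignments[[nm]], call, k, params)
          if (!is.null(rec)) {
            donor_seq <- substring(unclass(alternates[[nm]])[[rec$donor_id]],
                                   rec$donor_start + 1L, rec$donor_end)
            if (grepl("N", donor_seq, fixed = TRUE)) { rec <- NULL; next }
            draw <- j; rec$donor_assembly <- nm
            break
          }
        }
        if (is.null(rec)) {
          warning("no flanking anchors for call at ", call$base_id, ":",
                  call$position, "; skipped")
          n_skipped <- n_skipped + 1L
          next
        }
        cl <- claimed[[call$base_id]]
        if (!is.null(cl) &&
            any(rec$base_start < cl$end & rec$base_end > cl$start)) {
          next  # region already resolved by a stronger overlapping call
        }
        claimed[[call$base_id]] <- rbind(
          cl, data.frame(start = rec$base_start, end = rec$base_end))
        edits[[length(edits) + 1L]] <- tibble::tibble(
          kind = "block_replacement", base_id = call$base_id,
          base_start = rec$base_start, base_end = rec$base_end,
          donor_assembly = rec$donor_assembly, donor_id = rec$donor_id,
          donor_start = rec$donor_start, donor_end = rec$donor_end,
          donor_strand = rec$donor_strand,
          inserted_length = rec$donor_end - rec$donor_start,
          rng_draw = draw)
      }
    }
    edits <- if (length(edits) > 0) dplyr::bind_rows(edits) else empty_edits()
    plan <- plan_apply_edits(plan_identity(base, source = ".base"), edits)
    out <- plan_sequence(plan, c(list(.base = base), alternates))
    list(assembly = out, edits = edits, n_skipped = n_skipped)
  }
  if (is.null(rng_seed)) run() else withr::with_seed(rng_seed, run())
}

#' Fill N-gap tracts from gap-free alternate regions
#'
#' A gap is fillable by an alternate iff one of its blocks spans the gap with
#' at least `flank` bp of aligned sequence on both sides and the donor
#' interval between the innermost flanking anchors contains no N. Among
#' alternates able to fill a gap one is chosen by seeded RNG; overlapping
#' fillable gaps under one spanning block become one combined edit.
#'
#' @inheritParams apply_block_replacements
#' @param gaps gap tibble; defaults to `find_gaps(base)`.
#' @return list with `assembly`, `edits`, `filled` (gap rows filled),
#'   `unfilled` (gap rows left, with a `reason` column),
#'   `n_gaps_filled` and `filled_gap_total_length`.
#' @export
fill_gaps <- function(base, alternates, alignments, gaps = NULL,
                      params = reconcile_params(), rng_seed = NULL, k = 15L) {
  base <- as_assembly(base)
  if (is.null(gaps)) gaps <- find_gaps(base)
  run <- function() {
    per_gap <- vector("list", nrow(gaps))
    reason <- rep("no_spanning_block", nrow(gaps))
    for (gi in seq_len(nrow(gaps))) {
      g <- gaps[gi, ]
      options <- list()
      for (nm in names(alignments)) {
        bl <- alignments[[nm]]
        sp <- bl[bl$base_id == g$scaffold_id &
                 bl$base_start <= g$start - params$flank &
                 bl$base_end >= g$end + params$flank, , drop = FALSE]
        if (nrow(sp) == 0) next
        b <- sp[which.max(sp$score), ]
        fill <- gap_fill_interval(b, g, k)
        if (is.null(fill)) { reason[gi] <- "no_flanking_anchor"; next }
        donor_seq <- substring(unclass(alternates[[nm]])[[b$alt_id]],
                               fill$donor_start + 1L, fill$donor_end)
        if (grepl("N", donor_seq, fixed = TRUE)) {
          reason[gi] <- "donor_has_gap"; next
        }
        options[[nm]] <- c(fill, list(donor_assembly = nm,
                                      donor_id = b$alt_id,
                                      donor_strand = b$strand))
      }
      if (length(options) == 0) next
      draw <- if (length(options) == 1) 1L else sample.int(length(options), 1L)
      o <- options[[draw]]
      per_gap[[gi]] <- tibble::tibble(
        kind = "gap_fill", base_id = g$scaffold_id,
        base_start = o$base_start, base_end = o$base_end,
        donor_assembly = o$donor_assembly, donor_id = o$donor_id,
        donor_start = o$donor_start, donor_end = o$donor_end,
        donor_strand = o$donor_strand,
        inserted_length = o$donor_end - o$donor_start,
        rng_draw = draw, n_gaps = 1L, gap_length = g$length,
        gap_row = list(gi))
    }
    cand <- dplyr::bind_rows(per_gap)
    edits <- list()
    filled_rows <- integer(0)
    if (nrow(cand) > 0) {
      cand <- cand[order(cand$base_id, cand$base_start), , drop = FALSE]
      cur <- cand[1, ]
      flush <- function(cur) edits[[length(edits) + 1L]] <<- cur
      for (i in seq_len(nrow(cand))[-1]) {
        e <- cand[i, ]
        if (e$base_id == cur$base_id && e$base_start < cur$base_end) {
          same_donor <- e$donor_assembly == cur$donor_assembly &&
            e$donor_id == cur$donor_id && e$donor_strand == cur$donor_strand
          if (same_donor) {  # combined edit under one spanning block
            cur$base_end <- max(cur$base_end, e$base_end)
            cur$donor_start <- min(cur$donor_start, e$donor_start)
            cur$donor_end <- max(cur$donor_end, e$donor_end)
            cur$inserted_length <- cur$donor_end - cur$donor_start
            cur$n_gaps <- cur$n_gaps + 1L
            cur$gap_length <- cur$gap_length + e$gap_length
            cur$gap_row <- list(c(unlist(cur$gap_row), unlist(e$gap_row)))
          } else {
            reason[unlist(e$gap_row)] <- "overlapping_fill_conflict"
          }
        } else {
          flush(cur); cur <- e
        }
      }
      flush(cur)
      edits <- dplyr::bind_rows(edits)
      filled_rows <- unlist(edits$gap_row)
    } else {
      edits <- empty_edits()
    }
    edits <- edits[, setdiff(names(edits), c("gap_row", "gap_length")),
                   drop = FALSE]
    plan <- plan_apply_edits(plan_identity(base, source = ".base"), edits)
    out <- plan_sequence(plan, c(list(.base = base), alternates))
    unfilled <- gaps[setdiff(seq_len(nrow(gaps)), filled_rows), ,
                     drop = FALSE]
    if (nrow(unfilled) > 0) {
      unfilled$reason <- reason[setdiff(seq_len(nrow(gaps)), filled_rows)]
    } else {
      unfilled$reason <- character(0)
    }
    list(assembly = out, edits = edits,
         filled = gaps[filled_rows, , drop = FALSE], unfilled = unfilled,
         n_gaps_filled = length(filled_rows),
         filled_gap_total_length = sum(gaps$length[filled_rows]))
  }
  if (is.null(rng_seed)) run() else withr::with_seed(rng_seed, run())
}

# innermost flanking anchors around a gap under spanning block `b`
# (block-edge interpolation when the block carries no anchors, e.g. PAF)
gap_fill_interval <- function(b, g, k) {
  a <- b$anchors[[1]]
  if (!is.null(a) && nrow(a) > 0) {
    up <- anchor_innermost(a, k, "left", g$start)
    dn <- anchor_innermost(a, k, "right", g$end)
    if (is.null(up) || is.null(dn)) return(NULL)
    base_start <- up$base_pos; base_end <- dn$base_pos + k
    if (b$strand == "+") {
      donor_start <- up$alt_fwd; donor_end <- dn$alt_fwd + k
    } else {
      donor_start <- dn$alt_fwd; donor_end <- up$alt_fwd + k
    }
  } else {
    base_start <- max(b$base_start, g$start - 1000)
    base_end <- min(b$base_end, g$end + 1000)
    off1 <- base_start - b$base_start; off2 <- b$base_end - base_end
    if (b$strand == "+") {
      donor_start <- b$alt_start + off1; donor_end <- b$alt_end - off2
    } else {
      donor_start <- b$alt_start + off2; donor_end <- b$alt_end - off1
    }
  }
  if (donor_end <= donor_start || base_end <= base_start) return(NULL)
  list(base_start = base_start, base_end = base_end,
       donor_start = donor_start, donor_end = donor_end)
}

#' Merge scaffolds supported by alternate-assembly adjacency
#'
#' Scaffolds A and B (each at least `min_merge_len`) are merged when at least
#' `min_merge_evidence` alternates each have a single contig whose blocks
#' reach within `terminal_window` of A's joined terminus and B's joined
#' terminus collinearly. Orientations are resolved from block strands and the
#' halves are joined by `join_gap_len` N. Termini with conflicting partners
#' are left unmerged and reported.
#'
#' @inheritParams apply_block_replacements
#' @return list with `assembly`, `edits` (merge records) and `conflicts`
#'   (tibble of termini with contradictory support).
#' @export
merge_scaffolds <- function(base, alternates, alignments,
                            params = reconcile_params()) {
  base <- as_assembly(base)
  lens <- seq_lengths(base)
  elig <- names(lens)[lens >= params$min_merge_len]
  ev <- list()
  for (nm in names(alignments)) {
    bl <- alignments[[nm]]
    bl <- bl[bl$base_id %in% elig, , drop = FALSE]
    for (cid in unique(bl$alt_id)) {
      cb <- bl[bl$alt_id == cid, , drop = FALSE]
      if (length(unique(cb$base_id)) < 2) next
      cb <- cb[order(cb$alt_start), , drop = FALSE]
      for (i in seq_len(nrow(cb) - 1L)) {
        u <- cb[i, ]; v <- cb[i + 1L, ]
        if (u$base_id == v$base_id) next
        side_u <- terminal_side(u, lens[[u$base_id]], params, outgoing = TRUE)
        side_v <- terminal_side(v, lens[[v$base_id]], params, outgoing = FALSE)
        if (is.null(side_u) || is.null(side_v)) next
        ev[[length(ev) + 1L]] <- tibble::tibble(
          alt = nm, a = u$base_id, side_a = side_u,
          b = v$base_id, side_b = side_v)
      }
    }
  }
  ev <- dplyr::bind_rows(ev)
  edits <- empty_edits()
  conflicts <- tibble::tibble(scaffold = character(), side = character())
  if (nrow(ev) > 0) {
    # canonical undirected key
    flip <- ev$a > ev$b
    ev2 <- ev
    ev2$a[flip] <- ev$b[flip]; ev2$side_a[flip] <- ev$side_b[flip]
    ev2$b[flip] <- ev$a[flip]; ev2$side_b[flip] <- ev$side_a[flip]
    sup <- dplyr::summarise(
      dplyr::group_by(ev2, .data$a, .data$side_a, .data$b, .data$side_b),
      n_alts = dplyr::n_distinct(.data$alt), .groups = "drop")
    sup <- sup[sup$n_alts >= params$min_merge_evidence, , drop = FALSE]
    if (nrow(sup) > 0) {
      term <- c(paste(sup$a, sup$side_a), paste(sup$b, sup$side_b))
      dup <- unique(term[duplicated(term)])
      if (length(dup) > 0) {
        conflicts <- tibble::tibble(
          scaffold = sub(" .*$", "", dup), side = sub("^.* ", "", dup))
        bad <- paste(sup$a, sup$side_a) %in% dup |
          paste(sup$b, sup$side_b) %in% dup
        sup <- sup[!bad, , drop = FALSE]
      }
    }
    if (nrow(sup) > 0) {
      edits <- merge_path_edits(sup, params)
    }
  }
  plan <- plan_apply_edits(plan_identity(base, source = ".base"), edits)
  out <- plan_sequence(plan, c(list(.base = base), alternates))
  list(assembly = out, edits = edits, conflicts = conflicts)
}

# which terminus of its scaffold a block occupies, given chain direction
terminal_side <- function(b, len, params, outgoing) {
  towards_end <- (b$strand == "+") == outgoing
  if (towards_end) {
    if (len - b$base_end <= params$terminal_window) "end" else NULL
  } else {
    if (b$base_start <= params$terminal_window) "start" else NULL
  }
}

# turn accepted adjacencies into sequential merge edits along simple paths
merge_path_edits <- function(sup, params) {
  edges <- sup
  used <- rep(FALSE, nrow(edges))
  edits <- list()
  # degree per scaffold is at most 2 (one partner per terminus)
  adj <- dplyr::bind_rows(
    tibble::tibble(s = edges$a, side = edges$side_a, e = seq_len(nrow(edges))),
    tibble::tibble(s = edges$b, side = edges$side_b, e = seq_len(nrow(edges))))
  deg <- table(adj$s)
  starts <- names(deg)[deg == 1]
  visited <- character(0)
  for (s0 in sort(starts)) {
    if (s0 %in% visited) next
    # walk the path from s0
    path <- list()
    cur <- s0; prev_edge <- 0L
    repeat {
      visited <- c(visited, cur)
      cand <- adj$e[adj$s == cur & adj$e != prev_edge & !used[adj$e]]
      if (length(cand) == 0) break
      e <- cand[[1]]
      used[e] <- TRUE
      if (edges$a[e] == cur) {
        path[[length(path) + 1L]] <- list(
          from = cur, from_side = edges$side_a[e],
          to = edges$b[e], to_side = edges$side_b[e])
        cur <- edges$b[e]
      } else {
        path[[length(path) + 1L]] <- list(
          from = cur, from_side = edges$side_b[e],
          to = edges$a[e], to_side = edges$side_a[e])
        cur <- edges$a[e]
      }
      prev_edge <- e
    }
    if (length(path) == 0) next
    left_id <- path[[1]]$from
    left_or <- if (path[[1]]$from_side == "end") "+" else "-"
    for (step in path) {
      right_or <- if (step$to_side == "start") "+" else "-"
      new_id <- paste0(left_id, "_", step$to)
      edits[[length(edits) + 1L]] <- tibble::tibble(
        kind = "merge", base_id = left_id, base_start = NA_real_,
        base_end = NA_real_, donor_assembly = ".base", donor_id = step$to,
        donor_start = NA_real_, donor_end = NA_real_,
        donor_strand = right_or, inserted_length = params$join_gap_len,
        rng_draw = NA_integer_, base_or = left_or, donor_or = right_or,
        new_id = new_id, gap_len = params$join_gap_len)
      left_id <- new_id
      left_or <- "+"
    }
  }
  if (length(edits) == 0) empty_edits() else dplyr::bind_rows(edits)
}
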