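# Seeded synthetic scenarios ----------------------------------------------

#' Simulation configuration
#'
#' Describes a synthetic study: a multi-chromosome truth genome; a base
#' assembly derived from it by fragmentation, junction N-gaps (each gap
#' deletes `base_gap_length` truth bp and replaces them with that many N,
#' emulating a scaffolder's size estimate), misplaced fragments (misjoins)
#' and inverted fragments; independently fragmented gap-free alternate
#' assemblies; and BAC-end pairs drawn from the truth.
#'
#' `n_misjoins` counts misplaced fragments: n dedicated fragments of length
#' `misjoin_fragment_length` are excised and their contents rotated across
#' chromosomes, so each misjoined fragment sits at a locus belonging to
#' different truth sequence (0 or >= 2; a single fragment cannot be misplaced
#' while conserving content). Misjoin and inversion junctions always coincide
#' with gaps, as scaffolding joins do.
#'
#' @param seed integer master seed; every simulator operation is a pure
#'   function of the config.
#' @param n_chromosomes,chromosome_length truth genome shape.
#' @param gc_fraction expected GC of random sequence.
#' @param repeat_fraction,repeat_unit_length fraction of each chromosome
#'   covered by exact tandem repeats and the repeat unit size (bp).
#' @param base_n_fragments regular fragments per chromosome in the base
#'   assembly (cut positions uniform at random).
#' @param base_gap_length c(min, max) of uniform junction gap lengths (bp).
#' @param n_misjoins,misjoin_fragment_length misplaced-fragment events and
#'   their length bounds (bp).
#' @param n_inversions,inversion_length strand-flipped fragment events.
#' @param n_scaffold_breaks junctions rendered as scaffold boundaries
#'   instead of gaps (for merge testing).
#' @param n_alternates,alt_n_fragments alternate assemblies and their
#'   fragments per chromosome.
#' @param alt_error_rate per-base substitution rate in alternates (default 0).
#' @param bac_n_pairs,bac_insert_mean,bac_insert_sd,bac_read_length BAC-end
#'   pair sampling (insert ~ Normal truncated positive, inward FR ends).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_chromosomes = 3L,
                       chromosome_length = 1e6, gc_fraction = 0.41,
                       repeat_fraction = 0.05, repeat_unit_length = 20L,
                       base_n_fragments = 8L, base_gap_length = c(100, 900),
                       n_misjoins = 0L,
                       misjoin_fragment_length = c(10000, 20000),
                       n_inversions = 0L, inversion_length = c(10000, 20000),
                       n_scaffold_breaks = 0L, n_alternates = 3L,
                       alt_n_fragments = 3L, alt_error_rate = 0,
                       bac_n_pairs = 2000L, bac_insert_mean = 150000,
                       bac_insert_sd = 20000, bac_read_length = 500L) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = chromosome_length,
              gc_fraction = gc_fraction, repeat_fraction = repeat_fraction,
              repeat_unit_length = as.integer(repeat_unit_length),
              base_n_fragments = as.integer(base_n_fragments),
              base_gap_length = base_gap_length,
              n_misjoins = as.integer(n_misjoins),
              misjoin_fragment_length = misjoin_fragment_length,
              n_inversions = as.integer(n_inversions),
              inversion_length = inversion_length,
              n_scaffold_breaks = as.integer(n_scaffold_breaks),
              n_alternates = as.integer(n_alternates),
              alt_n_fragments = as.integer(alt_n_fragments),
              alt_error_rate = alt_error_rate,
              bac_n_pairs = as.integer(bac_n_pairs),
              bac_insert_mean = bac_insert_mean,
              bac_insert_sd = bac_insert_sd,
              bac_read_length = as.integer(bac_read_length))
  stopifnot(cfg$n_chromosomes >= 1, cfg$chromosome_length >= 1000,
            cfg$gc_fraction >= 0, cfg$gc_fraction <= 1,
            cfg$repeat_fraction >= 0, cfg$repeat_fraction <= 1,
            cfg$base_n_fragments >= 1,
            cfg$base_gap_length[1] <= cfg$base_gap_length[2],
            cfg$misjoin_fragment_length[1] <= cfg$misjoin_fragment_length[2],
            cfg$inversion_length[1] <= cfg$inversion_length[2],
            cfg$n_misjoins >= 0, cfg$n_inversions >= 0,
            cfg$n_alternates >= 0, cfg$alt_n_fragments >= 1,
            cfg$bac_insert_mean + 4 * cfg$bac_insert_sd <
              cfg$chromosome_length)
  if (cfg$n_misjoins == 1) {
    stop("n_misjoins must be 0 or >= 2: one fragment cannot be misplaced ",
         "while conserving genome content")
  }
  if (cfg$n_misjoins > 0 && cfg$base_n_fragments < 2) {
    stop("base_n_fragments must be >= 2 when n_misjoins > 0")
  }
  class(cfg) <- "sim_config"
  cfg
}

rand_dna <- function(n, gc) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE,
                                             prob = probs)])
}

#' Generate a seeded truth genome
#'
#' I.i.d. bases at the configured GC fraction with interspersed exact tandem
#' repeat tracts covering `repeat_fraction` of each chromosome.
#'
#' @param config a [sim_config()].
#' @return an `asm_set` of chromosomes `chr1..chrN`.
#' @export
generate_truth <- function(config) {
  withr::with_seed(config$seed, {
    L <- as.integer(config$chromosome_length)
    seqs <- vapply(seq_len(config$n_chromosomes), function(ci) {
      s <- rand_dna(L, config$gc_fraction)
      target <- config$repeat_fraction * L
      if (target >= config$repeat_unit_length * 2) {
        covered <- 0
        used <- matrix(numeric(0), ncol = 2)
        guard <- 0L
        while (covered < target && guard < 10000L) {
          guard <- guard + 1L
          tract <- min(sample(500:2000, 1L), ceiling(target - covered))
          tract <- max(tract, 2L * config$repeat_unit_length)
          p <- sample.int(L - tract, 1L)
          if (nrow(used) > 0 &&
              any(p < used[, 2] & (p + tract) > used[, 1])) next
          unit <- rand_dna(config$repeat_unit_length, config$gc_fraction)
          rep_seq <- strrep(unit, ceiling(tract / nchar(unit)))
          substr(s, p + 1L, p + tract) <- substr(rep_seq, 1L, tract)
          used <- rbind(used, c(p, p + tract))
          covered <- covered + tract
        }
      }
      s
    }, character(1))
    names(seqs) <- paste0("chr", seq_len(config$n_chromosomes))
    as_assembly(seqs)
  })
}

# choose a special fragment [p, p+len) on chromosome `ci`, away from margins
# and existing special intervals
pick_interval <- function(L, len, margin, used) {
  for (i in 1:1000) {
    p <- sample.int(L - len - 2 * margin, 1L) + margin
    if (length(used) == 0 ||
        !any(p < used[, 2] + margin & (p + len) > used[, 1] - margin)) {
      return(c(p, p + len))
    }
  }
  stop("could not place a special fragment; too many events requested")
}

#' Corrupt the truth into a gapped base assembly
#'
#' Cuts each chromosome into fragments, rejoins them in order with junction
#' N-gaps (each gap deletes sampled truth bp around the cut and inserts that
#' many N), then misplaces `n_misjoins` dedicated fragments by rotating their
#' contents across chromosomes and strand-flips `n_inversions` fragments.
#' Every junction, including misjoin and inversion boundaries, carries a gap;
#' selected junctions can instead become scaffold breaks.
#'
#' @param truth truth genome from [generate_truth()].
#' @param config the same [sim_config()].
#' @return a list with `assembly` (the base), and `truth_record`: `liftover`
#'   (segments tiling the base; see [compose_liftover()]), `gaps`,
#'   `junctions` (per-junction kind and position), `misjoins` and
#'   `inversions` (per-event slot coordinates on the base and truth
#'   provenance).
#' @export
corrupt_to_base <- function(truth, config) {
  truth <- as_assembly(truth)
  withr::with_seed(config$seed + 1L, {
    L <- as.integer(config$chromosome_length)
    chroms <- names(truth)
    nc <- length(chroms)
    margin <- 50000L
    # 1. dedicated misjoin / inversion fragments
    specials <- list()
    used <- stats::setNames(rep(list(matrix(numeric(0), ncol = 2)), nc),
                            chroms)
    assign_chrom <- function(i) chroms[((i - 1L) %% nc) + 1L]
    for (ei in seq_len(config$n_misjoins)) {
      ch <- assign_chrom(ei)
      len <- round(stats::runif(1, config$misjoin_fragment_length[1],
                                config$misjoin_fragment_length[2]))
      iv <- pick_interval(L, len, margin, used[[ch]])
      used[[ch]] <- rbind(used[[ch]], iv)
      specials[[length(specials) + 1L]] <- tibble::tibble(
        chrom = ch, start = iv[1], end = iv[2], kind = "misjoin", event = ei)
    }
    for (ei in seq_len(config$n_inversions)) {
      ch <- assign_chrom(config$n_misjoins + ei)
      len <- round(stats::runif(1, config$inversion_length[1],
                                config$inversion_length[2]))
      iv <- pick_interval(L, len, margin, used[[ch]])
      used[[ch]] <- rbind(used[[ch]], iv)
      specials[[length(specials) + 1L]] <- tibble::tibble(
        chrom = ch, start = iv[1], end = iv[2], kind = "inversion",
        event = ei)
    }
    specials <- dplyr::bind_rows(specials)
    # 2. regular cuts + fragment tables per chromosome
    frags <- list()
    for (ch in chroms) {
      sp <- if (nrow(specials) > 0) {
        specials[specials$chrom == ch, , drop = FALSE]
      } else specials
      bounds <- sort(unique(c(0L, if (nrow(sp) > 0) c(sp$start, sp$end), L)))
      ncut <- config$base_n_fragments - 1L
      cuts <- integer(0)
      guard <- 0L
      while (length(cuts) < ncut && guard < 10000L) {
        guard <- guard + 1L
        p <- sample.int(L - 2L, 1L) + 1L
        if (any(abs(p - c(bounds, cuts)) < 2000)) next
        if (nrow(sp) > 0 && any(p > sp$start & p < sp$end)) next
        cuts <- c(cuts, p)
      }
      bounds <- sort(unique(c(bounds, cuts)))
      f <- tibble::tibble(
        chrom = ch, start = bounds[-length(bounds)], end = bounds[-1])
      f$kind <- "normal"; f$event <- NA_integer_
      if (nrow(sp) > 0) {
        for (i in seq_len(nrow(sp))) {
          hit <- f$start == sp$start[i] & f$end == sp$end[i]
          f$kind[hit] <- sp$kind[i]; f$event[hit] <- sp$event[i]
        }
      }
      # content initially equals own truth interval on the forward strand
      f$src_chrom <- f$chrom; f$src_start <- f$start; f$src_end <- f$end
      f$strand <- "+"
      frags[[ch]] <- f
    }
    allf <- dplyr::bind_rows(frags)
    # 3. rotate misjoin contents across events; flip inversions
    mj <- which(allf$kind == "misjoin")
    mj <- mj[order(allf$event[mj])]
    if (length(mj) >= 2) {
      rot <- c(mj[-1], mj[1])
      allf$src_chrom[mj] <- allf$chrom[rot]
      allf$src_start[mj] <- allf$start[rot]
      allf$src_end[mj] <- allf$end[rot]
    }
    allf$strand[allf$kind == "inversion"] <- "-"
    # 4. scaffold breaks: pick junctions (not adjacent to special fragments)
    junction_index <- function(f) seq_len(nrow(f) - 1L)
    breaks <- list()
    if (config$n_scaffold_breaks > 0) {
      cand <- list()
      for (ch in chroms) {
        f <- allf[allf$chrom == ch, , drop = FALSE]
        for (j in junction_index(f)) {
          if (f$kind[j] == "normal" && f$kind[j + 1L] == "normal") {
            cand[[length(cand) + 1L]] <- c(ch = ch, j = j)
          }
        }
      }
      pick <- sample.int(length(cand),
                         min(config$n_scaffold_breaks, length(cand)))
      breaks <- cand[pick]
    }
    # 5. assemble scaffolds with junction gaps; record liftover + events
    seqs <- character(0)
    lift <- list(); gaps <- list(); juncs <- list()
    mis_rows <- list(); inv_rows <- list()
    for (ch in chroms) {
      f <- allf[allf$chrom == ch, , drop = FALSE]
      brk <- vapply(breaks, function(b)
        if (b[["ch"]] == ch) as.integer(b[["j"]]) else NA_integer_,
        integer(1))
      brk <- brk[!is.na(brk)]
      # junction deletions: each gap removes d truth bp (half from each
      # flanking fragment's content) and inserts d N
      d <- round(stats::runif(nrow(f) - 1L, config$base_gap_length[1],
                              config$base_gap_length[2]))
      s0v <- f$src_start; s1v <- f$src_end
      for (i in seq_len(nrow(f))) {
        if (i > 1L) {              # right side of junction i-1
          dr <- ceiling(d[i - 1L] / 2)
          if (f$strand[i] == "+") s0v[i] <- s0v[i] + dr
          else s1v[i] <- s1v[i] - dr
        }
        if (i < nrow(f)) {         # left side of junction i
          dl <- floor(d[i] / 2)
          if (f$strand[i] == "+") s1v[i] <- s1v[i] - dl
          else s0v[i] <- s0v[i] + dl
        }
      }
      scaf_no <- 1L
      pos <- 0
      sid <- paste0(ch, "_scaf", scaf_no)
      pieces <- character(0)
      for (i in seq_len(nrow(f))) {
        fr <- f[i, ]
        s0 <- s0v[i]; s1 <- s1v[i]
        piece <- substring(unclass(truth)[[fr$src_chrom]], s0 + 1L, s1)
        if (fr$strand == "-") piece <- revcomp(piece)
        pieces <- c(pieces, piece)
        lift[[length(lift) + 1L]] <- tibble::tibble(
          seq_id = sid, seg_start = pos, seg_end = pos + (s1 - s0),
          truth_chrom = fr$src_chrom, truth_start = s0, truth_end = s1,
          strand = fr$strand)
        slot_start <- pos
        pos <- pos + (s1 - s0)
        if (fr$kind == "misjoin") {
          mis_rows[[length(mis_rows) + 1L]] <- tibble::tibble(
            event = fr$event, scaffold_id = sid,
            slot_start = slot_start, slot_end = pos,
            home_chrom = fr$chrom, home_start = fr$start, home_end = fr$end,
            src_chrom = fr$src_chrom, src_start = s0, src_end = s1)
        }
        if (fr$kind == "inversion") {
          inv_rows[[length(inv_rows) + 1L]] <- tibble::tibble(
            event = fr$event, scaffold_id = sid,
            slot_start = slot_start, slot_end = pos,
            src_chrom = fr$src_chrom, src_start = s0, src_end = s1)
        }
        if (i < nrow(f)) {
          if (i %in% brk) {       # scaffold boundary instead of a gap
            seqs[sid] <- paste0(pieces, collapse = "")
            pieces <- character(0)
            scaf_no <- scaf_no + 1L
            sid <- paste0(ch, "_scaf", scaf_no)
            pos <- 0
          } else {
            gl <- d[i]
            pieces <- c(pieces, strrep("N", gl))
            lift[[length(lift) + 1L]] <- tibble::tibble(
              seq_id = sid, seg_start = pos, seg_end = pos + gl,
              truth_chrom = NA_character_, truth_start = NA_real_,
              truth_end = NA_real_, strand = "+")
            gaps[[length(gaps) + 1L]] <- tibble::tibble(
              scaffold_id = sid, start = pos, end = pos + gl, length = gl)
            kind_j <- if (f$kind[i] != "normal") f$kind[i]
              else if (f$kind[i + 1L] != "normal") f$kind[i + 1L]
              else "normal"
            plain <- f$kind[i] == "normal" && f$kind[i + 1L] == "normal" &&
              f$strand[i] == "+" && f$strand[i + 1L] == "+" &&
              f$src_chrom[i] == f$src_chrom[i + 1L]
            juncs[[length(juncs) + 1L]] <- tibble::tibble(
              scaffold_id = sid, pos = pos + floor(gl / 2), kind = kind_j,
              left_kind = f$kind[i], right_kind = f$kind[i + 1L],
              del_chrom = if (plain) f$src_chrom[i] else NA_character_,
              del_start = if (plain) s1v[i] else NA_real_,
              del_end = if (plain) s0v[i + 1L] else NA_real_)
            pos <- pos + gl
          }
        }
      }
      seqs[sid] <- paste0(pieces, collapse = "")
    }
    list(assembly = as_assembly(seqs),
         truth_record = list(
           liftover = dplyr::bind_rows(lift),
           gaps = dplyr::bind_rows(gaps),
           junctions = dplyr::bind_rows(juncs),
           misjoins = dplyr::bind_rows(mis_rows),
           inversions = dplyr::bind_rows(inv_rows)))
  })
}

#' Generate independently fragmented alternate assemblies
#'
#' Each alternate is a seeded fragmentation of the truth into gap-free
#' contigs (no misjoins); cut positions are independent across alternates so
#' most base junctions are spanned by at least two alternates. An optional
#' per-base substitution rate stresses anchor matching.
#'
#' @inheritParams corrupt_to_base
#' @return a named list (`alt1..altN`) of lists with `assembly` and
#'   `liftover`.
#' @export
make_alternates <- function(truth, config) {
  truth <- as_assembly(truth)
  out <- list()
  for (ai in seq_len(config$n_alternates)) {
    out[[paste0("alt", ai)]] <- withr::with_seed(config$seed + 100L + ai, {
      seqs <- character(0); lift <- list()
      for (ch in names(truth)) {
        L <- nchar(unclass(truth)[[ch]])
        ncut <- config$alt_n_fragments - 1L
        cuts <- if (ncut > 0) sort(sample.int(L - 2L, ncut) + 1L) else
          integer(0)
        bounds <- c(0L, cuts, L)
        for (j in seq_len(length(bounds) - 1L)) {
          cid <- paste0("alt", ai, "_", ch, ".", j)
          s <- substring(unclass(truth)[[ch]], bounds[j] + 1L, bounds[j + 1L])
          if (config$alt_error_rate > 0) {
            nmut <- stats::rbinom(1L, nchar(s), config$alt_error_rate)
            if (nmut > 0) {
              at <- sample.int(nchar(s), nmut)
              for (p in at) {
                substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                                  substr(s, p, p)), 1L)
              }
            }
          }
          seqs[cid] <- s
          lift[[length(lift) + 1L]] <- tibble::tibble(
            seq_id = cid, seg_start = 0, seg_end = bounds[j + 1L] - bounds[j],
            truth_chrom = ch, truth_start = bounds[j],
            truth_end = bounds[j + 1L], strand = "+")
        }
      }
      list(assembly = as_assembly(seqs), liftover = dplyr::bind_rows(lift))
    })
  }
  out
}

#' Sample BAC-end pairs from the truth genome
#'
#' Insert sizes are Normal(`bac_insert_mean`, `bac_insert_sd`) truncated
#' positive (and to the chromosome); ends are inward-facing FR reads of
#' `bac_read_length` bp recorded in truth coordinates. Project them onto any
#' assembly with [project_pairs()].
#'
#' @inheritParams corrupt_to_base
#' @return a tibble of truth placements: `pair_id`, `chrom`, `start1`
#'   (forward read, 0-based), `start2` (reverse read), `insert`.
#' @export
sample_bac_pairs <- function(truth, config) {
  truth <- as_assembly(truth)
  withr::with_seed(config$seed + 50L, {
    lens <- seq_lengths(truth)
    rl <- config$bac_read_length
    n <- config$bac_n_pairs
    chrom <- sample(names(lens), n, replace = TRUE,
                    prob = lens / sum(lens))
    lo <- 4 * rl
    ins <- round(stats::rnorm(n, config$bac_insert_mean,
                              config$bac_insert_sd))
    for (i in seq_len(n)) {
      while (ins[i] < lo || ins[i] > lens[[chrom[i]]]) {
        ins[i] <- round(stats::rnorm(1, config$bac_insert_mean,
                                     config$bac_insert_sd))
      }
    }
    start <- floor(stats::runif(n) * (lens[chrom] - ins + 1))
    tibble::tibble(pair_id = sprintf("bac%05d", seq_len(n)), chrom = chrom,
                   start1 = as.numeric(start),
                   start2 = as.numeric(start + ins - rl),
                   insert = as.numeric(ins))
  })
}

#' Project truth BAC placements onto an assembly
#'
#' Exact placement through a truth liftover (no alignment): an end maps iff
#' its read interval lies wholly inside one liftover segment; ends falling in
#' deleted (gap) sequence or across segment boundaries are unmapped.
#'
#' @param placements tibble from [sample_bac_pairs()].
#' @param liftover the target assembly's liftover (see [compose_liftover()]).
#' @param read_length read length used when sampling.
#' @return a pair tibble as in [read_pairs_tsv()] (mapq 60 for mapped ends).
#' @export
project_pairs <- function(placements, liftover, read_length = 500L) {
  p1 <- liftover_project(liftover, placements$chrom, placements$start1,
                         read_length)
  p2 <- liftover_project(liftover, placements$chrom, placements$start2,
                         read_length)
  flip <- function(s) ifelse(s == "+", "-", "+")
  tibble::tibble(
    pair_id = placements$pair_id,
    id1 = p1$seq_id, pos1 = p1$pos, strand1 = p1$strand,
    mapq1 = ifelse(is.na(p1$seq_id), NA_integer_, 60L),
    id2 = p2$seq_id, pos2 = p2$pos, strand2 = flip(p2$strand),
    mapq2 = ifelse(is.na(p2$seq_id), NA_integer_, 60L))
}

#' Simulate a full reconciliation scenario
#'
#' Convenience wrapper: truth genome, corrupted base, alternates and BAC
#' pairs, all from one config.
#'
#' @param config a [sim_config()].
#' @return a list with `truth`, `base`, `truth_record`, `alternates` (named
#'   list of assemblies), `alt_liftovers`, `bac_placements` and `config`.
#' @export
simulate_scenario <- function(config) {
  truth <- generate_truth(config)
  cb <- corrupt_to_base(truth, config)
  alts <- make_alternates(truth, config)
  bac <- sample_bac_pairs(truth, config)
  list(truth = truth, base = cb$assembly, truth_record = cb$truth_record,
       alternates = purrr::map(alts, "assembly"),
       alt_liftovers = purrr::map(alts, "liftover"),
       bac_placements = bac, config = config)
}

#' Standard study-scale scenario configuration
#'
#' The package's reference simulation: 3 chromosomes of 1 Mb, 3 alternate
#' assemblies, 5 misplaced-fragment misjoins, ~30 junction gaps of 100-900 bp
#' (mean ~500 bp, the scale of real scaffold gaps), BAC inserts
#' Normal(150 kb, 20 kb).
#'
#' @param seed master seed.
#' @return a [sim_config()].
#' @export
standard_scenario_config <- function(seed = 1L) {
  sim_config(seed = seed, n_chromosomes = 3L, chromosome_length = 1e6,
             base_n_fragments = 8L, n_misjoins = 5L, n_alternates = 3L,
             alt_n_fragments = 3L)
}

#' Write a simulated scenario to disk
#'
#' FASTA per assembly, truth records as JSON and BED (junctions on the base),
#' and BAC pairs projected onto the base as the validation TSV.
#'
#' @param scn output of [simulate_scenario()].
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_scenario <- function(scn, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_assembly(scn$truth, file.path(out_dir, "truth.fasta"))
  write_assembly(scn$base, file.path(out_dir, "base.fasta"))
  for (nm in names(scn$alternates)) {
    write_assembly(scn$alternates[[nm]],
                   file.path(out_dir, paste0(nm, ".fasta")))
  }
  jsonlite::write_json(scn$truth_record,
                       file.path(out_dir, "truth_record.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  j <- scn$truth_record$junctions
  writeLines(paste(j$scaffold_id, j$pos, j$pos + 1, j$kind, sep = "\t"),
             file.path(out_dir, "junctions.bed"))
  pairs <- project_pairs(scn$bac_placements, scn$truth_record$liftover,
                         scn$config$bac_read_length)
  write_pairs_tsv(pairs, file.path(out_dir, "bac_pairs_on_base.tsv"))
  invisible(out_dir)
}
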