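micro_params <- function() {
  list(ap = align_params(k = 11, window = 2, min_block_len = 50,
                         gap_limit = 2000, diag_limit = 500),
       rp = reconcile_params(gap_window = 500, merge_window = 500,
                             flank = 200, min_continuation = 100,
                             anchor_search = 2000, max_span = 5000))
}

test_that("a gap aligned to a gap-free alternate region is filled with truth", {
  p <- micro_params()
  truth <- rand_seq(4000, seed = 21)
  base <- as_assembly(c(s = paste0(substring(truth, 1, 1950), strrep("N", 100),
                                   substring(truth, 2051, 4000))))
  alt <- as_assembly(c(d = truth))
  aln <- list(alt1 = align_assemblies(base, alt, p$ap, alt_name = "alt1"))
  res <- fill_gaps(base, list(alt1 = alt), aln, params = p$rp, rng_seed = 1,
                   k = p$ap$k)
  expect_equal(res$n_gaps_filled, 1L)
  expect_equal(res$filled_gap_total_length, 100)
  expect_equal(unclass(res$assembly)[["s"]], truth)
  expect_equal(res$edits$kind, "gap_fill")
  expect_equal(res$edits$rng_draw, 1L)
})

test_that("a donor region that itself contains N cannot fill a gap", {
  p <- micro_params()
  truth <- rand_seq(4000, seed = 22)
  base <- as_assembly(c(s = paste0(substring(truth, 1, 1950), strrep("N", 100),
                                   substring(truth, 2051, 4000))))
  alt_n <- paste0(substring(truth, 1, 1990), strrep("N", 20),
                  substring(truth, 2011, 4000))
  aln <- list(alt1 = align_assemblies(base, as_assembly(c(d = alt_n)), p$ap,
                                      alt_name = "alt1"))
  res <- fill_gaps(base, list(alt1 = as_assembly(c(d = alt_n))), aln,
                   params = p$rp, rng_seed = 1, k = p$ap$k)
  expect_equal(res$n_gaps_filled, 0L)
  expect_equal(res$unfilled$reason, "donor_has_gap")
  expect_equal(unclass(res$assembly)[["s"]], unclass(base)[["s"]])
})

test_that("misjoin calls are actionable only with two agreeing alternates", {
  scn <- get_scn("misjoin")
  aln_true <- purrr::imap(scn$alternates, ~ align_assemblies(scn$base, .x,
                                                             alt_name = .y))
  gaps <- find_gaps(scn$base)
  calls <- call_breakpoints(scn$base, gaps, aln_true)
  expect_true(all(calls$actionable))
  expect_true(all(calls$n_discrepant_agreeing >= 2))

  # with one informative alternate and two base copies, the candidate is
  # called but fails check B
  mixed <- list(alt1 = aln_true[[1]],
                self1 = align_assemblies(scn$base, scn$base,
                                         alt_name = "self1"),
                self2 = align_assemblies(scn$base, scn$base,
                                         alt_name = "self2"))
  calls1 <- call_breakpoints(scn$base, gaps, mixed)
  expect_gt(nrow(calls1), 0)
  expect_true(all(!calls1$actionable))
  expect_true(all(calls1$n_discrepant_agreeing <= 1))
  ev <- calls1$evidence[[1]]
  expect_equal(unname(ev[c("self1", "self2")]),
               c("consistent_with_base", "consistent_with_base"))
})

test_that("breakpoint calling rejects unknown base scaffolds", {
  scn <- get_scn("gapfill")
  bl <- align_assemblies(scn$base, scn$alternates[[1]])
  bl$base_id <- "nonexistent"
  expect_error(
    call_breakpoints(scn$base, find_gaps(scn$base), list(a = bl)),
    "unknown base scaffold")
})

test_that("every misjoined locus is restored to truth by block replacement", {
  scn <- get_scn("misjoin")
  rec <- get_recon("misjoin")
  mis <- scn$truth_record$misjoins
  expect_equal(rec$report$n_actionable, rec$report$n_breakpoints_called)
  expect_gte(rec$report$n_blocks_replaced, nrow(mis) - 1)
  hl <- hybrid_liftover(rec, scn)
  for (i in seq_len(nrow(mis))) {
    m <- mis[i, ]
    w <- (m$home_end - m$home_start) - 30
    pr <- liftover_project(hl, m$home_chrom, m$home_start + 15, w)
    expect_false(is.na(pr$seq_id))
    hseq <- substring(unclass(rec$hybrid)[[pr$seq_id]], pr$pos + 1, pr$pos + w)
    tseq <- substring(unclass(scn$truth)[[m$home_chrom]], m$home_start + 16,
                      m$home_start + 15 + w)
    if (pr$strand == "-") tseq <- revcomp(tseq)
    expect_identical(hseq, tseq)
  }
})

test_that("gap count and N length never increase; contig N50 never drops", {
  scn <- get_scn("misjoin")
  rec <- get_recon("misjoin")
  st0 <- compute_stats(scn$base)
  st1 <- compute_stats(rec$hybrid)
  expect_lte(st1$n_gaps, st0$n_gaps)
  expect_lte(st1$gap_total_length, st0$gap_total_length)
  expect_gte(st1$contig_n50, st0$contig_n50)
  expect_lt(st1$n_gaps, st0$n_gaps)  # this scenario does fill gaps
})

test_that("edit replay reconstructs the hybrid from base and donors alone", {
  scn <- get_scn("misjoin")
  rec <- get_recon("misjoin")
  ed <- tidy(rec)
  expect_true(all(ed$kind %in% c("block_replacement", "gap_fill")))
  # independent replay: apply edits right-to-left with plain substring ops
  seqs <- unclass(scn$base)
  for (stage in c("replace", "fill")) {
    se <- ed[ed$stage == stage, , drop = FALSE]
    se <- se[order(se$base_id, -se$base_start), , drop = FALSE]
    for (i in seq_len(nrow(se))) {
      e <- se[i, ]
      donor <- substring(unclass(scn$alternates[[e$donor_assembly]])[[e$donor_id]],
                         e$donor_start + 1, e$donor_end)
      if (e$donor_strand == "-") donor <- revcomp(donor)
      s <- seqs[[e$base_id]]
      seqs[[e$base_id]] <- paste0(substring(s, 1, e$base_start), donor,
                                  substring(s, e$base_end + 1, nchar(s)))
    }
  }
  expect_identical(seqs[sort(names(seqs))],
                   unclass(rec$hybrid)[sort(names(rec$hybrid))])
})

test_that("inverted fragments are detected and corrected", {
  scn <- get_scn("inversion")
  rec <- get_recon("inversion")
  inv <- scn$truth_record$inversions
  expect_equal(rec$report$n_blocks_replaced, nrow(inv))
  hl <- hybrid_liftover(rec, scn)
  for (i in seq_len(nrow(inv))) {
    m <- inv[i, ]
    w <- (m$src_end - m$src_start) - 30
    pr <- liftover_project(hl, m$src_chrom, m$src_start + 15, w)
    expect_false(is.na(pr$seq_id))
    expect_equal(pr$strand, "+")  # no longer inverted
  }
})

test_that("reconciliation with identical assemblies is the identity", {
  scn <- get_scn("gapfill")
  rec <- reconcile_assemblies(scn$base,
                              list(a1 = scn$base, a2 = scn$base), seed = 9)
  expect_equal(nrow(tidy(rec)), 0L)
  expect_identical(unclass(rec$hybrid)[sort(names(rec$hybrid))],
                   unclass(scn$base)[sort(names(scn$base))])
  expect_equal(rec$report$n_breakpoints_called, 0L)
})

test_that("the pipeline is deterministic under a seed and converges", {
  scn <- get_scn("misjoin")
  rec1 <- get_recon("misjoin")
  rec2 <- reconcile_assemblies(scn$base, scn$alternates, seed = 1)
  expect_identical(unclass(rec1$hybrid), unclass(rec2$hybrid))
  expect_identical(tidy(rec1), tidy(rec2))

  # a second pass over the hybrid makes no more edits than the first
  rec3 <- reconcile_assemblies(rec1$hybrid, scn$alternates, seed = 1)
  expect_lte(nrow(tidy(rec3)), nrow(tidy(rec1)))
})

test_that("fewer than two alternates is refused with an explanation", {
  scn <- get_scn("gapfill")
  expect_error(reconcile_assemblies(scn$base, list(a = scn$alternates[[1]])),
               "at least 2 alternate")
})

test_that("scaffolds bridged by two alternates merge with truth orientation", {
  scn <- get_scn("brk")
  expect_equal(length(scn$base), 2L)
  aln <- purrr::imap(scn$alternates, ~ align_assemblies(scn$base, .x,
                                                        alt_name = .y))
  res <- merge_scaffolds(scn$base, scn$alternates, aln,
                         reconcile_params(min_merge_len = 1e4))
  expect_equal(nrow(res$edits), 1L)
  expect_equal(length(res$assembly), 1L)
  merged <- unclass(res$assembly)[[1]]
  # the merged scaffold is collinear with truth: both halves in truth order
  plan <- asmrec:::plan_apply_edits(
    asmrec:::plan_identity(scn$base, ".base"), res$edits)
  lo <- compose_liftover(plan, list(.base = scn$truth_record$liftover))
  seg <- lo[!is.na(lo$truth_chrom), ]
  expect_true(all(seg$strand == "+") || all(seg$strand == "-"))
  ts <- if (seg$strand[1] == "+") seg$truth_start else rev(seg$truth_start)
  expect_true(all(diff(ts) > 0))
  expect_true(grepl(strrep("N", 100), merged, fixed = TRUE))

  # a single supporting alternate is not enough
  res1 <- merge_scaffolds(scn$base, scn$alternates[1], aln[1],
                          reconcile_params(min_merge_len = 1e4))
  expect_equal(nrow(res1$edits), 0L)
})

test_that("conflicting merge partners cancel the merge and are reported", {
  blmk <- function(alt, cid, bid, bs, be, as_, ae, alen) tibble::tibble(
    base_id = bid, base_start = bs, base_end = be, alt_assembly_name = alt,
    alt_id = cid, alt_start = as_, alt_end = ae, strand = "+",
    n_anchors = 10L, score = be - bs, base_len = 50000, alt_len = alen,
    anchors = list(NULL))
  base <- as_assembly(stats::setNames(
    c(rand_seq(50000, seed = 31), rand_seq(50000, seed = 32),
      rand_seq(50000, seed = 33)), c("A", "B", "C")))
  # both alternates say A-end joins B-start, but alt2 also says A-end joins C
  aln <- list(
    a1 = dplyr::bind_rows(blmk("a1", "x", "A", 20000, 50000, 0, 30000, 60000),
                          blmk("a1", "x", "B", 0, 30000, 30000, 60000, 60000)),
    a2 = dplyr::bind_rows(blmk("a2", "y", "A", 20000, 50000, 0, 30000, 60000),
                          blmk("a2", "y", "C", 0, 30000, 30000, 60000, 60000),
                          blmk("a2", "z", "A", 25000, 50000, 0, 25000, 55000),
                          blmk("a2", "z", "B", 0, 30000, 25000, 55000, 55000)))
  res <- merge_scaffolds(base, list(), aln,
                         reconcile_params(min_merge_len = 1e4,
                                          min_merge_evidence = 1))
  expect_equal(nrow(res$edits), 0L)
  expect_gt(nrow(res$conflicts), 0L)
})
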