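test_that("truth genomes hit the configured GC and are reproducible", {
  cfg <- sim_config(seed = 1, n_chromosomes = 1, chromosome_length = 1e5,
                    gc_fraction = 0.5, repeat_fraction = 0,
                    bac_insert_mean = 20000, bac_insert_sd = 2000)
  tr <- generate_truth(cfg)
  s <- unclass(tr)[["chr1"]]
  gc <- (nchar(gsub("[AT]", "", s))) / nchar(s)
  expect_gt(gc, 0.48)
  expect_lt(gc, 0.52)
  expect_identical(unclass(generate_truth(cfg)), unclass(tr))
})

test_that("event-free corruption is the truth with junction deletions and N", {
  scn <- get_scn("gapfill")
  lo <- scn$truth_record$liftover
  # liftover segments tile the base exactly
  lens <- tapply(lo$seg_end - lo$seg_start, lo$seq_id, sum)
  expect_equal(as.numeric(lens[names(scn$base)]),
               unname(nchar(unclass(scn$base))))
  # every non-gap segment carries the exact truth sequence
  seg <- lo[!is.na(lo$truth_chrom), ]
  for (i in seq_len(nrow(seg))) {
    s <- seg[i, ]
    expect_identical(
      substring(unclass(scn$base)[[s$seq_id]], s$seg_start + 1, s$seg_end),
      substring(unclass(scn$truth)[[s$truth_chrom]], s$truth_start + 1,
                s$truth_end))
  }
  # gap count equals junction count, N length equals deleted truth length
  g <- find_gaps(scn$base)
  expect_equal(nrow(g), nrow(scn$truth_record$junctions))
  expect_equal(g$length,
               scn$truth_record$gaps$length[order(scn$truth_record$gaps$scaffold_id,
                                                  scn$truth_record$gaps$start)])
  j <- scn$truth_record$junctions
  expect_equal(sum(j$del_end - j$del_start), sum(g$length))
})

test_that("misjoined fragments lift to a different chromosome than home", {
  scn <- get_scn("misjoin")
  mis <- scn$truth_record$misjoins
  expect_equal(nrow(mis), 2L)
  expect_true(all(mis$src_chrom != mis$home_chrom))
  # the misplaced content is present verbatim at the slot
  for (i in seq_len(nrow(mis))) {
    m <- mis[i, ]
    expect_identical(
      substring(unclass(scn$base)[[m$scaffold_id]], m$slot_start + 1,
                m$slot_end),
      substring(unclass(scn$truth)[[m$src_chrom]], m$src_start + 1,
                m$src_end))
  }
  # junctions flanking each slot join sequence from different chromosomes
  jk <- scn$truth_record$junctions
  expect_equal(sum(jk$kind == "misjoin"), 2L * nrow(mis))
})

test_that("alternate contigs partition the truth and are seed-stable", {
  scn <- get_scn("gapfill")
  for (nm in names(scn$alternates)) {
    alt <- scn$alternates[[nm]]
    lo <- scn$alt_liftovers[[nm]]
    rebuilt <- tapply(
      unclass(alt)[lo$seq_id[order(lo$truth_start)]],
      lo$truth_chrom[order(lo$truth_start)],
      function(x) paste0(x, collapse = ""))
    for (ch in names(scn$truth)) {
      expect_identical(rebuilt[[ch]], unclass(scn$truth)[[ch]])
    }
  }
  again <- make_alternates(scn$truth, scn$config)
  expect_identical(unclass(again[[1]]$assembly),
                   unclass(scn$alternates[[1]]))
})

test_that("BAC inserts follow the configured truncated normal", {
  cfg <- sim_config(seed = 3, n_chromosomes = 1, chromosome_length = 1e6,
                    bac_n_pairs = 1000, bac_insert_mean = 150000,
                    bac_insert_sd = 20000)
  tr <- generate_truth(cfg)
  bac <- sample_bac_pairs(tr, cfg)
  expect_equal(nrow(bac), 1000L)
  # CLT bound: |mean - 150k| < 3 * sd / sqrt(n)
  expect_lt(abs(mean(bac$insert) - 150000), 3 * 20000 / sqrt(1000))
  # projected onto the truth itself every pair is concordant
  pairs <- project_pairs(bac, truth_self_liftover(tr), cfg$bac_read_length)
  cls <- classify_pairs(pairs, min_insert = 150000 - 4 * 20000,
                        max_insert = 150000 + 4 * 20000,
                        read_length = cfg$bac_read_length)
  expect_true(all(cls$verdict == "concordant"))
})

test_that("pairs straddling a misjoin project discordantly onto the base", {
  scn <- get_scn("misjoin")
  pairs <- project_pairs(scn$bac_placements, scn$truth_record$liftover,
                         scn$config$bac_read_length)
  cls <- classify_pairs(pairs, read_length = scn$config$bac_read_length)
  mis <- scn$truth_record$misjoins
  rl <- scn$config$bac_read_length
  # pairs with one end in the displaced fragment's home locus and the other
  # outside it land on different scaffolds
  straddle <- rep(FALSE, nrow(scn$bac_placements))
  for (i in seq_len(nrow(mis))) {
    m <- mis[i, ]
    p <- scn$bac_placements
    in1 <- p$chrom == m$home_chrom & p$start1 + rl > m$home_start &
      p$start1 < m$home_end
    in2 <- p$chrom == m$home_chrom & p$start2 + rl > m$home_start &
      p$start2 < m$home_end
    straddle <- straddle | (xor(in1, in2) & p$chrom == m$home_chrom)
  }
  hit <- cls$verdict[straddle]
  # ends falling into junction deletions are unmapped, not discordant
  hit <- hit[!hit %in% c("single_end", "unaligned")]
  expect_gt(length(hit), 0)
  expect_true(all(hit == "discordant"))
})

test_that("the simulator is a pure function of its config", {
  cfg <- sim_config(seed = 23, n_chromosomes = 2, chromosome_length = 2e5,
                    base_n_fragments = 4, n_misjoins = 2,
                    bac_insert_mean = 30000, bac_insert_sd = 4000,
                    bac_n_pairs = 50)
  s1 <- simulate_scenario(cfg)
  s2 <- simulate_scenario(cfg)
  expect_identical(unclass(s1$base), unclass(s2$base))
  expect_identical(s1$truth_record, s2$truth_record)
  expect_identical(s1$bac_placements, s2$bac_placements)
})

test_that("misjoin counts of one are rejected; zero is allowed", {
  expect_error(sim_config(n_misjoins = 1), "conserving")
  expect_s3_class(sim_config(n_misjoins = 0), "sim_config")
})
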