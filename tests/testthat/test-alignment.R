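test_that("minimizer sketch with window 1 keeps every k-mer position", {
  sk <- sketch_minimizers("ACGTACGTACGT", k = 4, window = 1)
  expect_equal(sk$pos, 0:8)
})

test_that("repetitive k-mers are dropped from the anchor index", {
  polyA <- c(r = strrep("A", 500))
  probe <- c(q = strrep("A", 100))
  anc <- find_anchors(probe, polyA, align_params(k = 11, window = 1,
                                                 max_occ = 2))
  expect_equal(nrow(anc), 0L)
})

test_that("self-alignment gives one full-length forward block per scaffold", {
  asm <- as_assembly(c(s1 = rand_seq(20000, seed = 1),
                       s2 = rand_seq(15000, seed = 2)))
  bl <- align_assemblies(asm, asm)
  expect_equal(nrow(bl), 2L)
  expect_true(all(bl$strand == "+"))
  expect_true(all(bl$base_id == bl$alt_id))
  cov <- sum(bl$base_end - bl$base_start) / sum(nchar(unclass(asm)))
  expect_gt(cov, 0.99)
})

test_that("reverse-complement alternates flip strand and mirror intervals", {
  asm <- as_assembly(c(s1 = rand_seq(20000, seed = 3)))
  rc <- as_assembly(c(s1 = revcomp(unclass(asm)[["s1"]])))
  fwd <- align_assemblies(asm, asm)
  rev <- align_assemblies(asm, rc)
  expect_equal(nrow(rev), 1L)
  expect_equal(rev$strand, "-")
  L <- 20000
  expect_equal(rev$alt_start, L - fwd$alt_end)
  expect_equal(rev$alt_end, L - fwd$alt_start)
  expect_equal(rev$base_start, fwd$base_start)
})

test_that("chaining links collinear anchors and breaks at large jumps", {
  a <- tibble::tibble(base_pos = c(0L, 100L, 200L), y = c(0, 100, 200))
  ch <- chain_anchors(a, k = 15, gap_limit = 10000)
  expect_equal(length(unique(ch$chain)), 1L)
  expect_equal(ch$chain, rep(1L, 3))
  expect_equal(attr(ch, "scores")[1], 45)  # k + 2 * min(k, dx, dy)

  # two collinear runs separated by a jump beyond gap_limit form two chains
  b <- tibble::tibble(base_pos = c(0L, 20L, 40L, 5000L, 5020L),
                      y = c(0, 20, 40, 5000, 5020))
  ch2 <- chain_anchors(b, k = 15, gap_limit = 1000)
  expect_equal(length(attr(ch2, "scores")), 2L)
})

test_that("banded chain scores match the exhaustive DP oracle", {
  withr::with_seed(99, {
    for (i in 1:25) {
      n <- sample(5:30, 1)
      x <- sample.int(400, n)
      y <- sample.int(400, n)
      k <- 15; gl <- sample(c(50, 100, 400), 1); dl <- sample(c(30, 400), 1)
      a <- tibble::tibble(base_pos = as.integer(x), y = as.numeric(y))
      ch <- chain_anchors(a, k = k, gap_limit = gl, diag_limit = dl,
                          max_lookback = 64)
      expect_equal(max(attr(ch, "scores")),
                   chain_bruteforce(x, y, k, gl, dl))
    }
  })
})

test_that("a base scaffold aligned to its three truth slices is tiled", {
  truth <- rand_seq(60000, seed = 12)
  cuts <- c(21000, 41000)
  alt <- as_assembly(c(c1 = substring(truth, 1, cuts[1]),
                       c2 = substring(truth, cuts[1] + 1, cuts[2]),
                       c3 = substring(truth, cuts[2] + 1, 60000)))
  bl <- align_assemblies(as_assembly(c(s = truth)), alt)
  expect_equal(nrow(bl), 3L)
  expect_equal(bl$alt_id, c("c1", "c2", "c3"))
  # block boundaries land within k + window of the true cut points
  slack <- 15 + 10
  expect_lt(abs(bl$base_end[1] - cuts[1]), slack)
  expect_lt(abs(bl$base_start[2] - cuts[1]), slack)
  expect_lt(abs(bl$base_end[2] - cuts[2]), slack)
})

test_that("alignment is deterministic", {
  scn <- get_scn("gapfill")
  b1 <- align_assemblies(scn$base, scn$alternates[[1]])
  b2 <- align_assemblies(scn$base, scn$alternates[[1]])
  expect_identical(b1, b2)
})

test_that("dot-plot table has one row per block", {
  scn <- get_scn("gapfill")
  bl <- align_assemblies(scn$base, scn$alternates[[1]])
  dp <- dotplot_table(bl)
  expect_equal(nrow(dp), nrow(bl))
  expect_named(dp, c("base_id", "base_start", "base_end", "alt_id",
                     "alt_start", "alt_end", "strand"))
  expect_s3_class(plot_dotplot(bl), "ggplot")
})

test_that("PAF round-trips and rejects malformed input", {
  f <- tempfile(fileext = ".paf")
  writeLines("q\t1000\t0\t1000\t+\tt\t2000\t0\t1000\t1000\t1000\t60", f)
  bl <- read_paf(f)
  expect_equal(nrow(bl), 1L)
  expect_equal(bl$strand, "+")
  expect_equal(bl$base_id, "t")
  expect_equal(bl$alt_id, "q")
  expect_equal(bl$base_start, 0)
  expect_equal(bl$alt_end, 1000)

  out <- tempfile(fileext = ".paf")
  write_paf(bl, out)
  expect_identical(readLines(out), readLines(f))

  bad <- tempfile(fileext = ".paf")
  writeLines("q\t1000\t0\t1000\t+\tt\t2000\t0\t1000\t1000\t1000", bad)
  expect_error(read_paf(bad), "line 1")

  multi <- tempfile(fileext = ".paf")
  writeLines(c("q\t1000\t0\t1000\t+\tt\t2000\t0\t1000\t1000\t1000\t60",
               "r\t500\t0\t400\t-\tt\t2000\t1200\t1600\t380\t400\t3"), multi)
  expect_equal(nrow(read_paf(multi, min_mapq = 10)), 1L)
})
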