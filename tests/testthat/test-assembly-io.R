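test_that("FASTA reading normalises case and U, truncates IDs, round-trips", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">a extra words", "acgTN", ">b", "NNAC", ">c", "acgu"), f)
  asm <- read_assembly(f)
  expect_s3_class(asm, "asm_set")
  expect_equal(names(asm), c("a", "b", "c"))
  expect_equal(unclass(asm)[["a"]], "ACGTN")
  expect_equal(unclass(asm)[["b"]], "NNAC")
  expect_equal(unclass(asm)[["c"]], "ACGT")
  expect_equal(unname(nchar(unclass(asm))), c(5L, 4L, 4L))

  out <- tempfile(fileext = ".fasta")
  write_assembly(asm, out)
  expect_identical(unclass(read_assembly(out)), unclass(asm))
})

test_that("duplicate IDs, empty files and IUPAC codes are handled", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "TTTT"), f)
  expect_error(read_assembly(f), "duplicate sequence ID: a")

  f2 <- tempfile(fileext = ".fasta")
  file.create(f2)
  expect_error(read_assembly(f2))

  expect_warning(as_assembly(c(x = "ACGTRY")), "IUPAC")
})

test_that("find_gaps reports maximal N runs with 0-based half-open coords", {
  expect_equal(nrow(find_gaps(c(a = "ACGTACGT"))), 0L)

  g <- find_gaps(c(a = "AANNNAAN"))
  expect_equal(g$start, c(2L, 7L))
  expect_equal(g$end, c(5L, 8L))
  expect_equal(g$length, c(3L, 1L))

  expect_equal(find_gaps(c(a = "AANNNAAN"), min_gap_len = 2)$length, 3L)

  # invariant to scaffold order
  two <- c(a = "AANNA", b = "NNNGG")
  g1 <- find_gaps(two)
  g2 <- find_gaps(two[c(2, 1)])
  expect_equal(g1, g2[order(g2$scaffold_id), ])
})

test_that("split_into_contigs cuts at qualifying gaps and derives IDs", {
  ct <- split_into_contigs(c(s = "AANNNAA"))
  expect_equal(unclass(ct), c(s.1 = "AA", s.2 = "AA"))

  one <- split_into_contigs(c(s = "AANNNAA"), min_split_gap = 5)
  expect_equal(unclass(one), c(s.1 = "AANNNAA"))

  expect_warning(
    ct2 <- split_into_contigs(c(s = "NNNN", t = "ACGT")),
    "all N")
  expect_equal(names(ct2), "t.1")
})

test_that("splitting at gaps conserves total sequence", {
  scn <- get_scn("gapfill")
  gaps <- find_gaps(scn$base)
  contigs <- split_into_contigs(scn$base)
  expect_equal(sum(nchar(unclass(contigs))) + sum(gaps$length),
               sum(nchar(unclass(scn$base))))
})

test_that("NX curve and summary statistics are correct", {
  s1 <- compute_stats(c(a = strrep("A", 100)))
  expect_equal(s1$n50, 100)
  expect_true(all(s1$nx_curve$length_bp == 100))

  lens <- c(50, 40, 10)
  asm <- as_assembly(stats::setNames(strrep("A", lens), c("x", "y", "z")))
  st <- compute_stats(asm)
  expect_equal(st$n50, 50)   # 50 covers exactly 50% of 100
  expect_equal(st$total_length, 100)
  expect_equal(st$max_length, 50)

  # invariants
  expect_equal(st$n50, st$nx_curve$length_bp[st$nx_curve$X == 50])
  expect_true(all(diff(st$nx_curve$length_bp) <= 0))
  expect_true(st$contig_n50 <= st$n50)

  # gap-aware fields
  st2 <- compute_stats(c(a = "AANNNAAN"))
  expect_equal(st2$n_gaps, 2L)
  expect_equal(st2$gap_total_length, 4L)
  expect_equal(st2$contig_n50, 2)
})

test_that("NX curve matches brute force on random length multisets", {
  withr::with_seed(42, {
    for (i in 1:50) {
      lens <- sample.int(5000, sample(1:40, 1), replace = TRUE)
      nx <- nx_curve(lens)
      expect_equal(nx$length_bp, nx_bruteforce(lens, nx$X))
    }
  })
})

test_that("stats objects support glance/tidy/autoplot and file output", {
  st <- compute_stats(c(a = "ACGTNNACGTAC", b = "AC"))
  g <- glance(st)
  expect_equal(g$n_sequences, 2L)
  expect_equal(nrow(tidy(st)), 100L)
  p <- autoplot(st)
  expect_s3_class(p, "ggplot")

  tsv <- tempfile(fileext = ".tsv")
  write_stats(st, tsv)
  expect_true(file.exists(tsv))
  expect_true(file.exists(paste0(tsv, ".nx.tsv")))
  js <- tempfile(fileext = ".json")
  write_stats(st, js, format = "json")
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$n_gaps, 1L)
})

test_that("AGP output describes plain and edited scaffolds", {
  f <- tempfile(fileext = ".agp")
  write_agp(as_assembly(c(s1 = "ACGTACGTAA")), f)
  rows <- strsplit(readLines(f)[-1], "\t")[[1]]
  expect_equal(rows[1:6], c("s1", "1", "10", "1", "W", "s1"))

  # a gap fill splits one scaffold into three W components
  plan <- asmrec:::plan_identity(as_assembly(c(s = strrep("A", 100))),
                                 source = ".base")
  edit <- tibble::tibble(kind = "gap_fill", base_id = "s", base_start = 40,
                         base_end = 60, donor_assembly = "alt",
                         donor_id = "c1", donor_start = 10, donor_end = 32,
                         donor_strand = "+")
  agp <- asmrec:::plan_to_agp(asmrec:::plan_apply_edits(plan, edit))
  expect_equal(agp$component_type, c("W", "W", "W"))
  expect_equal(agp$component_id, c("s", "c1", "s"))
  expect_equal(agp$object_beg, c(1, 41, 63))
  expect_equal(agp$object_end, c(40, 62, 102))

  # a merge yields W, N(100), W
  plan2 <- asmrec:::plan_identity(
    as_assembly(c(A = strrep("A", 50), B = strrep("C", 60))),
    source = ".base")
  m <- tibble::tibble(kind = "merge", base_id = "A", donor_id = "B",
                      base_or = "+", donor_or = "+", new_id = "A_B",
                      gap_len = 100L)
  agp2 <- asmrec:::plan_to_agp(asmrec:::plan_apply_edits(plan2, m))
  expect_equal(agp2$component_type, c("W", "N", "W"))
  expect_equal(agp2$component_id[2], "100")
  expect_equal(agp2$component_beg[2], "scaffold")
  expect_equal(agp2$orientation[2], "align_genus")
  expect_equal(agp2$object_end, c(50, 150, 210))
})
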