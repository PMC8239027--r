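# Full reconciliation pipeline -------------------------------------------

#' Reconcile a base assembly against alternate assemblies
#'
#' Runs the full consensus workflow: align each alternate to the base, call
#' breakpoints at gaps where at least two alternates are discrepant with the
#' base and mutually consistent, replace the misjoined blocks with
#' alternate-assembly sequence (hybrid assembly), re-align and fill remaining
#' gaps from gap-free alternate regions, and (optionally) merge scaffolds
#' bridged by alternate contigs. All randomness (donor choice among eligible
#' alternates) is governed by `seed`; identical inputs and seed give
#' byte-identical outputs.
#'
#' @param base the base assembly (`asm_set`, `DNAStringSet` or named
#'   character).
#' @param alternates named list of at least two alternate assemblies.
#' @param aparams aligner parameters, see [align_params()].
#' @param params reconciliation parameters, see [reconcile_params()].
#' @param seed integer seed for donor selection.
#' @param do_merge run the scaffold-merge step (default TRUE).
#' @return an object of class `asm_reconciliation`: a list with `hybrid`
#'   (the edited assembly), `edits` (all EditRecords with a `stage` column),
#'   `calls` (breakpoint calls), `plan` (component provenance used for AGP
#'   and liftover composition), `report` (summary counts), `unfilled`,
#'   `conflicts` and the parameters used.
#' @export
reconcile_assemblies <- function(base, alternates, aparams = align_params(),
                                 params = reconcile_params(), seed = 1L,
                                 do_merge = TRUE) {
  base <- as_assembly(base)
  if (!is.list(alternates) || length(alternates) < 2) {
    stop("at least 2 alternate assemblies are required: the consensus check ",
         "needs two alternates that agree with each other against the base")
  }
  if (is.null(names(alternates)) || any(!nzchar(names(alternates)))) {
    names(alternates) <- paste0("alt", seq_along(alternates))
  }
  alternates <- lapply(alternates, as_assembly)
  withr::with_seed(as.integer(seed), {
    k <- aparams$k
    aln <- purrr::imap(alternates, function(a, nm)
      align_assemblies(base, a, aparams, alt_name = nm))
    gaps0 <- find_gaps(base)
    calls <- call_breakpoints(base, gaps0, aln, params, k = k)
    repl <- apply_block_replacements(base, alternates, aln, calls, params,
                                     rng_seed = NULL, k = k)
    aln2 <- if (nrow(repl$edits) == 0) aln else {
      purrr::imap(alternates, function(a, nm)
        align_assemblies(repl$assembly, a, aparams, alt_name = nm))
    }
    fl <- fill_gaps(repl$assembly, alternates, aln2, gaps = NULL,
                    params = params, rng_seed = NULL, k = k)
    merge_possible <- sum(seq_lengths(fl$assembly) >= params$min_merge_len) >= 2
    if (do_merge && merge_possible) {
      aln3 <- if (fl$n_gaps_filled == 0) aln2 else {
        purrr::imap(alternates, function(a, nm)
          align_assemblies(fl$assembly, a, aparams, alt_name = nm))
      }
      mg <- merge_scaffolds(fl$assembly, alternates, aln3, params)
    } else {
      mg <- list(assembly = fl$assembly, edits = empty_edits(),
                 conflicts = tibble::tibble(scaffold = character(),
                                            side = character()))
    }
    edits <- dplyr::bind_rows(
      dplyr::mutate(repl$edits, stage = "replace"),
      dplyr::mutate(fl$edits, stage = "fill"),
      dplyr::mutate(mg$edits, stage = "merge"))
    plan <- plan_identity(base, source = ".base")
    plan <- plan_apply_edits(plan, repl$edits)
    plan <- plan_apply_edits(plan, fl$edits)
    plan <- plan_apply_edits(plan, mg$edits)
    report <- list(
      n_breakpoints_called = nrow(calls),
      n_actionable = sum(calls$actionable),
      n_blocks_replaced = nrow(repl$edits),
      n_replacements_skipped = repl$n_skipped,
      n_gaps_filled = fl$n_gaps_filled,
      filled_gap_total_length = fl$filled_gap_total_length,
      n_gaps_unfilled = nrow(fl$unfilled),
      n_merges = nrow(mg$edits),
      n_merge_conflicts = nrow(mg$conflicts))
    structure(list(
      hybrid = mg$assembly, base = base, alternates = alternates,
      edits = edits, calls = calls, plan = plan, report = report,
      unfilled = fl$unfilled, conflicts = mg$conflicts,
      aparams = aparams, params = params, seed = as.integer(seed)),
      class = "asm_reconciliation")
  })
}

#' @export
print.asm_reconciliation <- function(x, ...) {
  cat("<asm_reconciliation>\n")
  print(glance(x))
  invisible(x)
}

#' Edit records of a reconciliation
#'
#' @param x an `asm_reconciliation`.
#' @param ... unused.
#' @return the EditRecord tibble (one row per applied modification, with full
#'   coordinate provenance and the recorded random donor draw).
#' @export
tidy.asm_reconciliation <- function(x, ...) x$edits

#' One-row summary of a reconciliation
#'
#' @inheritParams tidy.asm_reconciliation
#' @return a one-row tibble of the report counts.
#' @export
glance.asm_reconciliation <- function(x, ...) {
  tibble::as_tibble(x$report)
}

#' Write the reconciliation report as JSON
#'
#' @param x an `asm_reconciliation`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  stopifnot(inherits(x, "asm_reconciliation"))
  payload <- c(x$report, list(
    seed = x$seed,
    edits = x$edits[, c("kind", "base_id", "base_start", "base_end",
                        "donor_assembly", "donor_id", "donor_start",
                        "donor_end", "donor_strand", "inserted_length",
                        "rng_draw", "stage")]))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Write breakpoint calls as BED
#'
#' 0-based half-open intervals on the base assembly (the clustered junction
#' span), with the name column `actionable|candidate` and the score column
#' holding the number of discrepant agreeing alternates.
#'
#' @param calls calls tibble from [call_breakpoints()], or an
#'   `asm_reconciliation`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_breakpoints_bed <- function(calls, path) {
  if (inherits(calls, "asm_reconciliation")) calls <- calls$calls
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  lines <- paste(calls$base_id, fmt(calls$jmin), fmt(pmax(calls$jmax,
                 calls$jmin + 1)),
                 ifelse(calls$actionable, "actionable", "candidate"),
                 calls$n_discrepant_agreeing,
                 ".", sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' File-level reconciliation run
#'
#' Reads FASTA inputs, runs [reconcile_assemblies()], and writes the hybrid
#' FASTA, AGP v2.1 provenance, report JSON, breakpoint BED and a manifest
#' (input checksums, parameters, seed, package version) into `out_dir`.
#'
#' @param base_path base assembly FASTA.
#' @param alt_paths character vector (>= 2) of alternate FASTAs; names are
#'   used as alternate labels (basenames by default).
#' @param out_dir output directory (created if needed).
#' @inheritParams reconcile_assemblies
#' @return the `asm_reconciliation`, invisibly.
#' @export
reconcile_run <- function(base_path, alt_paths, out_dir,
                          aparams = align_params(),
                          params = reconcile_params(), seed = 1L,
                          do_merge = TRUE) {
  if (length(alt_paths) < 2) {
    stop("at least 2 alternate assemblies are required: the consensus check ",
         "needs two alternates that agree with each other against the base")
  }
  base <- read_assembly(base_path)
  nms <- names(alt_paths)
  if (is.null(nms) || any(!nzchar(nms))) {
    nms <- make.unique(sub("\\.(fa|fasta|fna)(\\.gz)?$", "",
                           basename(alt_paths)))
  }
  alts <- stats::setNames(lapply(alt_paths, read_assembly), nms)
  rec <- reconcile_assemblies(base, alts, aparams, params, seed, do_merge)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_assembly(rec$hybrid, file.path(out_dir, "hybrid.fasta"))
  write_agp(rec, file.path(out_dir, "hybrid.agp"))
  write_report(rec, file.path(out_dir, "report.json"))
  write_breakpoints_bed(rec, file.path(out_dir, "breakpoints.bed"))
  manifest <- list(
    tool = "asmrec", version = as.character(utils::packageVersion("asmrec")),
    seed = as.integer(seed),
    inputs = c(stats::setNames(as.character(tools::md5sum(base_path)),
                               basename(base_path)),
               stats::setNames(as.character(tools::md5sum(alt_paths)), nms)),
    align_params = aparams, reconcile_params = params, do_merge = do_merge)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(rec)
}
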