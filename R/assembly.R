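#' Assembly containers
#'
#' An assembly is represented as a named character vector of uppercase DNA
#' sequences (`A`, `C`, `G`, `T`, `N`, plus any IUPAC ambiguity codes, which
#' are preserved but flagged). `as_assembly()` normalises arbitrary input
#' (named character, `Biostrings::DNAStringSet`, or a list of single strings).
#'
#' @param x sequences: a named character vector, a `DNAStringSet`, or a list.
#' @return a named character vector of class `asm_set`.
#' @export
as_assembly <- function(x) {
  if (inherits(x, "asm_set")) return(x)
  if (methods::is(x, "XStringSet")) x <- as.character(x)
  if (is.list(x)) x <- vapply(x, as.character, character(1))
  if (!is.character(x)) stop("cannot interpret input as an assembly")
  if (length(x) == 0) stop("assembly is empty")
  nm <- names(x)
  if (is.null(nm) || any(!nzchar(nm))) stop("all sequences must be named")
  nm <- sub("\\s.*$", "", nm)
  if (anyDuplicated(nm)) {
    stop("duplicate sequence ID: ", nm[duplicated(nm)][1])
  }
  if (any(!nzchar(x))) stop("empty sequence for ID: ", nm[!nzchar(x)][1])
  x <- chartr("u", "t", x)
  x <- toupper(x)
  x <- chartr("U", "T", x)
  odd <- grepl("[^ACGTN]", x)
  if (any(odd)) {
    warning("IUPAC ambiguity codes other than N present in: ",
            paste(nm[odd], collapse = ", "), " (preserved)")
  }
  names(x) <- nm
  structure(x, class = "asm_set")
}

#' @export
print.asm_set <- function(x, ...) {
  cat("<asm_set> ", length(x), " sequence(s), ",
      format(sum(nchar(x)), big.mark = ","), " bp total\n", sep = "")
  n <- utils::head(seq_along(x), 10)
  for (i in n) cat("  ", names(x)[i], ": ", nchar(x[[i]]), " bp\n", sep = "")
  if (length(x) > 10) cat("  ...\n")
  invisible(x)
}

#' @export
`[.asm_set` <- function(x, i) {
  structure(NextMethod(), class = "asm_set")
}

#' Read an assembly from FASTA
#'
#' Sequences are uppercased and U is normalised to T; lowercase (soft-masked)
#' state is not preserved. Duplicate record IDs and empty files are errors;
#' IDs are truncated at the first whitespace.
#'
#' @param path FASTA file (optionally gzip-compressed).
#' @return an `asm_set`.
#' @export
read_assembly <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("empty FASTA: ", path)
  as_assembly(stats::setNames(as.character(ss), names(ss)))
}

#' Write an assembly to FASTA
#'
#' Multi-line FASTA with a 60 bp wrap.
#'
#' @param assembly an `asm_set` (or coercible).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_assembly <- function(assembly, path) {
  assembly <- as_assembly(assembly)
  ss <- Biostrings::BStringSet(unclass(assembly))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

seq_lengths <- function(assembly) {
  stats::setNames(nchar(unclass(assembly)), names(assembly))
}
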