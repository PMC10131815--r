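#' Construct a validated RNA sequence
#'
#' An `rna_sequence` is an ordered residue string over the alphabet
#' `{A, U, G, C}` together with a name. `T` is accepted on input and
#' transliterated silently to `U` (sequences are frequently supplied as DNA);
#' any other character is an error, because downstream molecular-weight
#' arithmetic is undefined for ambiguity codes.
#'
#' @param residues Character scalar; the residue string. Whitespace is
#'   stripped and case is normalized to upper before validation, so sequences
#'   pasted as space-separated blocks are accepted.
#' @param name Free-text sequence name.
#' @return An object of class `rna_sequence`: a character scalar of residues
#'   with attribute `name`.
#' @examples
#' rna_sequence("aug ccc", "demo")
#' @export
rna_sequence <- function(residues, name = "") {
  res <- .normalize_residues(residues)
  res <- chartr("T", "U", res)
  .check_alphabet(res, c("A", "U", "G", "C"), "RNA")
  structure(res, name = as.character(name)[1], class = "rna_sequence")
}

#' Construct a validated protein sequence
#'
#' Residues must be the 20 standard amino-acid one-letter codes; a stop
#' symbol (`*`) inside the string is rejected.
#'
#' @inheritParams rna_sequence
#' @return An object of class `protein_sequence`.
#' @examples
#' protein_sequence("MNFLLSWVHW")
#' @export
protein_sequence <- function(residues, name = "") {
  res <- .normalize_residues(residues)
  .check_alphabet(res, .AA_CODES, "protein")
  structure(res, name = as.character(name)[1], class = "protein_sequence")
}

.AA_CODES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.normalize_residues <- function(residues) {
  stopifnot(is.character(residues), length(residues) >= 1)
  res <- toupper(gsub("[[:space:]]+", "", paste(residues, collapse = "")))
  if (nchar(res) < 1) {
    stop("malformed input: empty sequence record", call. = FALSE)
  }
  res
}

.check_alphabet <- function(res, alphabet, what) {
  chars <- strsplit(res, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% alphabet)
  if (length(bad) > 0) {
    stop(sprintf("invalid %s residue '%s' at position %d",
                 what, chars[bad[1]], bad[1]), call. = FALSE)
  }
  invisible(res)
}

#' @export
print.rna_sequence <- function(x, ...) {
  cat(sprintf("RNA sequence '%s': %d nt\n", attr(x, "name"), nchar(x)))
  cat(.abbrev_seq(x), "\n")
  invisible(x)
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("Protein sequence '%s': %d aa\n", attr(x, "name"), nchar(x)))
  cat(.abbrev_seq(x), "\n")
  invisible(x)
}

.abbrev_seq <- function(x) {
  if (nchar(x) <= 60) return(unclass(x))
  paste0(substr(x, 1, 57), "...")
}

#' @export
length.rna_sequence <- function(x) nchar(unclass(x))

#' @export
length.protein_sequence <- function(x) nchar(unclass(x))

#' Parse FASTA-formatted text into validated sequences
#'
#' Accepts multi-record FASTA with wrapped lines and whitespace inside
#' sequence lines (e.g. sequences printed as space-separated 5-mer blocks).
#' Case is normalized to upper; for RNA, `T` is transliterated to `U`.
#' Records with no sequence are a malformed-input error; residues outside the
#' alphabet (after normalization) raise a validation error naming the
#' offending position.
#'
#' @param text Character vector of FASTA lines, or a single string containing
#'   newlines. Plain sequence text without a `>` header is accepted as one
#'   anonymous record.
#' @param alphabet `"rna"` or `"protein"`.
#' @return A list of [rna_sequence()] or [protein_sequence()] objects.
#' @examples
#' parse_fasta(">x\nAUG CCC\n", "rna")
#' @export
parse_fasta <- function(text, alphabet = c("rna", "protein")) {
  alphabet <- match.arg(alphabet)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    stop("malformed input: no FASTA records found", call. = FALSE)
  }
  is_header <- startsWith(lines, ">")
  if (!is_header[1]) {
    # headerless plain-text paste: treat as a single anonymous record
    lines <- c(">sequence", lines)
    is_header <- c(TRUE, is_header)
  }
  rec_idx <- cumsum(is_header)
  headers <- sub("^>", "", lines[is_header])
  out <- vector("list", length(headers))
  ctor <- if (alphabet == "rna") rna_sequence else protein_sequence
  for (i in seq_along(headers)) {
    body <- lines[rec_idx == i & !is_header]
    if (length(body) == 0) {
      stop(sprintf("malformed input: record '%s' has no sequence",
                   headers[i]), call. = FALSE)
    }
    name <- strsplit(trimws(headers[i]), "[[:space:]]+")[[1]][1]
    out[[i]] <- ctor(paste(body, collapse = ""), name = name)
  }
  out
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over [parse_fasta()] applying the same normalization.
#'
#' @param path Path to a FASTA file.
#' @inheritParams parse_fasta
#' @return A list of sequence objects.
#' @export
read_fasta <- function(path, alphabet = c("rna", "protein")) {
  parse_fasta(readLines(path, warn = FALSE), alphabet = alphabet)
}

#' Bundled VEGF-A 165 sequences
#'
#' The 576-nt coding sequence of human VEGF-A 165 (start and stop codons
#' included) and the 191-aa protein it encodes, shipped as package data.
#' These are the construct sequences all worked examples use.
#'
#' @return `vegfa_cds()` an [rna_sequence()]; `vegfa_protein()` a
#'   [protein_sequence()].
#' @examples
#' length(vegfa_cds())
#' @export
vegfa_cds <- function() {
  read_fasta(system.file("extdata", "vegfa_mrna_cds.fasta",
                         package = "vesikin", mustWork = TRUE), "rna")[[1]]
}

#' @rdname vegfa_cds
#' @export
vegfa_protein <- function() {
  read_fasta(system.file("extdata", "vegfa_protein.fasta",
                         package = "vesikin", mustWork = TRUE), "protein")[[1]]
}
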