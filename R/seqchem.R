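# Residue mass tables (average isotopic masses, g/mol).
#
# RNA nucleotide-monophosphate residue masses follow the convention used for
# oligonucleotide molecular weights: per-residue mass of the internal
# monophosphate, with an optional +159 term accounting for the mass of a
# 5'-triphosphate on the full-length message.
.RNA_RESIDUE_MASS <- c(A = 329.2, U = 306.2, C = 305.2, G = 345.2)
.TRIPHOSPHATE_MASS <- 159.0

# Standard average amino-acid residue masses (ExPASy); one water is added per
# chain for the free termini.
.AA_RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
.WATER_MASS <- 18.01524

# Standard genetic code, RNA codons.
.GENETIC_CODE <- c(
  UUU = "F", UUC = "F", UUA = "L", UUG = "L",
  CUU = "L", CUC = "L", CUA = "L", CUG = "L",
  AUU = "I", AUC = "I", AUA = "I", AUG = "M",
  GUU = "V", GUC = "V", GUA = "V", GUG = "V",
  UCU = "S", UCC = "S", UCA = "S", UCG = "S",
  CCU = "P", CCC = "P", CCA = "P", CCG = "P",
  ACU = "T", ACC = "T", ACA = "T", ACG = "T",
  GCU = "A", GCC = "A", GCA = "A", GCG = "A",
  UAU = "Y", UAC = "Y", UAA = "*", UAG = "*",
  CAU = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAU = "N", AAC = "N", AAA = "K", AAG = "K",
  GAU = "D", GAC = "D", GAA = "E", GAG = "E",
  UGU = "C", UGC = "C", UGA = "*", UGG = "W",
  CGU = "R", CGC = "R", CGA = "R", CGG = "R",
  AGU = "S", AGC = "S", AGA = "R", AGG = "R",
  GGU = "G", GGC = "G", GGA = "G", GGG = "G"
)

#' Nucleotide or amino-acid composition of a sequence
#'
#' Counts every residue of the alphabet (zero counts included) and the
#' corresponding fractions `count / length`.
#'
#' @param seq An [rna_sequence()] or [protein_sequence()].
#' @return A list of class `seq_composition` with elements `counts` (named
#'   integer vector over the full alphabet), `fractions` (named numeric,
#'   summing to 1), and `length`.
#' @examples
#' composition(rna_sequence("AUGC"))
#' @export
composition <- function(seq) {
  alphabet <- if (inherits(seq, "rna_sequence")) {
    c("A", "U", "G", "C")
  } else if (inherits(seq, "protein_sequence")) {
    .AA_CODES
  } else {
    stop("composition() expects an rna_sequence or protein_sequence",
         call. = FALSE)
  }
  chars <- strsplit(unclass(seq), "", fixed = TRUE)[[1]]
  counts <- table(factor(chars, levels = alphabet))
  counts <- stats::setNames(as.integer(counts), alphabet)
  structure(
    list(counts = counts,
         fractions = counts / length(chars),
         length = length(chars)),
    class = "seq_composition"
  )
}

#' @export
print.seq_composition <- function(x, ...) {
  cat(sprintf("Composition of a %d-residue sequence\n", x$length))
  nz <- x$counts[x$counts > 0]
  cat(paste(sprintf("%s=%d (%.1f%%)", names(nz), nz,
                    100 * nz / x$length), collapse = ", "), "\n")
  invisible(x)
}

#' Molecular weight of an RNA sequence
#'
#' Linear combination of per-nucleotide average residue masses
#' (A 329.2, U 306.2, C 305.2, G 345.2 g/mol), plus 159 g/mol for the
#' 5'-triphosphate when `triphosphate = TRUE` (the default, appropriate for a
#' full-length in vitro transcript; set `FALSE` for an internal fragment such
#' as a bare CDS). Depends only on composition, so it is invariant under
#' residue permutation and additive under concatenation (without the
#' triphosphate term).
#'
#' Chemically modified bases (5-methylcytidine, pseudouridine) are treated as
#' their parent bases; no modification mass corrections are applied.
#'
#' @param seq An [rna_sequence()].
#' @param triphosphate Logical; add the 159 g/mol 5'-triphosphate term.
#' @return Mass in g/mol.
#' @examples
#' rna_molecular_weight(rna_sequence("A")) # 329.2 + 159
#' @export
rna_molecular_weight <- function(seq, triphosphate = TRUE) {
  comp <- composition(seq)
  if (!inherits(seq, "rna_sequence")) {
    stop("rna_molecular_weight() expects an rna_sequence", call. = FALSE)
  }
  sum(comp$counts[names(.RNA_RESIDUE_MASS)] * .RNA_RESIDUE_MASS) +
    if (isTRUE(triphosphate)) .TRIPHOSPHATE_MASS else 0
}

#' Average molecular weight of a protein sequence
#'
#' Sum of standard average residue masses plus one water (18.01524 g/mol)
#' for the termini. Average (not monoisotopic) masses are used, matching
#' standard protein MW calculators.
#'
#' @param seq A [protein_sequence()].
#' @return Mass in g/mol.
#' @examples
#' protein_molecular_weight(protein_sequence("G")) # glycine + water
#' @export
protein_molecular_weight <- function(seq) {
  if (!inherits(seq, "protein_sequence")) {
    stop("protein_molecular_weight() expects a protein_sequence",
         call. = FALSE)
  }
  chars <- strsplit(unclass(seq), "", fixed = TRUE)[[1]]
  sum(.AA_RESIDUE_MASS[chars]) + .WATER_MASS
}

#' Translate an RNA coding sequence
#'
#' Standard genetic code, reading from the first position (which must be the
#' AUG start codon) to the first stop codon, which is excluded from the
#' returned protein. A stop codon before the final codon triggers a warning
#' naming its position (the downstream residues are dropped); a missing
#' terminal stop warns but still returns the full-length translation, so that
#' fragments can be analyzed.
#'
#' @param seq An [rna_sequence()] whose length is a multiple of 3.
#' @return A [protein_sequence()].
#' @examples
#' translate_rna(rna_sequence("AUGUGA")) # "M"
#' @export
translate_rna <- function(seq) {
  if (!inherits(seq, "rna_sequence")) {
    stop("translate_rna() expects an rna_sequence", call. = FALSE)
  }
  n <- nchar(seq)
  if (n %% 3 != 0) {
    stop(sprintf("sequence length %d is not a multiple of 3", n),
         call. = FALSE)
  }
  codons <- substring(unclass(seq), seq(1, n, 3), seq(3, n, 3))
  if (codons[1] != "AUG") {
    stop(sprintf("sequence does not begin with AUG start codon (found %s)",
                 codons[1]), call. = FALSE)
  }
  aa <- .GENETIC_CODE[codons]
  stop_at <- which(aa == "*")
  if (length(stop_at) == 0) {
    warning("no stop codon found; translating full length", call. = FALSE)
    keep <- aa
  } else {
    if (stop_at[1] < length(codons)) {
      warning(sprintf("internal stop codon at codon %d (nt %d); %s",
                      stop_at[1], (stop_at[1] - 1) * 3 + 1,
                      "downstream residues dropped"), call. = FALSE)
    }
    keep <- aa[seq_len(stop_at[1] - 1)]
  }
  protein_sequence(paste(keep, collapse = ""),
                   name = paste0(attr(seq, "name"), "_translated"))
}
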