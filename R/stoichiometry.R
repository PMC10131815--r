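#' Physical constants and construct defaults
#'
#' `avogadro()` returns the 2019 SI exact Avogadro constant used by every
#' mass/copy conversion. `vegfa_mrna_mw()` returns the working molecular
#' weight of the full-length 852-nt VEGF-A mRNA construct (CleanCap, UTRs,
#' poly(A)): 277900 g/mol. The full-length sequence is not available, so this
#' constant is *derived* by back-calculation from the construct's dose
#' stoichiometry (3 ug corresponding to 6.5e12 copies); it is a documented
#' default that every function taking an `mw` argument lets you override.
#'
#' @return A numeric scalar.
#' @examples
#' mass_to_copies(3e-6, vegfa_mrna_mw())
#' @export
avogadro <- function() 6.02214076e23

#' @rdname avogadro
#' @export
vegfa_mrna_mw <- function() 277900

.check_positive <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("%s must be a positive finite number", what), call. = FALSE)
  }
  invisible(x)
}

#' Convert a mass to a molecule copy number
#'
#' `copies = mass / mw * N_A` (the mole definition). Copy counts are kept as
#' reals throughout: they are estimates derived from bulk mass, and integer
#' rounding happens only at display.
#'
#' @param mass Mass in grams (>= 0).
#' @param mw Molecular weight in g/mol (> 0).
#' @return Number of molecules (numeric).
#' @examples
#' mass_to_copies(3e-6, vegfa_mrna_mw()) # ~6.5e12
#' @export
mass_to_copies <- function(mass, mw) {
  .check_positive(mw, "mw")
  if (any(mass < 0)) stop("mass must be >= 0", call. = FALSE)
  mass / mw * avogadro()
}

#' Convert a molecule copy number to a mass
#'
#' Exact inverse of [mass_to_copies()].
#'
#' @param copies Number of molecules (>= 0).
#' @param mw Molecular weight in g/mol (> 0).
#' @return Mass in grams.
#' @export
copies_to_mass <- function(copies, mw) {
  .check_positive(mw, "mw")
  if (any(copies < 0)) stop("copies must be >= 0", call. = FALSE)
  copies / avogadro() * mw
}

#' Copies per particle, cell, or vesicle
#'
#' Divides a total copy number by an entity count. The display convention of
#' the field rounds copies-per-particle to the nearest integer; the return
#' value carries full precision with the rounded value as attribute
#' `rounded`.
#'
#' @param total Total molecule copies (>= 0).
#' @param units Number of particles / cells / EVs (> 0).
#' @return Copies per unit (numeric, full precision) with attribute
#'   `rounded`.
#' @examples
#' per_unit_copies(6.5e12, 2.5e11) # 26 copies per LNP
#' @export
per_unit_copies <- function(total, units) {
  .check_positive(units, "units")
  if (any(total < 0)) stop("total copies must be >= 0", call. = FALSE)
  x <- total / units
  attr(x, "rounded") <- round(x)
  x
}

#' Protein copies produced per mRNA copy
#'
#' The translation yield: protein copies divided by delivered mRNA copies.
#' Full precision is returned; attribute `display` holds the value rounded
#' to 2 significant figures, the field's reporting convention.
#'
#' @param protein_copies Protein molecule count (>= 0).
#' @param mrna_copies mRNA molecule count (> 0).
#' @return Dimensionless yield with attribute `display`.
#' @examples
#' translation_yield(1e12, 6.5e12) # displayed 0.15
#' @export
translation_yield <- function(protein_copies, mrna_copies) {
  .check_positive(mrna_copies, "mrna_copies")
  if (any(protein_copies < 0)) stop("protein copies must be >= 0",
                                    call. = FALSE)
  y <- protein_copies / mrna_copies
  attr(y, "display") <- signif(y, 2)
  y
}

#' Fold ratio between two per-unit copy numbers
#'
#' @param a,b Per-unit copy numbers; `b` must be > 0.
#' @return `a / b` at full precision.
#' @examples
#' fold_ratio(1355, 6) # ~225.8-fold more copies per cell than per EV
#' @export
fold_ratio <- function(a, b) {
  .check_positive(b, "denominator")
  a / b
}

#' Normalize a concentration to tissue weight
#'
#' Divides an assay concentration (e.g. ELISA pg/mL) by the weight in grams
#' of the source tissue, the convention for comparing organ-level protein
#' readings.
#'
#' @param amount Concentration (e.g. pg/mL), >= 0.
#' @param weight_g Tissue weight in grams (> 0).
#' @return `amount / weight_g`.
#' @export
normalize_per_weight <- function(amount, weight_g) {
  .check_positive(weight_g, "weight_g")
  if (any(amount < 0)) stop("amount must be >= 0", call. = FALSE)
  amount / weight_g
}
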