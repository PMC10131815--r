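#' Describe an LNP formulation
#'
#' Captures the lipid composition and physical characteristics of a
#' four-lipid nanoparticle formulation: molar fractions of the ionizable
#' lipid, cholesterol, DSPC, and the PEG-lipid; total lipid molarity of the
#' ethanol phase; total lipid to mRNA weight ratio; Z-average diameter;
#' polydispersity index; encapsulation efficiency; and mRNA concentration of
#' the final product. Defaults are the MC3 benchmark formulation
#' (50:38.5:10:1.5 mol%, 12.5 mM lipid, 10:1 w/w, 85 nm, PDI 0.024, 99%
#' encapsulation, 0.1 mg/mL mRNA).
#'
#' @param molar_fractions Named numeric vector of lipid molar fractions;
#'   must sum to 1 within 1e-6. The ionizable lipid must be named first or
#'   identified by `ionizable`.
#' @param total_lipid_molar Total lipid concentration, mol/L.
#' @param lipid_to_mrna_w_w Total lipid : mRNA weight ratio.
#' @param diameter_z_nm Z-average diameter in nm.
#' @param pdi Polydispersity index.
#' @param encapsulation Encapsulated fraction of mRNA, in `[0, 1]`.
#' @param mrna_conc_mg_ml mRNA concentration of the product, mg/mL.
#' @param ionizable Name of the ionizable lipid within `molar_fractions`.
#' @return An object of class `formulation` (a validated list).
#' @examples
#' formulation()
#' @export
formulation <- function(molar_fractions = c(MC3 = 0.50, cholesterol = 0.385,
                                            DSPC = 0.10,
                                            `DMPE-PEG2000` = 0.015),
                        total_lipid_molar = 12.5e-3,
                        lipid_to_mrna_w_w = 10,
                        diameter_z_nm = 85,
                        pdi = 0.024,
                        encapsulation = 0.99,
                        mrna_conc_mg_ml = 0.1,
                        ionizable = names(molar_fractions)[1]) {
  stopifnot(is.numeric(molar_fractions), !is.null(names(molar_fractions)))
  if (abs(sum(molar_fractions) - 1) > 1e-6) {
    stop("lipid molar fractions must sum to 1 (within 1e-6)", call. = FALSE)
  }
  if (any(molar_fractions <= 0)) {
    stop("lipid molar fractions must be positive", call. = FALSE)
  }
  if (encapsulation < 0 || encapsulation > 1) {
    stop("encapsulation must be a fraction in [0, 1]", call. = FALSE)
  }
  for (v in c(total_lipid_molar, lipid_to_mrna_w_w, diameter_z_nm,
              mrna_conc_mg_ml)) {
    .check_positive(v, "formulation parameter")
  }
  if (!ionizable %in% names(molar_fractions)) {
    stop("ionizable lipid name not found in molar_fractions", call. = FALSE)
  }
  structure(
    list(molar_fractions = molar_fractions,
         total_lipid_molar = total_lipid_molar,
         lipid_to_mrna_w_w = lipid_to_mrna_w_w,
         diameter_z_nm = diameter_z_nm,
         pdi = pdi,
         encapsulation = encapsulation,
         mrna_conc_mg_ml = mrna_conc_mg_ml,
         ionizable = ionizable),
    class = "formulation"
  )
}

#' @export
print.formulation <- function(x, ...) {
  cat("LNP formulation\n")
  cat(sprintf("  lipids (mol%%): %s\n",
              paste(sprintf("%s %.1f", names(x$molar_fractions),
                            100 * x$molar_fractions), collapse = ", ")))
  cat(sprintf("  total lipid %.3g M, lipid:mRNA %g:1 (w/w)\n",
              x$total_lipid_molar, x$lipid_to_mrna_w_w))
  cat(sprintf("  d(Z) %g nm, PDI %g, encapsulation %.0f%%, mRNA %g mg/mL\n",
              x$diameter_z_nm, x$pdi, 100 * x$encapsulation,
              x$mrna_conc_mg_ml))
  invisible(x)
}

#' Summarize a nanoparticle tracking analysis (NTA) measurement
#'
#' Mean and SEM of per-capture mean diameters, and mean and SEM of the
#' particle concentration back-scaled to the undiluted sample by the
#' dilution factor. SEM is `sd / sqrt(n)` over captures; with a single
#' capture SEM is reported as `NA`, never 0.
#'
#' @param capture_sizes_nm Per-capture mean diameters, nm (> 0).
#' @param capture_conc_per_ml Per-capture particle concentrations,
#'   particles/mL of the measured (diluted) suspension.
#' @param dilution_factor Dilution applied before measurement (>= 1).
#' @return A list with `mean_size_nm`, `sem_size_nm`, `mean_conc_per_ml`
#'   (undiluted), `sem_conc_per_ml` (undiluted), and `n_captures`.
#' @examples
#' summarize_nta(c(90, 100, 110), rep(1e8, 3), dilution_factor = 5)
#' @export
summarize_nta <- function(capture_sizes_nm, capture_conc_per_ml,
                          dilution_factor = 1) {
  if (length(capture_sizes_nm) < 1 ||
      length(capture_sizes_nm) != length(capture_conc_per_ml)) {
    stop("need >= 1 capture with matching size and concentration vectors",
         call. = FALSE)
  }
  .check_positive(capture_sizes_nm, "capture sizes")
  .check_positive(capture_conc_per_ml, "capture concentrations")
  if (dilution_factor < 1) stop("dilution_factor must be >= 1",
                                call. = FALSE)
  n <- length(capture_sizes_nm)
  sem <- function(x) if (n < 2) NA_real_ else stats::sd(x) / sqrt(n)
  conc <- capture_conc_per_ml * dilution_factor
  list(mean_size_nm = mean(capture_sizes_nm),
       sem_size_nm = sem(capture_sizes_nm),
       mean_conc_per_ml = mean(conc),
       sem_conc_per_ml = sem(conc),
       n_captures = n)
}

#' Estimate the number of LNP particles in a dose
#'
#' Two modes. The default, transparent mode divides the total mRNA copies in
#' the dose by a calibration constant of copies per particle (26 for the
#' VEGF-A construct, the value implied by a 3 ug dose of 6.5e12 copies loaded
#' in 2.5e11 particles). The `"geometric"` mode is a labelled approximation:
#' it computes the per-particle mRNA payload from the sphere volume at the
#' formulation's Z-average diameter, an assumed core density, and the
#' lipid:mRNA weight ratio, and should be trusted to order of magnitude only.
#'
#' @param f A [formulation()].
#' @param dose_mrna_g mRNA mass in the dose, grams.
#' @param mrna_mw mRNA molecular weight, g/mol.
#' @param mode `"calibration"` or `"geometric"`.
#' @param copies_per_particle Calibration constant for the default mode.
#' @param core_density_g_ml Assumed particle density for geometric mode.
#' @return A list with `particles`, `copies_per_particle`, and `mode`.
#' @examples
#' estimate_lnp_count(formulation(), 3e-6, vegfa_mrna_mw(),
#'                    copies_per_particle = 26)
#' @export
estimate_lnp_count <- function(f, dose_mrna_g, mrna_mw,
                               mode = c("calibration", "geometric"),
                               copies_per_particle = NULL,
                               core_density_g_ml = 1.1) {
  stopifnot(inherits(f, "formulation"))
  mode <- match.arg(mode)
  .check_positive(dose_mrna_g, "dose_mrna_g")
  .check_positive(mrna_mw, "mrna_mw")
  total_copies <- mass_to_copies(dose_mrna_g, mrna_mw)
  if (mode == "calibration") {
    if (is.null(copies_per_particle)) {
      stop("calibration mode requires copies_per_particle", call. = FALSE)
    }
    .check_positive(copies_per_particle, "copies_per_particle")
    cpp <- copies_per_particle
  } else {
    r_cm <- f$diameter_z_nm / 2 * 1e-7
    particle_mass_g <- 4 / 3 * pi * r_cm^3 * core_density_g_ml
    mrna_mass_frac <- 1 / (1 + f$lipid_to_mrna_w_w)
    cpp <- mass_to_copies(particle_mass_g * mrna_mass_frac, mrna_mw)
  }
  list(particles = total_copies / cpp,
       copies_per_particle = cpp,
       mode = mode)
}

#' LNP uptake fraction from radiolabel scintillation counts
#'
#' Normalizes a sample's counts-per-minute reading between two references
#' measured alongside it: plain medium (0% radioactivity) and medium spiked
#' with the full LNP dose at time zero (100%). After blank subtraction of
#' all terms, the radioactivity remaining in the medium is
#' `100 * (sample - ref0) / (ref100 - ref0)` and the uptake is its
#' complement, clamped to `[0, 100]` with a `clamped` flag when noise pushes
#' it outside. Duplicate readings should be averaged before calling
#' (pass a vector to `mean()` or use the `sample_cpm` mean).
#'
#' @param sample_cpm Sample reading, counts/min.
#' @param ref0_cpm Medium-only (0%) reference.
#' @param ref100_cpm Medium + LNPs at t0 (100%) reference.
#' @param blank_cpm Blank subtracted from every term (default 0).
#' @return A list with `uptake_pct`, `remaining_pct`, and `clamped`.
#' @examples
#' uptake_fraction(550, ref0_cpm = 100, ref100_cpm = 1000)
#' @export
uptake_fraction <- function(sample_cpm, ref0_cpm, ref100_cpm,
                            blank_cpm = 0) {
  vals <- c(sample_cpm, ref0_cpm, ref100_cpm, blank_cpm)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("CPM readings must be non-negative and finite", call. = FALSE)
  }
  s <- mean(sample_cpm) - blank_cpm
  r0 <- ref0_cpm - blank_cpm
  r100 <- ref100_cpm - blank_cpm
  if (r100 <= r0) {
    stop("invalid references: 100% reference must exceed 0% reference ",
         "after blank subtraction", call. = FALSE)
  }
  remaining <- 100 * (s - r0) / (r100 - r0)
  uptake <- 100 - remaining
  clamped <- uptake < 0 || uptake > 100
  list(uptake_pct = min(max(uptake, 0), 100),
       remaining_pct = remaining,
       clamped = clamped)
}

#' Nitrogen-to-phosphate ratio of a formulation
#'
#' Moles of ionizable-lipid amine nitrogen per mole of mRNA backbone
#' phosphate. The lipid molar masses are not part of the formulation record
#' and must be supplied. mRNA phosphate moles are derived from the lipid:mRNA
#' weight ratio and the mean per-nucleotide residue mass. This is a helper
#' for formulation bookkeeping; published N:P values also depend on
#' preparation details (e.g. mixing volumes) not captured here.
#'
#' @param f A [formulation()].
#' @param lipid_molar_masses Named numeric vector, g/mol, covering every
#'   lipid in `f$molar_fractions`.
#' @param mrna_mean_nt_mass Mean residue mass per nucleotide, g/mol
#'   (default: the mean RNA residue mass, ~321.45).
#' @param amines_per_ionizable Nitrogen atoms per ionizable lipid molecule.
#' @return The dimensionless N:P ratio.
#' @export
np_ratio <- function(f, lipid_molar_masses,
                     mrna_mean_nt_mass = mean(c(329.2, 306.2, 305.2, 345.2)),
                     amines_per_ionizable = 1) {
  stopifnot(inherits(f, "formulation"))
  missing <- setdiff(names(f$molar_fractions), names(lipid_molar_masses))
  if (length(missing) > 0) {
    stop("missing molar masses for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  .check_positive(lipid_molar_masses, "lipid molar masses")
  .check_positive(mrna_mean_nt_mass, "mrna_mean_nt_mass")
  mm <- lipid_molar_masses[names(f$molar_fractions)]
  lipid_mass_per_l <- sum(f$molar_fractions * mm) * f$total_lipid_molar
  mrna_mass_per_l <- lipid_mass_per_l / f$lipid_to_mrna_w_w
  p_moles <- mrna_mass_per_l / mrna_mean_nt_mass
  n_moles <- f$molar_fractions[[f$ionizable]] * f$total_lipid_molar *
    amines_per_ionizable
  n_moles / p_moles
}
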