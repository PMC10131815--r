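#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10(quantity) over a serial-dilution
#' standard series (conventionally 10-fold from 100 ng down to 0.0001 ng).
#' The slope is in Cq per decade (about -3.32 at 100% amplification
#' efficiency) and the intercept is the Cq at 1 ng. The fit carries the
#' quality gate used for absolute quantification: `qc_pass` is `TRUE` iff
#' R-squared strictly exceeds `r2_threshold` (default 0.975) and the slope is
#' negative.
#'
#' Technical replicates may be supplied as repeated quantities; they enter
#' the regression as individual points.
#'
#' @param quantity_ng Standard quantities in ng (> 0), at least 3 distinct.
#' @param cq Measured quantification cycles, same length.
#' @param r2_threshold Strict lower bound on R-squared for QC pass.
#' @return An object of class `standard_curve` with components `slope`,
#'   `intercept`, `r_squared`, `qc_pass`, `r2_threshold`, `points`
#'   (data frame), `range_ng`, and the underlying `lm` fit.
#' @seealso [predict.standard_curve()], [interpolate_quantity()],
#'   [amplification_efficiency()]
#' @examples
#' q <- 10^(2:-4)
#' fit <- standard_curve(q, 24 - 3.3219 * log10(q))
#' coef(fit)
#' @export
standard_curve <- function(quantity_ng, cq, r2_threshold = 0.975) {
  if (length(quantity_ng) != length(cq)) {
    stop("quantity_ng and cq must have the same length", call. = FALSE)
  }
  if (any(!is.finite(quantity_ng)) || any(quantity_ng <= 0)) {
    stop("standard quantities must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(cq))) stop("Cq values must be finite", call. = FALSE)
  if (length(unique(quantity_ng)) < 3) {
    stop("at least 3 distinct standard quantities are required to fit",
         call. = FALSE)
  }
  points <- data.frame(quantity_ng = quantity_ng,
                       log10_ng = log10(quantity_ng),
                       cq = cq)
  fit <- stats::lm(cq ~ log10_ng, data = points)
  # direct R-squared; summary.lm warns on noiseless (perfect) series
  sstot <- sum((cq - mean(cq))^2)
  r2 <- if (sstot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / sstot
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  structure(
    list(slope = slope,
         intercept = intercept,
         r_squared = r2,
         qc_pass = (r2 > r2_threshold) && (slope < 0),
         r2_threshold = r2_threshold,
         points = points,
         range_ng = range(quantity_ng),
         lm = fit),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("qPCR standard curve: Cq = intercept + slope * log10(ng)\n")
  cat(sprintf("  slope      %8.4f Cq/decade (efficiency %.1f%%)\n",
              x$slope,
              if (x$slope < 0) amplification_efficiency(x$slope) else NA))
  cat(sprintf("  intercept  %8.4f Cq at 1 ng\n", x$intercept))
  cat(sprintf("  R-squared  %8.6f (gate: > %g -> %s)\n", x$r_squared,
              x$r2_threshold, if (x$qc_pass) "PASS" else "FAIL"))
  cat(sprintf("  standards  %d points spanning %g to %g ng\n",
              nrow(x$points), x$range_ng[1], x$range_ng[2]))
  invisible(x)
}

#' @export
summary.standard_curve <- function(object, ...) {
  print(object)
  cat("\nResiduals (Cq):\n")
  print(summary(stats::residuals(object$lm)))
  invisible(object)
}

#' @export
coef.standard_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.standard_curve <- function(object, ...) {
  stats::residuals(object$lm)
}

#' Predict Cq from quantity, or invert the curve
#'
#' With `quantity_ng` supplied, returns the fitted Cq. With `cq` supplied,
#' inverts the curve (equivalent to [interpolate_quantity()]).
#'
#' @param object A [standard_curve()].
#' @param quantity_ng Quantities in ng at which to predict Cq.
#' @param cq Cq values to invert into ng.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.standard_curve <- function(object, quantity_ng = NULL, cq = NULL,
                                   ...) {
  if (!is.null(quantity_ng)) {
    return(object$intercept + object$slope * log10(quantity_ng))
  }
  if (!is.null(cq)) {
    return(interpolate_quantity(object, cq, force = TRUE))
  }
  stats::fitted(object$lm)
}

#' Plot a standard curve
#'
#' Standards and fitted line on the log10(ng) axis.
#'
#' @param x A [standard_curve()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.standard_curve <- function(x, ...) {
  graphics::plot(x$points$log10_ng, x$points$cq,
                 xlab = "log10(quantity, ng)", ylab = "Cq",
                 main = sprintf("Standard curve (R² = %.4f)",
                                x$r_squared), ...)
  graphics::abline(x$intercept, x$slope, col = "steelblue")
  invisible(x)
}

#' Interpolate unknown quantities against a standard curve
#'
#' Inverts the fitted line: `ng = 10^((cq - intercept) / slope)`. Requires a
#' QC-passing curve (override with `force = TRUE`, which warns). Results
#' outside the standard series' quantity span are extrapolations and are
#' flagged in the `extrapolated` attribute, not forbidden.
#'
#' @param curve A [standard_curve()].
#' @param cq Cq values of the unknowns.
#' @param force Interpolate despite a failed QC gate.
#' @return Quantities in ng, with logical attribute `extrapolated`.
#' @examples
#' fit <- standard_curve(10^(2:-4), 24 - 3.3219 * log10(10^(2:-4)))
#' interpolate_quantity(fit, 24) # 1 ng by definition of the intercept
#' @export
interpolate_quantity <- function(curve, cq, force = FALSE) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope >= 0) {
    stop("invalid curve: slope must be negative for amplification",
         call. = FALSE)
  }
  if (!curve$qc_pass) {
    if (!force) {
      stop(sprintf(
        "standard curve failed QC (R-squared %.4f, required > %g); %s",
        curve$r_squared, curve$r2_threshold,
        "use force = TRUE to interpolate anyway"), call. = FALSE)
    }
    warning("interpolating against a curve that failed QC", call. = FALSE)
  }
  q <- 10^((cq - curve$intercept) / curve$slope)
  attr(q, "extrapolated") <- q < curve$range_ng[1] | q > curve$range_ng[2]
  q
}

#' Convert an interpolated quantity to molecule copies
#'
#' ng are converted to grams and delegated to [mass_to_copies()].
#'
#' @param quantity_ng Quantity in ng (>= 0).
#' @param mw Molecular weight in g/mol, e.g. [vegfa_mrna_mw()].
#' @return Molecule copies.
#' @examples
#' quantity_to_copies(1, vegfa_mrna_mw()) # ~2.17e9 copies per ng
#' @export
quantity_to_copies <- function(quantity_ng, mw) {
  mass_to_copies(quantity_ng * 1e-9, mw)
}

#' Amplification efficiency from a standard-curve slope
#'
#' `(10^(-1/slope) - 1) * 100`; a slope of -3.3219 Cq/decade (perfect
#' doubling each cycle) gives 100%.
#'
#' @param slope Standard-curve slope in Cq per decade (< 0).
#' @return Efficiency in percent.
#' @examples
#' amplification_efficiency(-3.3219)
#' @export
amplification_efficiency <- function(slope) {
  if (any(slope >= 0)) stop("slope must be negative", call. = FALSE)
  (10^(-1 / slope) - 1) * 100
}

#' Absolute quantification of unknowns through a standard curve
#'
#' Convenience composition of the absolute-quantification chain: technical
#' Cq replicates are averaged on the Cq scale per sample, interpolated
#' against the curve, converted to copies via the molecular weight, and
#' optionally divided by an entity count to give per-cell / per-EV copies.
#'
#' @param curve A [standard_curve()].
#' @param unknowns Data frame with columns `sample_id`, `cq`, and optionally
#'   `dilution_factor` (applied multiplicatively to the quantity).
#' @param mw Molecular weight in g/mol.
#' @param units Optional named or single entity count (cells, EVs) per
#'   sample.
#' @param force Passed to [interpolate_quantity()].
#' @return Data frame with one row per sample: mean Cq, quantity (ng),
#'   copies, and (if `units` given) `per_unit` copies.
#' @export
quantify_unknowns <- function(curve, unknowns, mw, units = NULL,
                              force = FALSE) {
  stopifnot(is.data.frame(unknowns),
            all(c("sample_id", "cq") %in% names(unknowns)))
  cq_mean <- tapply(unknowns$cq, unknowns$sample_id, mean)
  dil <- if ("dilution_factor" %in% names(unknowns)) {
    tapply(unknowns$dilution_factor, unknowns$sample_id, function(d) d[1])
  } else {
    rep(1, length(cq_mean))
  }
  q <- interpolate_quantity(curve, as.numeric(cq_mean), force = force)
  out <- data.frame(sample_id = names(cq_mean),
                    cq = as.numeric(cq_mean),
                    quantity_ng = as.numeric(q) * as.numeric(dil),
                    extrapolated = attr(q, "extrapolated"),
                    row.names = NULL)
  out$copies <- quantity_to_copies(out$quantity_ng, mw)
  if (!is.null(units)) {
    out$per_unit <- as.numeric(per_unit_copies(out$copies, units))
  }
  out
}
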