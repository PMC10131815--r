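#' Assemble a per-timepoint, per-compartment time course
#'
#' Validates and classes a long-format table of replicate measurements with
#' columns `timepoint_h`, `compartment`, `replicate`, `value`, and `unit`.
#' Units must be consistent within a compartment.
#'
#' @param records Data frame with the columns above (`unit` optional,
#'   defaults to `""`).
#' @return A data frame of class `timecourse`.
#' @examples
#' tc <- timecourse(data.frame(timepoint_h = c(1, 1, 5, 5),
#'                             compartment = "cell", replicate = c(1, 2),
#'                             value = c(1300, 1400, 420, 450)))
#' find_peak(tc, "cell")
#' @export
timecourse <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c("timepoint_h", "compartment", "replicate", "value")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    stop("timecourse records lack columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"unit" %in% names(records)) records$unit <- ""
  if (any(records$timepoint_h < 0)) {
    stop("timepoints must be non-negative", call. = FALSE)
  }
  per_comp_units <- tapply(records$unit, records$compartment,
                           function(u) length(unique(u)))
  if (any(per_comp_units > 1)) {
    stop("unit must be consistent within a compartment", call. = FALSE)
  }
  class(records) <- c("timecourse", "data.frame")
  records
}

.compartment_means <- function(tc, compartment) {
  rows <- tc[tc$compartment == compartment, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop(sprintf("no records for compartment '%s'", compartment),
         call. = FALSE)
  }
  means <- tapply(rows$value, rows$timepoint_h, mean)
  data.frame(timepoint_h = as.numeric(names(means)),
             mean = as.numeric(means))
}

#' Locate the peak of a compartment's time course
#'
#' Argmax over per-timepoint replicate means. Ties are broken toward the
#' earlier timepoint, with `tie = TRUE` flagged. Invariant to record order
#' and replicate permutation.
#'
#' @param tc A [timecourse()].
#' @param compartment Compartment label to summarize.
#' @return A list with `timepoint_h`, `mean`, and `tie`.
#' @export
find_peak <- function(tc, compartment) {
  m <- .compartment_means(tc, compartment)
  if (nrow(m) < 2) {
    stop("need >= 2 timepoints to locate a peak", call. = FALSE)
  }
  m <- m[order(m$timepoint_h), ]
  top <- which(m$mean == max(m$mean))
  list(timepoint_h = m$timepoint_h[top[1]],
       mean = m$mean[top[1]],
       tie = length(top) > 1)
}

#' Fold contrast between two compartments at one timepoint
#'
#' Ratio of per-timepoint replicate means, e.g. copies per cell over copies
#' per EV at 1 h. Delegates to [fold_ratio()].
#'
#' @param tc A [timecourse()].
#' @param a,b Compartment labels (numerator, denominator).
#' @param timepoint_h Timepoint at which to contrast.
#' @return The fold ratio (numeric).
#' @export
compartment_contrast <- function(tc, a, b, timepoint_h) {
  ma <- .compartment_means(tc, a)
  mb <- .compartment_means(tc, b)
  va <- ma$mean[ma$timepoint_h == timepoint_h]
  vb <- mb$mean[mb$timepoint_h == timepoint_h]
  if (length(va) == 0 || length(vb) == 0) {
    stop(sprintf("both compartments must be measured at t = %g h",
                 timepoint_h), call. = FALSE)
  }
  fold_ratio(va, vb)
}

.star_bands <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"))
}

.test_result <- function(statistic, p_value, method, comparisons = NULL) {
  structure(list(statistic = statistic, p_value = p_value, method = method,
                 comparisons = comparisons),
            class = "vesikin_test")
}

#' @export
print.vesikin_test <- function(x, ...) {
  cat(sprintf("%s\n  statistic = %.4g, p = %.4g (%s)\n",
              x$method, x$statistic, x$p_value,
              as.character(.star_bands(x$p_value))))
  if (!is.null(x$comparisons)) {
    cat("  pairwise comparisons (Dunn):\n")
    print(x$comparisons, row.names = FALSE)
  }
  invisible(x)
}

#' Two-sample Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent samples. The exact U
#' distribution is used when the smaller sample has n <= 8 and there are no
#' ties; otherwise the normal approximation with tie correction. The
#' reported statistic is U for the first sample.
#'
#' @param x,y Numeric samples, each with n >= 1.
#' @return A `vesikin_test` result with `statistic` (U), `p_value`, and
#'   `method`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= 8 && !has_ties
  wt <- stats::wilcox.test(x, y, exact = exact, correct = !exact,
                           alternative = "two.sided")
  .test_result(unname(wt$statistic), wt$p.value,
               if (exact) "Mann-Whitney U test (exact)"
               else "Mann-Whitney U test (normal approximation)")
}

# Dunn's z statistics on pooled ranks with tie correction; p-values are
# two-sided and adjusted by stats::p.adjust.
.dunn_pooled <- function(values, groups, adjust) {
  r <- rank(values)
  n <- tapply(r, groups, length)
  rbar <- tapply(r, groups, mean)
  N <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term
  labs <- names(n)
  pairs <- utils::combn(labs, 2)
  z <- apply(pairs, 2, function(pr) {
    (rbar[[pr[1]]] - rbar[[pr[2]]]) /
      sqrt(v0 * (1 / n[[pr[1]]] + 1 / n[[pr[2]]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
             p_value = p, p_adjusted = stats::p.adjust(p, method = adjust),
             row.names = NULL)
}

#' Kruskal-Wallis test with Dunn's multiple-comparison follow-up
#'
#' Kruskal-Wallis H (tie-corrected, via [stats::kruskal.test()]) across
#' three or more independent groups, followed by Dunn's pairwise
#' z-statistics on the pooled ranks. Pairwise p-values are two-sided and
#' adjusted by the chosen method (default Holm; Bonferroni and none are the
#' alternatives, mirroring common post-hoc conventions).
#'
#' @param groups A list of >= 3 numeric samples (named or not).
#' @param adjust Multiplicity adjustment for the pairwise p-values.
#' @return A `vesikin_test` result whose `comparisons` data frame holds the
#'   Dunn z, raw and adjusted p per pair.
#' @examples
#' kruskal_dunn(list(a = c(1, 2), b = c(3, 4), c = c(5, 6)))
#' @export
kruskal_dunn <- function(groups, adjust = c("holm", "bonferroni", "none")) {
  adjust <- match.arg(adjust)
  if (!is.list(groups) || length(groups) < 3) {
    stop("kruskal_dunn() needs >= 3 groups; use mann_whitney() for 2",
         call. = FALSE)
  }
  if (any(lengths(groups) < 1)) {
    stop("every group must be non-empty", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  glab <- factor(rep(names(groups), lengths(groups)),
                 levels = names(groups))
  if (length(unique(values)) == 1) {
    # fully tied data: no evidence against the null by construction
    npairs <- utils::combn(length(groups), 2)
    comp <- data.frame(group1 = names(groups)[npairs[1, ]],
                       group2 = names(groups)[npairs[2, ]],
                       z = 0, p_value = 1, p_adjusted = 1)
    return(.test_result(0, 1, "Kruskal-Wallis test with Dunn's post hoc",
                        comp))
  }
  kw <- stats::kruskal.test(values, glab)
  .test_result(unname(kw$statistic), kw$p.value,
               "Kruskal-Wallis test with Dunn's post hoc",
               .dunn_pooled(values, glab, adjust))
}

#' Friedman test with Dunn's multiple-comparison follow-up
#'
#' Friedman chi-squared on within-block ranks of a complete block design
#' (rows = blocks/subjects, columns = treatments), via
#' [stats::friedman.test()], followed by Dunn's pairwise z-statistics for
#' matched samples: `z = (Rbar_i - Rbar_j) / sqrt(k (k + 1) / (6 n))` with
#' `k` treatments and `n` blocks. Missing cells are an error; no imputation
#' is attempted.
#'
#' @param blocks Numeric matrix (or data frame) of matched measurements,
#'   blocks in rows, >= 3 treatment columns.
#' @param adjust Multiplicity adjustment for the pairwise p-values.
#' @return A `vesikin_test` result.
#' @examples
#' friedman_dunn(cbind(a = c(1, 2, 3, 4), b = c(2, 3, 4, 5),
#'                     c = c(5, 6, 7, 8)))
#' @export
friedman_dunn <- function(blocks, adjust = c("holm", "bonferroni", "none")) {
  adjust <- match.arg(adjust)
  m <- as.matrix(blocks)
  if (ncol(m) < 3) stop("need >= 3 treatments", call. = FALSE)
  if (nrow(m) < 2) stop("need >= 2 blocks", call. = FALSE)
  if (anyNA(m)) stop("incomplete block design: missing cells", call. = FALSE)
  if (is.null(colnames(m))) colnames(m) <- paste0("t", seq_len(ncol(m)))
  ranks <- t(apply(m, 1, rank))
  if (all(ranks == ranks[1, 1])) {
    # every block fully tied: statistic 0, no evidence against the null
    pairs <- utils::combn(colnames(m), 2)
    comp <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                       z = 0, p_value = 1, p_adjusted = 1)
    return(.test_result(0, 1, "Friedman test with Dunn's post hoc", comp))
  }
  ft <- stats::friedman.test(m)
  rbar <- colMeans(ranks)
  k <- ncol(m)
  n <- nrow(m)
  se <- sqrt(k * (k + 1) / (6 * n))
  pairs <- utils::combn(colnames(m), 2)
  z <- apply(pairs, 2, function(pr) (rbar[pr[1]] - rbar[pr[2]]) / se)
  p <- 2 * stats::pnorm(-abs(z))
  comp <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
                     p_value = p,
                     p_adjusted = stats::p.adjust(p, method = adjust),
                     row.names = NULL)
  .test_result(unname(ft$statistic), ft$p.value,
               "Friedman test with Dunn's post hoc", comp)
}
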