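#' Assign continuous activity values in `[0, 1]` to equal-width bins
#'
#' Uses the same convention as [classify_activity_bin()]: bins are closed
#' below and the top bin is closed at 1, so `n_bins` equal parts cover the
#' whole interval (with 4 bins: `[0,0.25) [0.25,0.5) [0.5,0.75) [0.75,1]`).
#' Binary 0/1 variables need no binning — they already form two categories —
#' and [bin_binary()] passes them through.
#'
#' @param values numeric vector in `[0, 1]`.
#' @param n_bins number of bins (>= 2), default 4.
#' @return Integer bin indices in `1..n_bins`.
#' @export
bin_values <- function(values, n_bins = 4) {
  stopifnot(n_bins >= 2)
  if (any(values < 0 | values > 1)) stop("values must lie in [0, 1]")
  pmin(floor(values * n_bins), n_bins - 1) + 1L
}

#' @rdname bin_values
#' @export
bin_binary <- function(values) {
  if (!all(values %in% c(0, 1))) stop("values must be 0 or 1")
  as.integer(values) + 1L
}

#' Pearson chi-squared test of independence on a contingency table
#'
#' Expected cell counts come from the row/column marginal products
#' `E = row_total * col_total / grand_total` (the standard Pearson
#' independence formulation); a uniform-expectation goodness-of-fit variant
#' (`expected = "uniform"`, every cell expected equal) is available for
#' comparison. The statistic is `sum((O - E)^2 / E)`, degrees of freedom
#' `(r - 1)(c - 1)` after dropping all-zero rows and columns, and the null
#' is rejected when the statistic exceeds the upper critical value of the
#' chi-squared distribution at the chosen significance level. Tables that
#' degenerate to fewer than two non-empty rows or columns yield an
#' inconclusive result rather than an error.
#'
#' @param counts matrix of non-negative integer counts (>= 2 rows and
#'   columns).
#' @param significance significance level, default 0.05.
#' @param expected `"margins"` (default) or `"uniform"`.
#' @return Object of class `independence_test`: list with `statistic`,
#'   `dof`, `critical_value`, `significance`, `reject` (NA when
#'   inconclusive), `inconclusive`, `observed`, `expected`.
#' @examples
#' chi_squared_independence(matrix(c(10, 0, 0, 10), 2))  # statistic 20
#' @export
chi_squared_independence <- function(counts, significance = 0.05,
                                     expected = c("margins", "uniform")) {
  expected <- match.arg(expected)
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("contingency table needs at least 2 rows and 2 columns")
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    return(structure(list(statistic = NA_real_, dof = NA_integer_,
                          critical_value = NA_real_,
                          significance = significance, reject = NA,
                          inconclusive = TRUE,
                          observed = counts, expected = NULL),
                     class = "independence_test"))
  }
  total <- sum(counts)
  E <- if (expected == "margins")
    outer(rowSums(counts), colSums(counts)) / total
  else matrix(total / length(counts), nrow(counts), ncol(counts))
  stat <- sum((counts - E)^2 / E)
  dof <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  crit <- stats::qchisq(1 - significance, df = dof)
  structure(list(statistic = stat, dof = dof, critical_value = crit,
                 significance = significance, reject = stat > crit,
                 inconclusive = FALSE, observed = counts, expected = E),
            class = "independence_test")
}

#' @export
print.independence_test <- function(x, ...) {
  if (x$inconclusive) {
    cat("Chi-squared independence test: inconclusive (degenerate table)\n")
  } else {
    cat(sprintf(paste0("Chi-squared independence test: X^2 = %.4f, ",
                       "dof = %d, critical = %.4f (alpha = %g) -> %s\n"),
                x$statistic, x$dof, x$critical_value, x$significance,
                if (x$reject) "reject independence" else "fail to reject"))
  }
  invisible(x)
}

#' Direction heuristic for an ordered-by-ordered association
#'
#' Given a contingency table whose row and column categories both carry an
#' inherent order (e.g. activity bins), computes the mean row-category index
#' conditional on each non-empty column level. The association is `positive`
#' if those conditional means strictly increase with the column level,
#' `negative` if they strictly decrease, and `indeterminate` otherwise
#' (non-monotone, e.g. U-shaped, profiles).
#'
#' @param counts matrix of counts with ordered rows (variable 1) and ordered
#'   columns (variable 2).
#' @return One of `"positive"`, `"negative"`, `"indeterminate"`.
#' @export
correlation_direction <- function(counts) {
  counts <- as.matrix(counts)
  keep <- colSums(counts) > 0
  counts <- counts[, keep, drop = FALSE]
  if (ncol(counts) < 2) return("indeterminate")
  means <- colSums(counts * seq_len(nrow(counts))) / colSums(counts)
  d <- diff(means)
  if (all(d > 0)) "positive"
  else if (all(d < 0)) "negative"
  else "indeterminate"
}

# Resolve one association variable on a completed scan.
#
# Returns a list(values, type) where type is "binary" or "activity".
# Units: "control" = one observation per control state; "attractor" = one
# observation per final state (the control-level quantities of its control
# state are attached to each attractor).
resolve_variable <- function(scan, var, unit) {
  tab <- scan$table
  ctrl <- scan$controls
  ints <- scan$internal
  per_control <- function(col, type) {
    if (unit == "control") list(values = col, type = type)
    else list(values = rep(col, vapply(scan$basins,
                                       function(b) length(b$attractors),
                                       numeric(1))),
              type = type)
  }
  if (var %in% ctrl) {
    per_control(tab[[var]], "binary")
  } else if (var == "combined") {
    per_control(tab$avg_combined, "activity")
  } else if (var %in% ints) {
    if (unit == "control") {
      list(values = tab[[paste0("avg_", var)]], type = "activity")
    } else {
      vals <- unlist(lapply(scan$basins, function(b)
        vapply(b$attractors, node_activity, numeric(1), node = var)))
      list(values = vals, type = "activity")
    }
  } else if (var %in% paste0("avg_", ints)) {
    per_control(tab[[var]], "activity")
  } else {
    stop("cannot resolve variable: ", var)
  }
}

#' Association report over a completed control-state scan
#'
#' For each requested pair of variables, builds the observations, bins
#' continuous activities into `n_bins` equal parts (binary control values
#' pass through), runs the chi-squared independence test, and — when
#' independence is rejected — reports the direction heuristic of
#' [correlation_direction()].
#'
#' Variables are resolved by name: a control-node name gives its 0/1 value;
#' an internal-node name gives its activity; `"combined"` gives the combined
#' reporter activity; `"avg_<node>"` forces the per-control-state average of
#' an internal node. The observation unit is one *final state* (attractor)
#' whenever either variable is an internal-node activity, otherwise one
#' *control state*; it can be forced per pair via `unit`. With
#' `weight = "basin"`, attractor-level observations are replicated by their
#' basin size `I(F)` (integer counts), i.e. weighted by the number of
#' initial conditions.
#'
#' @param scan a `control_scan`.
#' @param pairs list of pairs; each element is a list/character vector with
#'   `var1`, `var2`, and optionally `conditions` (named 0/1 vector of control
#'   values to filter on) and `unit` (`"auto"`, `"control"`, `"attractor"`).
#' @param n_bins bins for continuous variables, default 4.
#' @param significance significance level, default 0.05.
#' @param weight `"none"` (each observation once, default) or `"basin"`.
#' @return data.frame with one row per pair: `var1`, `var2`, `conditions`,
#'   `n_obs`, `statistic`, `dof`, `reject`, `direction`.
#' @export
association_report <- function(scan, pairs, n_bins = 4, significance = 0.05,
                               weight = c("none", "basin")) {
  weight <- match.arg(weight)
  stopifnot(inherits(scan, "control_scan"))
  rows <- lapply(pairs, function(p) {
    if (is.character(p)) p <- list(var1 = p[[1]], var2 = p[[2]])
    var1 <- p$var1 %||% p[[1]]
    var2 <- p$var2 %||% p[[2]]
    conditions <- p$conditions
    unit <- p$unit %||% "auto"
    if (unit == "auto")
      unit <- if (var1 %in% scan$internal || var2 %in% scan$internal)
        "attractor" else "control"
    v1 <- resolve_variable(scan, var1, unit)
    v2 <- resolve_variable(scan, var2, unit)
    keep <- rep(TRUE, length(v1$values))
    if (!is.null(conditions)) {
      for (nm in names(conditions)) {
        cond <- resolve_variable(scan, nm, unit)
        keep <- keep & (cond$values == conditions[[nm]])
      }
    }
    if (!any(keep))
      stop("conditioning filter leaves no observations for ",
           var1, " vs ", var2)
    x1 <- v1$values[keep]
    x2 <- v2$values[keep]
    w <- if (weight == "basin" && unit == "attractor") {
      unlist(lapply(scan$basins, function(b) b$basin_sizes))[keep]
    } else rep(1, length(x1))
    b1 <- if (v1$type == "binary") bin_binary(x1) else bin_values(x1, n_bins)
    b2 <- if (v2$type == "binary") bin_binary(x2) else bin_values(x2, n_bins)
    k1 <- if (v1$type == "binary") 2L else n_bins
    k2 <- if (v2$type == "binary") 2L else n_bins
    counts <- matrix(0, k1, k2)
    for (i in seq_along(b1))
      counts[b1[i], b2[i]] <- counts[b1[i], b2[i]] + w[i]
    test <- chi_squared_independence(counts, significance = significance)
    direction <- if (isTRUE(test$reject)) {
      # direction of var1 as var2 increases: var1 bins are rows
      correlation_direction(test$observed)
    } else if (test$inconclusive) "not_applicable" else "none"
    data.frame(var1 = var1, var2 = var2,
               conditions = if (is.null(conditions)) "-" else
                 paste(names(conditions), conditions, sep = "=",
                       collapse = ","),
               n_obs = sum(w),
               statistic = test$statistic, dof = test$dof,
               reject = test$reject, direction = direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
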