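#' Average per-operator measurements
#'
#' Each case is measured independently by several operators; the case-level
#' 3D error is the arithmetic mean of the operator RMS values. A single
#' operator is allowed but warned about, since operator averaging exists to
#' damp selection variability.
#'
#' @param operator_values numeric vector of non-negative RMS values (mm).
#' @return The mean (mm).
#' @export
average_operators <- function(operator_values) {
  if (length(operator_values) == 0L) {
    stop("no operator values", call. = FALSE)
  }
  if (any(operator_values < 0) || !all(is.finite(operator_values))) {
    stop("operator values must be finite and non-negative", call. = FALSE)
  }
  if (length(operator_values) == 1L) {
    warning("single operator value; no averaging performed", call. = FALSE)
  }
  mean(operator_values)
}

#' Per-group summary of 3D errors
#'
#' @param values numeric vector of case-level 3D errors (mm).
#' @return One-row tibble with `mean`, `sd` (sample SD, n-1 denominator; `NA`
#'   for a single value) and `n`.
#' @export
group_summary <- function(values) {
  if (length(values) == 0L) stop("empty group", call. = FALSE)
  tibble::tibble(mean = mean(values),
                 sd = if (length(values) >= 2L) stats::sd(values) else NA_real_,
                 n = length(values))
}

#' Kolmogorov-Smirnov normality check (Lilliefors)
#'
#' One-sample KS test of normality with mean and SD estimated from the data
#' (Lilliefors correction, via `nortest::lillie.test`). The plug-in
#' correction makes the test stricter than a naive KS against fixed
#' parameters, which would be anti-conservative here.
#'
#' @param values numeric vector, n >= 4, non-constant.
#' @return One-row tibble with `statistic`, `p_value` and `n`.
#' @export
ks_normality <- function(values) {
  if (length(values) < 4L) {
    stop("need at least 4 values for the normality test", call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    stop("constant input: normality test undefined (SD = 0)", call. = FALSE)
  }
  res <- nortest::lillie.test(values)
  tibble::tibble(statistic = unname(res$statistic),
                 p_value = res$p.value, n = length(values))
}

#' Two-group comparison of 3D errors
#'
#' Student's t-test between two groups of case-level 3D errors. Three modes
#' are available: `"independent-pooled"` (equal-variance two-sample t, the
#' default), `"independent-welch"`, and `"paired"`. The clinical protocol
#' this mirrors describes a "coupled samples" (paired) test while comparing
#' two independent patient groups; pairing across unrelated patients is
#' undefined, so the default here is the independent pooled test. Paired mode
#' remains available for genuinely paired designs (e.g. the same cases
#' re-measured under two settings).
#'
#' @param values_a,values_b numeric vectors of 3D errors (mm).
#' @param mode test variant; see above.
#' @param alpha significance level (default 0.05).
#' @param group_labels length-2 character labels for reporting.
#' @return A `group_comparison` object; see [tidy.group_comparison()] and
#'   [glance.group_comparison()].
#' @export
t_test <- function(values_a, values_b,
                   mode = c("independent-pooled", "independent-welch",
                            "paired"),
                   alpha = 0.05,
                   group_labels = c("splintless", "splint")) {
  mode <- match.arg(mode)
  na <- length(values_a)
  nb <- length(values_b)
  if (mode == "paired" && na != nb) {
    stop("paired mode requires equal group sizes", call. = FALSE)
  }
  if (na < 2L || nb < 2L) stop("need at least 2 values per group",
                               call. = FALSE)
  zero_var <- if (mode == "paired") stats::sd(values_a - values_b) == 0
              else stats::sd(values_a) == 0 && stats::sd(values_b) == 0
  if (zero_var) {
    # degenerate spread: equal means -> no evidence (p = 1 by convention);
    # a constant non-zero shift is infinitely many SDs away (p = 0)
    d <- mean(values_a) - mean(values_b)
    df <- if (mode == "paired") na - 1 else na + nb - 2
    t_stat <- if (d == 0) 0 else sign(d) * Inf
    p <- if (d == 0) 1 else 0
  } else {
    ht <- switch(mode,
      "independent-pooled" = stats::t.test(values_a, values_b,
                                           var.equal = TRUE),
      "independent-welch" = stats::t.test(values_a, values_b,
                                          var.equal = FALSE),
      "paired" = stats::t.test(values_a, values_b, paired = TRUE))
    t_stat <- unname(ht$statistic)
    df <- unname(ht$parameter)
    p <- ht$p.value
  }
  structure(list(
    group_labels = group_labels,
    means = c(mean(values_a), mean(values_b)),
    sds = c(if (na >= 2) stats::sd(values_a) else NA_real_,
            if (nb >= 2) stats::sd(values_b) else NA_real_),
    n = c(na, nb),
    test_used = mode,
    t_statistic = t_stat,
    degrees_of_freedom = df,
    p_value = p,
    alpha = alpha,
    significant = p < alpha
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s vs %s (%s)\n", x$group_labels[1],
              x$group_labels[2], x$test_used))
  cat(sprintf("  %s: mean %.3f mm (SD %.3f, n = %d)\n", x$group_labels[1],
              x$means[1], x$sds[1], x$n[1]))
  cat(sprintf("  %s: mean %.3f mm (SD %.3f, n = %d)\n", x$group_labels[2],
              x$means[2], x$sds[2], x$n[2]))
  cat(sprintf("  t = %.4f, df = %.4g, p = %.4f (%ssignificant at %.2g)\n",
              x$t_statistic, x$degrees_of_freedom, x$p_value,
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Tidy a group comparison
#'
#' @param x a `group_comparison` from [t_test()].
#' @param ... unused.
#' @return `tidy()`: one row per group with `group`, `mean`, `sd`, `n`.
#'   `glance()`: one row with the test statistic, df, p-value and
#'   significance flag.
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble::tibble(group = x$group_labels, mean = x$means, sd = x$sds, n = x$n)
}

#' @rdname tidy.group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(test_used = x$test_used, t_statistic = x$t_statistic,
                 degrees_of_freedom = x$degrees_of_freedom,
                 p_value = x$p_value, alpha = x$alpha,
                 significant = x$significant)
}

#' Tidy a registration report
#'
#' @param x a `registration_report` from [icp_refine()].
#' @param ... unused.
#' @return `tidy()`: per-iteration tibble (`iteration`, `rms`). `glance()`:
#'   one row with iteration count, convergence flag, final RMS and number of
#'   correspondences.
#' @export
tidy.registration_report <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$rms_per_iteration),
                 rms = x$rms_per_iteration)
}

#' @rdname tidy.registration_report
#' @export
glance.registration_report <- function(x, ...) {
  tibble::tibble(iterations_run = x$iterations_run, converged = x$converged,
                 final_rms = utils::tail(x$rms_per_iteration, 1),
                 correspondences_used = x$correspondences_used)
}

#' Tidy a deviation result
#'
#' @param x a `deviation_result` from [surface_deviation()].
#' @param ... unused.
#' @return `tidy()`: per-point tibble (`point_id`, `x`, `y`, `z`,
#'   `distance`). `glance()`: the summary row.
#' @export
tidy.deviation_result <- function(x, ...) {
  pts <- x$sample_points
  d <- x$distances
  tibble::tibble(point_id = seq_along(d),
                 x = pts[, 1], y = pts[, 2], z = pts[, 3], distance = d)
}

#' @rdname tidy.deviation_result
#' @export
glance.deviation_result <- function(x, ...) x$summary

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
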