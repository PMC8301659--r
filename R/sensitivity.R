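# Prior-scale sensitivity analysis: recompute a Bayes factor over a grid of
# prior settings and summarize whether the evidence category is stable.

#' Default Cauchy scale grid for sensitivity analysis
#'
#' Quarter-root-two through root-two: `sqrt(2)/4` (narrow), `sqrt(2)/2`
#' (the default "medium" prior), `1` (wide), `sqrt(2)` (ultrawide) --
#' spanning the conventional range of default effect-size priors.
#'
#' @return Increasing numeric vector of four scales.
#' @export
default_scale_grid <- function() c(sqrt(2) / 4, sqrt(2) / 2, 1, sqrt(2))

#' Bayes factor sensitivity curve
#'
#' Recomputes a Bayes factor across a grid of prior settings. For a
#' [two_arm_comparison()] the Cauchy prior scale is varied (the JZS Bayes
#' factor at each scale); for a [contingency_table_2x2()] the Beta prior
#' concentration `prior_a` is varied instead, an optional analog for the
#' binary-outcome analyses.
#'
#' @param x A [two_arm_comparison()] or [contingency_table_2x2()].
#' @param scales Strictly increasing positive grid; defaults to
#'   [default_scale_grid()].
#' @param analysis_id Provenance label carried into the tidy output.
#' @param ... Passed on to the underlying Bayes factor function
#'   (e.g. `variant` for tables).
#'
#' @return Object of class `"sensitivity_curve"`: a list with `scales`,
#'   `bf01`, `category`, `analysis_id`, `test`. `as.data.frame()` yields
#'   tidy long format (`analysis_id`, `scale`, `bf01`, `category`).
#' @export
#' @examples
#' cmp <- two_arm_comparison(t = 3, n1 = 50, n2 = 50)
#' sc <- sensitivity_curve(cmp)
#' as.data.frame(sc)
sensitivity_curve <- function(x, scales = default_scale_grid(),
                              analysis_id = "analysis", ...) {
  UseMethod("sensitivity_curve")
}

.check_scales <- function(scales) {
  if (!is.numeric(scales) || length(scales) < 1L || any(!is.finite(scales)) ||
      any(scales <= 0)) {
    stop("'scales' must be positive and finite", call. = FALSE)
  }
  if (is.unsorted(scales, strictly = TRUE)) {
    stop("'scales' must be strictly increasing", call. = FALSE)
  }
  as.numeric(scales)
}

#' @rdname sensitivity_curve
#' @export
sensitivity_curve.two_arm_comparison <- function(x,
                                                 scales = default_scale_grid(),
                                                 analysis_id = "analysis",
                                                 ...) {
  scales <- .check_scales(scales)
  bf01 <- vapply(scales,
                 function(r) jzs_bf01(x, prior = prior_spec(r), ...)$bf01,
                 numeric(1))
  structure(
    list(scales = scales, bf01 = bf01, category = categorize(bf01),
         analysis_id = analysis_id, test = "jzs_t"),
    class = "sensitivity_curve"
  )
}

#' @rdname sensitivity_curve
#' @export
sensitivity_curve.contingency_table_2x2 <- function(x,
                                                    scales = default_scale_grid(),
                                                    analysis_id = "analysis",
                                                    ...) {
  scales <- .check_scales(scales)
  bf01 <- vapply(scales, function(a) {
    tab <- contingency_table_2x2(x$n1, x$y1, x$n2, x$y2, prior_a = a)
    mortality_bf(tab, ...)$bf01
  }, numeric(1))
  structure(
    list(scales = scales, bf01 = bf01, category = categorize(bf01),
         analysis_id = analysis_id, test = "contingency"),
    class = "sensitivity_curve"
  )
}

#' @export
as.data.frame.sensitivity_curve <- function(x, ...) {
  data.frame(analysis_id = x$analysis_id, scale = x$scales, bf01 = x$bf01,
             category = x$category, stringsAsFactors = FALSE)
}

#' @export
print.sensitivity_curve <- function(x, ...) {
  cat("Sensitivity curve [", x$analysis_id, "]:\n", sep = "")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Summarize the robustness of a sensitivity curve
#'
#' @param curve A [sensitivity_curve()].
#' @return List with `min_bf01`, `max_bf01`, `categories` (unique evidence
#'   categories attained over the grid) and `stable` (`TRUE` iff a single
#'   category is attained).
#' @export
#' @examples
#' cmp <- two_arm_comparison(t = 3, n1 = 50, n2 = 50)
#' robustness_summary(sensitivity_curve(cmp))
robustness_summary <- function(curve) {
  stopifnot(inherits(curve, "sensitivity_curve"))
  cats <- unique(curve$category)
  list(min_bf01 = min(curve$bf01), max_bf01 = max(curve$bf01),
       categories = cats, stable = length(cats) == 1L)
}
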