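# Common result container for every Bayes factor the package computes.

#' Bayes factor result
#'
#' Container returned by all Bayes factor computations in the package.
#' `bf01` is the Bayes factor in favor of the null hypothesis (no effect /
#' independence); values above 1 favor the null, below 1 favor the
#' alternative. `bf10 = 1/bf01`.
#'
#' @param log_bf01 Natural log of BF01 (log scale avoids overflow for
#'   decisive data).
#' @param test Label of the test that produced the value: `"jzs_t"`,
#'   `"contingency_indep_binomial"` or `"contingency_gd_multinomial"`.
#' @param prior Prior description (a [prior_spec()] or a list of contingency
#'   prior parameters).
#' @param inputs Provenance record: the comparison or table the value was
#'   computed from.
#'
#' @return Object of class `"bf_result"` with fields `bf01`, `bf10`,
#'   `log_bf01`, `test`, `prior`, `inputs`, `category` (see [categorize()]).
#' @keywords internal
bf_result <- function(log_bf01, test, prior, inputs) {
  if (!is.finite(log_bf01)) {
    stop("Bayes factor computation returned a non-finite value", call. = FALSE)
  }
  bf01 <- exp(log_bf01)
  # categorize on a clamped log scale so that Bayes factors beyond double
  # range (decisive data) still land in the correct outer band
  category <- categorize(exp(min(max(log_bf01, -30), 30)))
  structure(
    list(bf01 = bf01, bf10 = exp(-log_bf01), log_bf01 = log_bf01,
         test = test, prior = prior, inputs = inputs, category = category),
    class = "bf_result"
  )
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("BF01 = %s (BF10 = %s) [%s]\n",
              format_bf(x$bf01), format_bf(x$bf10), x$test))
  cat("  evidence:", x$category, "\n")
  invisible(x)
}

#' Display-round a Bayes factor
#'
#' Renders a Bayes factor the way the reanalysis tables print it: two
#' decimal places below 1 and one decimal place at or above 1 (so 0.134
#' prints as "0.13" and 45.37 as "45.4").
#'
#' @param bf01 Positive numeric vector.
#' @return Character vector.
#' @export
#' @examples
#' format_bf(c(0.134, 2.83, 45.37))
format_bf <- function(bf01) {
  ifelse(bf01 < 1, sprintf("%.2f", bf01), sprintf("%.1f", bf01))
}
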