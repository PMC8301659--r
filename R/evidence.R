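# Verbal evidence categories for Bayes factors: the conventional ladder
# with moderate evidence beyond 3 (or 1/3) and strong evidence beyond 10
# (or 1/10).

#' Evidence category labels
#'
#' The five categories partitioning the positive half-line, ordered from
#' most pro-alternative to most pro-null.
#'
#' @return Character vector of the five labels.
#' @export
evidence_categories <- function() {
  c("strong_pro_alternative", "moderate_pro_alternative", "ambiguous",
    "moderate_pro_null", "strong_pro_null")
}

#' Evidence thresholds
#'
#' @return The numeric thresholds `c(1/10, 1/3, 3, 10)` separating the
#'   categories of [evidence_categories()].
#' @export
evidence_thresholds <- function() c(1 / 10, 1 / 3, 3, 10)

#' Categorize a Bayes factor on the evidence ladder
#'
#' Maps `BF01` values onto verbal evidence categories:
#' `BF01 <= 1/10` strong pro-alternative; `(1/10, 1/3]` moderate
#' pro-alternative; `(1/3, 3)` ambiguous; `[3, 10)` moderate pro-null;
#' `>= 10` strong pro-null. Exact threshold values are assigned to the
#' stronger (outer) category on the null side and to the weaker category on
#' the alternative side; thresholds are measure-zero and do not arise from
#' the pipeline's floating-point outputs, so the convention is cosmetic.
#'
#' @param bf01 Positive numeric vector of Bayes factors in favor of the null.
#' @return Character vector of category labels (see [evidence_categories()]).
#' @export
#' @examples
#' categorize(c(0.05, 0.13, 1, 8.3, 45.4))
categorize <- function(bf01) {
  if (!is.numeric(bf01) || length(bf01) < 1L) {
    stop("'bf01' must be numeric", call. = FALSE)
  }
  if (any(!is.finite(bf01)) || any(bf01 <= 0)) {
    stop("'bf01' must be finite and > 0", call. = FALSE)
  }
  labels <- evidence_categories()
  out <- character(length(bf01))
  out[bf01 <= 1 / 10] <- labels[1L]
  out[bf01 > 1 / 10 & bf01 <= 1 / 3] <- labels[2L]
  out[bf01 > 1 / 3 & bf01 < 3] <- labels[3L]
  out[bf01 >= 3 & bf01 < 10] <- labels[4L]
  out[bf01 >= 10] <- labels[5L]
  out
}
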