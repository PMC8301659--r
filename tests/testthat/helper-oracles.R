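# Brute-force numerical oracles, deliberately independent of the package's
# adaptive quadrature and closed forms: dense fixed-grid rules on explicit
# integral representations of each Bayes factor.

# JZS marginal likelihood by dense trapezoid over the effect size delta on
# [-lim, lim]. The default limit covers every delta whose noncentrality is
# within 15 of the observed t; beyond it the Cauchy x likelihood product is
# far below double precision.
oracle_jzs_bf01 <- function(t, n1, n2, r = sqrt(2) / 2, nodes = 2e5,
                            lim = NULL) {
  nu <- n1 + n2 - 2
  n_eff <- n1 * n2 / (n1 + n2)
  if (is.null(lim)) lim <- min(15, (abs(t) + 15) / sqrt(n_eff))
  d <- seq(-lim, lim, length.out = nodes)
  f <- suppressWarnings(stats::dt(t, df = nu, ncp = d * sqrt(n_eff))) *
    stats::dcauchy(d, 0, r)
  f[!is.finite(f)] <- 0
  p1 <- sum((f[-1] + f[-nodes]) / 2) * (d[2] - d[1])
  stats::dt(t, df = nu) / p1
}

# Contingency-table Bayes factors by Simpson-rule integration of the
# marginal likelihoods over the event rates: a 2-D grid over (theta1,
# theta2) in (0,1)^2 for H1, a 1-D grid for the common rate under H0.
# Binomial coefficients cancel between the two marginals and are omitted.
oracle_table_bf01 <- function(n1, y1, n2, y2, a = 1,
                              variant = c("indep_binomial",
                                          "gd_indep_multinomial"),
                              nodes = 1001) {
  variant <- match.arg(variant)
  th <- seq(0, 1, length.out = nodes)
  w <- rep(c(2, 4), length.out = nodes)
  w[1] <- 1
  w[nodes] <- 1
  h <- th[2] - th[1]
  kern <- function(y, n) th^y * (1 - th)^(n - y)
  f1 <- kern(y1, n1) * stats::dbeta(th, a, a)
  f2 <- kern(y2, n2) * stats::dbeta(th, a, a)
  m1 <- sum(outer(w * f1, w * f2)) * h^2 / 9
  a0 <- if (variant == "indep_binomial") a else 2 * a
  f0 <- kern(y1 + y2, n1 + n2) * stats::dbeta(th, a0, a0)
  m0 <- sum(w * f0) * h / 3
  m0 / m1
}

# Category index on the evidence ladder (1 = strongest pro-alternative).
category_index <- function(category) {
  match(category, evidence_categories())
}
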