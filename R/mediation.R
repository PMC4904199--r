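#' Sobel test from an indirect-effect summary
#'
#' Given an indirect-effect estimate and its standard error, returns
#' the Sobel z statistic and the two-sided normal p-value.
#'
#' @param indirect_estimate indirect effect (a x b).
#' @param indirect_se its standard error (> 0).
#' @return A list with `z` and `p`.
#' @examples
#' sobelFromSummary(0.35, 0.16)   # z ~ 2.19, p ~ 0.03
#' @export
sobelFromSummary <- function(indirect_estimate, indirect_se) {
  if (indirect_se <= 0) stop("indirect_se must be positive")
  z <- indirect_estimate / indirect_se
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Multilevel Sobel mediation analysis
#'
#' Tests whether a mediator carries part of a binary treatment's effect
#' on an outcome, with all three path models fit by the same multilevel
#' machinery as the main analyses ([fitMixed()]): mediator on treatment
#' (path a), outcome on treatment (total effect c), and outcome on
#' treatment plus mediator (paths b and c').  The indirect effect is
#' a x b with first-order Sobel standard error
#' sqrt(b^2 SE_a^2 + a^2 SE_b^2) (optionally second-order, adding
#' SE_a^2 SE_b^2), z = indirect / SE and a two-sided normal p.
#' Mediation is classified "inconsistent" when the direct effect c'
#' and the indirect effect have opposite signs — the signature of a
#' suppression-type pathway.
#'
#' In the light study the treatment is low vs high light, the mediator
#' is right-hemisphere pre-target log alpha of left-hemifield trials,
#' and the outcome is RT.  The mediator is standardised within the
#' mediation data before fitting (z and p are invariant; the sd used
#' is returned for back-transformation).
#'
#' @param data trial table restricted to the two treatment levels.
#' @param treatment column name of the binary treatment.
#' @param mediator column name of the mediator.
#' @param outcome column name of the outcome.
#' @param random character vector of random terms used in every path
#'   model.
#' @param treatment_levels the two levels, coded 0 and 1 in order.
#' @param standardize standardise the mediator before fitting.
#' @param second_order use the second-order Sobel variance.
#' @return A [MediationResult-class].
#' @export
mediationSobel <- function(data, treatment = "light_condition",
                           mediator = "log_alpha_right",
                           outcome = "rt_ms",
                           random = "(1 | participant_id)",
                           treatment_levels = c("low", "high"),
                           standardize = TRUE, second_order = FALSE) {
  lev <- unique(as.character(data[[treatment]]))
  if (!setequal(lev, treatment_levels) || length(lev) != 2L)
    stop("treatment must be binary with levels ",
         paste(treatment_levels, collapse = "/"),
         " (got: ", paste(lev, collapse = ", "), ")")
  d <- data
  d$.treat <- as.numeric(as.character(d[[treatment]]) ==
                           treatment_levels[2L])
  mSd <- 1
  m <- d[[mediator]]
  if (sd(m) == 0) stop("mediator is constant")
  if (standardize) {
    mSd <- sd(m)
    m <- (m - mean(m)) / mSd
  }
  d$.med <- m

  coefOf <- function(fit, term) {
    row <- fit$coefficients[fit$coefficients$term == term, ]
    c(est = row$estimate, se = row$se)
  }
  fa <- fitMixed(modelSpec(".med", ".treat", random), d)
  fc <- fitMixed(modelSpec(outcome, ".treat", random), d)
  fb <- fitMixed(modelSpec(outcome, c(".treat", ".med"), random), d)
  a <- coefOf(fa, ".treat"); cc <- coefOf(fc, ".treat")
  b <- coefOf(fb, ".med");  cp <- coefOf(fb, ".treat")

  indirect <- a[["est"]] * b[["est"]]
  v <- b[["est"]]^2 * a[["se"]]^2 + a[["est"]]^2 * b[["se"]]^2
  if (second_order) v <- v + a[["se"]]^2 * b[["se"]]^2
  se <- sqrt(v)
  st <- sobelFromSummary(indirect, se)
  consistency <- if (indirect != 0 && cp[["est"]] != 0 &&
                     sign(cp[["est"]]) != sign(indirect))
    "inconsistent" else "consistent"
  new("MediationResult",
      paths = c(a = a[["est"]], se_a = a[["se"]],
                b = b[["est"]], se_b = b[["se"]],
                c = cc[["est"]], se_c = cc[["se"]],
                c_prime = cp[["est"]], se_c_prime = cp[["se"]]),
      indirect = indirect, sobelSe = se, sobelZ = st$z, sobelP = st$p,
      consistency = consistency, mediatorSd = mSd)
}
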