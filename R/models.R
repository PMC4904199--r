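#' Specify a multilevel model
#'
#' Describes one of the study's models: the outcome, the fixed-effect
#' terms (R formula syntax), and the random-effect terms (lme4 syntax,
#' e.g. `"(1 | condition_order/participant_id)"` for the nesting of
#' participants inside counterbalancing orders, or
#' `"(0 + hemifield | participant_id)"` for a by-subject slope).
#'
#' @param outcome outcome column name (`"rt_ms"` or `"log_alpha"`).
#' @param fixed character vector of fixed-effect terms.
#' @param random character vector of random-effect terms (may be empty:
#'   the model is then fit by ordinary least squares).
#' @return A list of class `ModelSpec`.
#' @examples
#' modelSpec("rt_ms", c("light_condition * hemifield", "tnorm"),
#'           "(1 | participant_id)")
#' @export
modelSpec <- function(outcome, fixed, random = character(0)) {
  stopifnot(is.character(outcome), length(outcome) == 1L)
  structure(list(outcome = outcome, fixed = as.character(fixed),
                 random = as.character(random)), class = "ModelSpec")
}

specFormula <- function(spec) {
  rhs <- paste(c(if (length(spec$fixed)) spec$fixed else "1",
                 spec$random), collapse = " + ")
  as.formula(paste(spec$outcome, "~", rhs))
}

## Factor coding with fixed reference levels: low light, right
## hemifield, left hemisphere; light ordered low < medium < high.
codeFactors <- function(data) {
  if ("light_condition" %in% names(data))
    data$light_condition <- factor(data$light_condition,
                                   levels = LIGHT_LEVELS)
  if ("hemifield" %in% names(data))
    data$hemifield <- factor(data$hemifield, levels = c("right", "left"))
  if ("hemisphere" %in% names(data))
    data$hemisphere <- factor(data$hemisphere, levels = c("left", "right"))
  for (nm in c("condition_order", "participant_id"))
    if (nm %in% names(data)) data[[nm]] <- factor(data[[nm]])
  data
}

#' Fit a multilevel model by maximum likelihood
#'
#' Builds the model from a [modelSpec()] (factor coding with fixed
#' reference levels, fixed design matrix, random structure) and fits it
#' by maximum likelihood — via `lme4::lmer` when random terms are
#' present, ordinary least squares otherwise.  Rank-deficient fixed
#' designs error, listing the aliased terms; non-convergence is
#' recorded in the result, never silently accepted.
#'
#' @param spec a [modelSpec()].
#' @param data a screened trial table.
#' @return A list of class `FitResult`: `coefficients` (data.frame with
#'   `estimate`, `se`, `t`), `logLik`, `df` (fitted parameters),
#'   `n_obs`, `converged`, `singular`, `model` (the underlying fit),
#'   `spec`.
#' @export
fitMixed <- function(spec, data) {
  stopifnot(inherits(spec, "ModelSpec"))
  if (!spec$outcome %in% names(data))
    stop("outcome '", spec$outcome, "' not found in data")
  data <- codeFactors(data)
  fixedForm <- as.formula(paste(
    spec$outcome, "~",
    if (length(spec$fixed)) paste(spec$fixed, collapse = " + ") else "1"))
  mm <- model.matrix(fixedForm, data)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qrm$pivot[(qrm$rank + 1L):ncol(mm)]]
    stop("rank-deficient fixed design; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  if (!length(spec$random)) {
    fit <- lm(fixedForm, data = data)
    sm <- summary(fit)$coefficients
    res <- list(
      coefficients = data.frame(term = rownames(sm),
                                estimate = sm[, 1L], se = sm[, 2L],
                                t = sm[, 3L], row.names = NULL),
      logLik = as.numeric(logLik(fit)),
      df = attr(logLik(fit), "df"),
      n_obs = nrow(mm), converged = TRUE, singular = FALSE,
      model = fit, spec = spec)
  } else {
    conv <- TRUE
    ctrl <- lme4::lmerControl(optimizer = "bobyqa",
                              optCtrl = list(maxfun = 1e5))
    fit <- withCallingHandlers(
      lme4::lmer(specFormula(spec), data = data, REML = FALSE,
                 control = ctrl),
      warning = function(w) {
        if (grepl("converge", conditionMessage(w), ignore.case = TRUE))
          conv <<- FALSE
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        ## boundary (singular) fits are recorded via isSingular below
        if (grepl("singular|boundary", conditionMessage(m)))
          invokeRestart("muffleMessage")
      })
    if (length(fit@optinfo$conv$lme4$messages) &&
        any(grepl("converge", unlist(fit@optinfo$conv$lme4$messages),
                  ignore.case = TRUE)))
      conv <- FALSE
    sm <- summary(fit)$coefficients
    res <- list(
      coefficients = data.frame(term = rownames(sm),
                                estimate = sm[, 1L], se = sm[, 2L],
                                t = sm[, 3L], row.names = NULL),
      logLik = as.numeric(logLik(fit)),
      df = attr(logLik(fit), "df"),
      n_obs = stats::nobs(fit),
      converged = conv,
      singular = lme4::isSingular(fit),
      model = fit, spec = spec)
  }
  class(res) <- "FitResult"
  res
}

#' @export
print.FitResult <- function(x, ...) {
  cat(sprintf("FitResult: %s, n = %d, logLik = %.2f (df %d)%s%s\n",
              x$spec$outcome, x$n_obs, x$logLik, x$df,
              if (!x$converged) ", NOT CONVERGED" else "",
              if (x$singular) ", singular" else ""))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Likelihood-ratio test of nested maximum-likelihood fits
#'
#' chi-square = 2 (logLik_full - logLik_reduced) with degrees of
#' freedom equal to the parameter-count difference; p from the upper
#' chi-square tail.  The fits must be on the same rows.
#'
#' @param full,reduced [fitMixed()] results, `reduced` nested in
#'   `full`.
#' @param term optional label of the term being tested.
#' @return A list of class `LRTResult`: `chi_square`, `df`, `p_value`,
#'   `term`.
#' @export
lrTest <- function(full, reduced, term = NA_character_) {
  stopifnot(inherits(full, "FitResult"), inherits(reduced, "FitResult"))
  if (full$n_obs != reduced$n_obs)
    stop("fits use different numbers of observations")
  df <- full$df - reduced$df
  if (df < 0)
    stop("'reduced' has more parameters than 'full' (not nested)")
  chi <- max(0, 2 * (full$logLik - reduced$logLik))
  p <- if (df == 0) 1 else pchisq(chi, df, lower.tail = FALSE)
  structure(list(chi_square = chi, df = df, p_value = p, term = term),
            class = "LRTResult")
}

#' @export
print.LRTResult <- function(x, ...) {
  cat(sprintf("LRT%s: chi-square(%d) = %.3f, p = %.4g\n",
              if (!is.na(x$term)) paste0(" [", x$term, "]") else "",
              x$df, x$chi_square, x$p_value), sep = "")
  invisible(x)
}

#' Prune the random-effects structure iteratively
#'
#' Implements the parsimonious-structure procedure: the maximal model
#' (all candidate by-subject slopes) is attempted first; then, in the
#' listed candidate order, each random term is tested by comparing the
#' model without it to the model with it via likelihood-ratio test,
#' retaining only terms whose inclusion both converges and improves
#' fit (LRT p < `alpha`).  Intercept terms in `keep` are always
#' retained.  The audit trail records every comparison.
#'
#' @param spec a [modelSpec()] whose `random` holds the always-kept
#'   intercept terms.
#' @param data trial table.
#' @param candidates character vector of candidate random terms (lme4
#'   syntax), tested in order.
#' @param alpha retention threshold for the LRT p-value.
#' @return A list with `spec` (pruned [modelSpec()]), `audit`
#'   (data.frame: candidate, chi_square, df, p_value, converged,
#'   retained) and `maximal_converged`.
#' @export
pruneRandomStructure <- function(spec, data, candidates, alpha = 0.05) {
  stopifnot(inherits(spec, "ModelSpec"))
  if (!length(candidates))
    return(list(spec = spec,
                audit = data.frame(candidate = character(0)),
                maximal_converged = NA))
  maxSpec <- modelSpec(spec$outcome, spec$fixed,
                       c(spec$random, candidates))
  maxConv <- tryCatch(fitMixed(maxSpec, data)$converged,
                      error = function(e) FALSE)
  current <- spec$random
  base <- fitMixed(modelSpec(spec$outcome, spec$fixed, current), data)
  audit <- list()
  for (cand in candidates) {
    withCand <- tryCatch(
      fitMixed(modelSpec(spec$outcome, spec$fixed, c(current, cand)),
               data),
      error = function(e) NULL)
    if (is.null(withCand)) {
      audit[[cand]] <- data.frame(candidate = cand, chi_square = NA,
                                  df = NA, p_value = NA,
                                  converged = FALSE, retained = FALSE)
      next
    }
    lrt <- lrTest(withCand, base, term = cand)
    keep <- withCand$converged && lrt$p_value < alpha
    audit[[cand]] <- data.frame(candidate = cand,
                                chi_square = lrt$chi_square,
                                df = lrt$df, p_value = lrt$p_value,
                                converged = withCand$converged,
                                retained = keep)
    if (keep) {
      current <- c(current, cand)
      base <- withCand
    }
  }
  list(spec = modelSpec(spec$outcome, spec$fixed, current),
       audit = do.call(rbind, c(audit, list(make.row.names = FALSE))),
       maximal_converged = maxConv)
}

#' Multiplicity-adjusted pairwise contrasts of a factor
#'
#' All pairwise level differences of a fitted factor, with standard
#' errors from the fitted covariance and p-values adjusted over the
#' contrast family: `"single-step"` (multivariate-normal max-|t|, the
#' default), `"holm"`, `"bonferroni"` or `"none"`.  Tests use the
#' normal reference.
#'
#' @param fit a [fitMixed()] result containing the factor.
#' @param factor name of the factor column.
#' @param adjustment p-value adjustment method.
#' @return A data.frame with `contrast`, `estimate`, `se`, `z`,
#'   `p_raw`, `p_adj`, `adjustment`.
#' @export
pairwiseContrasts <- function(fit, factor = "light_condition",
                              adjustment = c("single-step", "holm",
                                             "bonferroni", "none")) {
  stopifnot(inherits(fit, "FitResult"))
  adjustment <- match.arg(adjustment)
  mf <- if (inherits(fit$model, "merMod"))
    fit$model@frame else fit$model$model
  if (!factor %in% names(mf) || !is.factor(mf[[factor]]))
    stop("'", factor, "' is not a factor in the fitted model")
  if (nlevels(droplevels(mf[[factor]])) < 2L)
    stop("factor has fewer than 2 levels in the fit")
  linfct <- do.call(multcomp::mcp, setNames(list("Tukey"), factor))
  gl <- multcomp::glht(fit$model, linfct = linfct)
  raw <- summary(gl, test = multcomp::adjusted("none"))
  adj <- if (adjustment == "single-step")
    summary(gl, test = multcomp::adjusted("single-step"))
  else if (adjustment == "none") raw
  else summary(gl, test = multcomp::adjusted(adjustment))
  data.frame(
    contrast = names(raw$test$coefficients),
    estimate = as.numeric(raw$test$coefficients),
    se = as.numeric(raw$test$sigma),
    z = as.numeric(raw$test$tstat),
    p_raw = as.numeric(raw$test$pvalues),
    p_adj = pmax(as.numeric(adj$test$pvalues),
                 as.numeric(raw$test$pvalues)),
    adjustment = adjustment, row.names = NULL)
}
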