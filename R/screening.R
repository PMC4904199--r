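#' Apply trial-exclusion rules
#'
#' Removes, in fixed order: trials without a response; pre-emptive
#' responses (RT < `rt_bounds[1]`, default 200 ms); responses after
#' coherent-motion offset (RT > `rt_bounds[2]`, default 1000 ms); and
#' trials whose broad-band voltage exceeds the artifact threshold on
#' any channel inside the purpose-specific window: -500..0 ms before
#' target onset for the pre-target alpha analysis, or -100 ms to
#' RT + 100 ms for the desynchronisation analysis used in electrode
#' selection.
#'
#' @param trials trial table (one row per epoch, aligned with
#'   `epochs`).
#' @param epochs matching [EpochSet-class]; may be `NULL`, in which
#'   case only the response-time rules are applied (behaviour-only
#'   simulations).
#' @param purpose `"pretarget"` or `"desync"`.
#' @param rt_bounds `c(low, high)` RT bounds in ms.
#' @param artifact_uv artifact threshold in microvolts.
#' @return A list with `trials` (surviving rows), `kept` (logical over
#'   input rows) and `report` (a `FilterReport`: per-rule removal
#'   counts and surviving n).
#' @export
filterTrials <- function(trials, epochs = NULL,
                         purpose = c("pretarget", "desync"),
                         rt_bounds = c(200, 1000), artifact_uv = 100) {
  purpose <- match.arg(purpose)
  if (!is.null(epochs)) {
    stopifnot(is(epochs, "EpochSet"))
    if (nrow(trials) != nTrials(epochs))
      stop("trials and epochs are not aligned (row counts differ)")
  }
  n <- nrow(trials)
  kept <- rep(TRUE, n)
  counts <- c(no_response = 0L, rt_low = 0L, rt_high = 0L, artifact = 0L)

  miss <- !trials$responded | is.na(trials$rt_ms)
  counts["no_response"] <- sum(miss & kept)
  kept[miss] <- FALSE
  low <- kept & trials$rt_ms < rt_bounds[1L]
  counts["rt_low"] <- sum(low)
  kept[low] <- FALSE
  high <- kept & trials$rt_ms > rt_bounds[2L]
  counts["rt_high"] <- sum(high)
  kept[high] <- FALSE

  if (!is.null(epochs)) {
    tt <- sampleTimes(epochs)
    surv <- which(kept)
    bad <- vapply(surv, function(i) {
      win <- if (purpose == "pretarget") c(-500, 0)
             else c(-100, trials$rt_ms[i] + 100)
      idx <- which(tt >= win[1L] & tt <= win[2L])
      any(abs(epochs@voltages[i, , idx]) > artifact_uv)
    }, logical(1L))
    counts["artifact"] <- sum(bad)
    kept[surv[bad]] <- FALSE
  }

  report <- structure(list(purpose = purpose, n_input = n,
                           removed = counts, surviving = sum(kept)),
                      class = "FilterReport")
  list(trials = trials[kept, , drop = FALSE], kept = kept,
       report = report)
}

#' @export
print.FilterReport <- function(x, ...) {
  cat(sprintf("FilterReport (%s): %d in, %d surviving\n", x$purpose,
              x$n_input, x$surviving))
  for (nm in names(x$removed))
    cat(sprintf("  %-12s %d\n", nm, x$removed[[nm]]))
  invisible(x)
}

#' Natural-log transform of alpha values
#'
#' Single-trial alpha amplitudes are strongly right-skewed; analyses
#' with alpha as the dependent variable use their natural logarithm.
#'
#' @param values positive numeric vector.
#' @return `log(values)`, with attribute `transform = "log"`.
#' @export
transformAlpha <- function(values) {
  bad <- which(!(values > 0))
  if (length(bad))
    stop("non-positive alpha value(s) at trial(s): ",
         paste(head(bad, 5L), collapse = ", "))
  structure(log(values), transform = "log")
}

#' Remove conditional-mean outliers
#'
#' Single-pass removal of observations farther than `k` standard
#' deviations from their group mean, within participant x condition
#' cells (plus hemisphere, for alpha measures).  Degenerate groups
#' (SD = 0, or fewer than 2 observations) remove nothing.
#'
#' @param values numeric vector (the model's dependent variable: RT in
#'   ms, or log alpha).
#' @param groups factor or interaction of grouping columns, same
#'   length as `values`.
#' @param k standard-deviation criterion.
#' @return A list with `kept` (logical), `removed` (indices) and
#'   `values` (surviving values).
#' @export
removeOutliers <- function(values, groups, k = 3) {
  stopifnot(length(values) == length(groups))
  groups <- as.factor(groups)
  mu <- ave(values, groups, FUN = function(x) mean(x, na.rm = TRUE))
  sdv <- ave(values, groups, FUN = function(x) {
    if (sum(!is.na(x)) < 2L) return(0)
    sd(x, na.rm = TRUE)
  })
  out <- !is.na(values) & sdv > 0 & abs(values - mu) > k * sdv
  list(kept = !out, removed = which(out), values = values[!out])
}
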