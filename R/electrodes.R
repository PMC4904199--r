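#' Select per-hemisphere electrodes most sensitive to spatial attention
#'
#' Ranks each hemisphere's candidate electrodes by their
#' contralateral-minus-ipsilateral post-target desynchronisation
#' difference and keeps the `k` most negative (strongest attention-
#' induced contralateral suppression), with deterministic tie-breaking
#' by candidate-list order.  `ranking = "magnitude"` instead ranks by
#' absolute difference, descending.
#'
#' @param desync_table output of [posttargetDesync()] covering all
#'   candidates of both pools.
#' @param pools candidate pools (default [candidatePools()]).
#' @param k electrodes to keep per hemisphere.
#' @param ranking `"signed"` (default, most negative first) or
#'   `"magnitude"`.
#' @param session_id optional identifier stored in the result.
#' @return A list of class `SelectionResult`: `session_id`, and per
#'   hemisphere the `chosen` labels plus the full named `metric`
#'   vector over its 8 candidates.
#' @export
selectElectrodes <- function(desync_table, pools = candidatePools(),
                             k = 4L, ranking = c("signed", "magnitude"),
                             session_id = NA_character_) {
  ranking <- match.arg(ranking)
  out <- list(session_id = session_id, k = k, ranking = ranking)
  for (h in c("left", "right")) {
    cand <- pools[[h]]
    if (k > length(cand))
      stop("k exceeds the candidate pool size (", length(cand), ")")
    row <- match(cand, desync_table$electrode)
    if (anyNA(row))
      stop("desync_table is missing candidate(s): ",
           paste(cand[is.na(row)], collapse = ", "))
    metric <- setNames(desync_table$diff[row], cand)
    key <- if (ranking == "signed") metric else -abs(metric)
    ord <- order(key, seq_along(cand))   # candidate order breaks ties
    out[[h]] <- list(chosen = cand[ord[seq_len(k)]], metric = metric)
  }
  class(out) <- "SelectionResult"
  out
}

#' @export
print.SelectionResult <- function(x, ...) {
  cat("Electrode selection", if (!is.na(x$session_id))
    paste0("(session ", x$session_id, ")"), "\n")
  for (h in c("left", "right"))
    cat(sprintf("  %-5s: %s\n", h, paste(x[[h]]$chosen, collapse = ", ")))
  invisible(x)
}

#' Cumulative light-condition topography
#'
#' Per-channel sum of the pairwise condition differences of pre-target
#' alpha means, (High - Low) + (High - Medium) + (Medium - Low), which
#' is algebraically identical to 2 x (High - Low).  Used to visualise
#' where on the scalp light modulates alpha power.
#'
#' @param low,medium,high named per-channel mean alpha vectors on
#'   identical channel sets.
#' @return A named per-channel numeric vector.
#' @export
cumulativeLightTopography <- function(low, medium, high) {
  if (!identical(names(low), names(medium)) ||
      !identical(names(low), names(high)))
    stop("condition maps must share an identical channel set")
  (high - low) + (high - medium) + (medium - low)
}
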