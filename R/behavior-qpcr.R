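#' Novel-object-recognition preference index
#'
#' Novel-object exploration time as a percentage of total exploration time:
#' `100 * t_novel / (t_novel + t_familiar)`.
#'
#' @param t_novel_s,t_familiar_s Exploration seconds; nonnegative.
#' @return Percent in [0, 100]; `NA` when both times are zero.
#' @export
#' @examples
#' preference_index(45, 15) # 75
preference_index <- function(t_novel_s, t_familiar_s) {
  if (any(t_novel_s < 0) || any(t_familiar_s < 0)) {
    abort("exploration times must be nonnegative")
  }
  total <- t_novel_s + t_familiar_s
  ifelse(total > 0, 100 * t_novel_s / total, NA_real_)
}

#' Y-maze spontaneous alternation percentage
#'
#' Sliding windows of three consecutive arm entries; a window visiting three
#' distinct arms (e.g. ABC, BCA, CAB) is a successful triad. Percent =
#' `100 * successes / (n_entries - 2)`.
#'
#' @param entries Character vector of arm labels drawn from A, B, C.
#' @return Percent in [0, 100]; `NA` when fewer than 3 entries.
#' @export
#' @examples
#' spontaneous_alternation(c("A", "B", "C", "A", "B", "C")) # 100
spontaneous_alternation <- function(entries) {
  entries <- as.character(entries)
  if (!all(entries %in% c("A", "B", "C"))) {
    abort("arm entries must be labels A, B or C")
  }
  n <- length(entries)
  if (n < 3) return(NA_real_)
  wins <- vapply(seq_len(n - 2L), function(i) {
    length(unique(entries[i:(i + 2L)])) == 3L
  }, logical(1))
  100 * sum(wins) / (n - 2L)
}

#' qPCR fold change by the 2^-ddCt method
#'
#' Per sample: `dCt = Ct_target - Ct_reference`; `ddCt = dCt - mean(dCt)` of
#' the control group; `fold = 2^-ddCt`. Expression of the target gene is
#' thereby normalized to the reference gene (e.g. GAPDH) and to the control
#' condition. Samples lacking a reference Ct are excluded with a warning.
#'
#' @param ct Data frame / tibble with columns `sample`, `condition`,
#'   `ct_target`, `ct_reference`.
#' @param control Label of the control condition.
#' @return Tibble: sample, condition, dct, ddct, fold_change.
#' @export
#' @examples
#' ct <- tibble::tibble(
#'   sample = c("c1", "c2", "t1"), condition = c("ctl", "ctl", "trt"),
#'   ct_target = c(24, 24, 25), ct_reference = c(20, 20, 20)
#' )
#' fold_change_ddct(ct, control = "ctl")
fold_change_ddct <- function(ct, control = "control") {
  ct <- tibble::as_tibble(ct)
  req <- c("sample", "condition", "ct_target", "ct_reference")
  if (!all(req %in% names(ct))) {
    abort(paste("ct table needs columns:", paste(req, collapse = ", ")))
  }
  drop <- !is.finite(ct$ct_reference)
  if (any(drop)) {
    warn(sprintf("excluding %d sample(s) without a reference Ct", sum(drop)))
    ct <- ct[!drop, ]
  }
  if (!any(ct$condition == control)) {
    abort(sprintf("no samples with control condition '%s'", control))
  }
  dct <- ct$ct_target - ct$ct_reference
  ref <- mean(dct[ct$condition == control])
  ddct <- dct - ref
  tibble::tibble(
    sample = ct$sample, condition = ct$condition,
    dct = dct, ddct = ddct, fold_change = 2^(-ddct)
  )
}

#' Group geometric-mean fold change
#' @param folds Result of [fold_change_ddct()].
#' @return Tibble: condition, n, geometric_mean_fold.
#' @export
fold_change_summary <- function(folds) {
  folds |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      geometric_mean_fold = exp(mean(log(.data$fold_change))),
      .groups = "drop"
    )
}
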