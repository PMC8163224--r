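# Test-cohort evaluation: per-case vote table, consensus calls, and
# nearest-percent accuracies.

#' Nearest-integer percent accuracy
#'
#' @param correct Logical vector (non-empty).
#' @return `round(100 * mean(correct))` to the nearest integer (half away
#'   from zero, so 13/15 -> 87, 14/15 -> 93, 11/15 -> 73).
#' @export
accuracy_percent <- function(correct) {
  if (length(correct) == 0) stop("accuracy of an empty vector is undefined")
  stopifnot(is.logical(correct), !anyNA(correct))
  floor(100 * mean(correct) + 0.5)
}

#' Evaluate a consensus panel on a test cohort
#'
#' Applies all eight predictors to every test subject's delta-Crt profile
#' in the panel's training stratum, forms the consensus call, and compares
#' with the truth labels. Indeterminate calls count as incorrect.
#' Per-predictor accuracies are computed over non-abstaining votes.
#'
#' @param panel A [fit_consensus_panel()] object.
#' @param test_nm Normalized test-cohort table.
#' @param truth Named character vector `subject_id -> DCV_POS/DCV_NEG`.
#'   Subjects without a truth label are excluded with a warning.
#' @param dedup Drop duplicated subject ids, keeping the first occurrence
#'   (experimental re-runs are distinct rows by default).
#' @return A `dcv_prediction` tibble: one row per subject with `truth`,
#'   one `vote_*` column per predictor, `n_pos`, `n_neg`, `call`,
#'   `correct`; the summary (n, n_correct, accuracy_percent, per-predictor
#'   accuracies) is attached as attribute `"summary"` and available via
#'   [glance.dcv_prediction()].
#' @export
evaluate_panel <- function(panel, test_nm, truth, dedup = FALSE) {
  stopifnot(inherits(panel, "consensus_panel"))
  profiles <- subject_profiles(test_nm, panel$fluid, panel$day)
  if (length(profiles) == 0) stop("Test set has no subjects in stratum ",
                                  panel$fluid, "/", panel$day)
  unlabeled <- setdiff(names(profiles), names(truth))
  if (length(unlabeled) > 0) {
    warning("Excluding subject(s) without truth labels: ",
            paste(unlabeled, collapse = ", "))
    profiles <- profiles[setdiff(names(profiles), unlabeled)]
  }
  if (length(profiles) == 0) stop("No labeled test subjects remain")
  if (dedup) profiles <- profiles[!duplicated(names(profiles))]

  pred_names <- names(panel$predictors)
  rows <- purrr::imap_dfr(profiles, function(prof, sid) {
    res <- predict(panel, prof)
    votes <- stats::setNames(as.list(res$votes),
                             paste0("vote_", pred_names))
    true_label <- truth[[sid]]
    tibble::tibble(
      subject_id = sid, truth = true_label, !!!votes,
      n_pos = res$n_pos, n_neg = res$n_neg, call = res$call,
      correct = res$call == true_label
    )
  })

  per_pred <- purrr::map_dfr(pred_names, function(p) {
    v <- rows[[paste0("vote_", p)]]
    keep <- v != "ABSTAIN"
    tibble::tibble(
      predictor = p,
      n_voted = sum(keep),
      accuracy_percent = if (any(keep)) {
        accuracy_percent(v[keep] == rows$truth[keep])
      } else {
        NA_real_
      }
    )
  })

  structure(
    rows,
    summary = list(
      n = nrow(rows),
      n_correct = sum(rows$correct),
      accuracy_percent = accuracy_percent(rows$correct),
      per_predictor = per_pred
    ),
    class = c("dcv_prediction", class(rows))
  )
}

#' @export
print.dcv_prediction <- function(x, ...) {
  s <- attr(x, "summary")
  cat("DCV risk prediction table: ", s$n_correct, "/", s$n,
      " correct (", s$accuracy_percent, "%)\n", sep = "")
  NextMethod()
}
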