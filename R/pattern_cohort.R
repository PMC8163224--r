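# Constructs a test cohort whose per-predictor correctness pattern is known
# exactly, by placing each subject's delta-Crt values on the requested side
# of every predictor's decision boundary. This is how cohort-level accuracy
# narratives (e.g. "one case wrong on all 8 predictors, one wrong on 5 of
# 8, consensus 13/15") are reproduced without patient-level data.

#' Generate a test cohort realizing a per-predictor error pattern
#'
#' Builds a Crt table of `n_subjects` test subjects (CSF at the panel's
#' training day) such that applying `panel` reproduces the requested
#' correctness pattern exactly: for every predictor named in
#' `error_pattern[[subject]]` the vote is wrong for that subject's truth
#' label, and every other vote is right. Threshold votes are realized by
#' placing the miRNA's value `margin` cycles on the chosen side of the
#' cutoff; the tree vote by routing down a leaf path of the requested class
#' with every split variable `tree_margin` cycles clear of its threshold.
#' Values of unconstrained miRNAs balance each sample to a zero mean shift
#' so global-mean normalization reproduces the targeted delta-Crt values to
#' within a few hundredths of a cycle.
#'
#' @param panel A [fit_consensus_panel()] object.
#' @param error_pattern Named list: `subject_id -> character vector` of
#'   predictor ids to make wrong (separator miRNA ids and/or `"tree"`).
#'   Subjects are `case01 ... caseNN`.
#' @param truth Optional named truth vector; by default subjects named in
#'   `error_pattern` are DCV- (so their wrong votes are false positives)
#'   and the remainder are split to roughly half DCV+.
#' @param n_subjects Number of test subjects; default 15.
#' @param baseline_crt Raw-Crt location the profiles are written around.
#' @param margin,tree_margin Clearance (cycles) from threshold cutoffs and
#'   tree split thresholds.
#' @return A list with `crt` (the [as_crt_tbl()] table) and `truth`.
#' @export
generate_pattern_cohort <- function(panel, error_pattern = list(),
                                    truth = NULL, n_subjects = 15,
                                    baseline_crt = 28,
                                    margin = 0.5, tree_margin = 0.3) {
  stopifnot(inherits(panel, "consensus_panel"))
  subjects <- sprintf("case%02d", seq_len(n_subjects))
  bad <- setdiff(names(error_pattern), subjects)
  if (length(bad) > 0) {
    stop("error_pattern names unknown subject(s): ",
         paste(bad, collapse = ", "))
  }
  pred_ids <- names(panel$predictors)
  bad_pred <- setdiff(unique(unlist(error_pattern)), pred_ids)
  if (length(bad_pred) > 0) {
    stop("error_pattern references unknown predictor(s): ",
         paste(bad_pred, collapse = ", "))
  }

  if (is.null(truth)) {
    truth <- stats::setNames(rep("DCV_NEG", n_subjects), subjects)
    free <- setdiff(subjects, names(error_pattern))
    truth[utils::head(free, ceiling(length(free) / 2))] <- "DCV_POS"
  }
  stopifnot(all(subjects %in% names(truth)),
            all(truth[subjects] %in% c("DCV_POS", "DCV_NEG")))

  mirnas <- panel_mirnas()
  flip <- function(lbl) if (lbl == "DCV_POS") "DCV_NEG" else "DCV_POS"

  profile_for <- function(sid) {
    wrong <- error_pattern[[sid]] %||% character()
    target <- stats::setNames(rep(NA_real_, length(mirnas)), mirnas)

    for (m in panel$separators) {
      p <- panel$predictors[[m]]
      want <- if (m %in% wrong) flip(truth[[sid]]) else truth[[sid]]
      pos_side <- want == "DCV_POS"
      above <- xor(p$orientation == "LOWER_IS_DCV", pos_side)
      target[m] <- p$cutoff + if (above) margin else -margin
    }

    want_tree <- if ("tree" %in% wrong) flip(truth[[sid]]) else truth[[sid]]
    constraints <- tree_class_constraints(panel$tree, want_tree, tree_margin,
                                          fixed = target)
    if (is.null(constraints)) {
      stop("Infeasible pattern for ", sid, ": no ", want_tree,
           " leaf of the tree is reachable consistent with the threshold ",
           "predictors (", paste(intersect(panel$separators,
                                           tree_vars_used(panel$tree$root)),
                                 collapse = ", "), ")")
    }
    for (v in names(constraints)) target[v] <- constraints[[v]]

    free <- is.na(target)
    target[free] <- 0
    target[free] <- -sum(target) / sum(free)
    target
  }

  rows <- purrr::map_dfr(subjects, function(sid) {
    d <- profile_for(sid)
    tibble::tibble(
      sample_id = paste(sid, panel$fluid, panel$day, sep = "_"),
      subject_id = sid,
      group = truth[[sid]],
      fluid = panel$fluid,
      day = panel$day,
      cohort = ifelse(match(sid, subjects) <= 9, "B", "C"),
      mirna_id = names(d),
      crt = baseline_crt + unname(d),
      qc_pass = TRUE
    )
  })
  list(crt = as_crt_tbl(rows), truth = truth[subjects])
}

# Value assignments routing the tree to a leaf of class `want`. Walks every
# root-to-leaf path of that class, accumulating (lo, hi) interval
# constraints per variable with `width` clearance from each threshold;
# returns the assignments of the first feasible path (shortest first), or
# NULL if none is consistent with the already-`fixed` values.
tree_class_constraints <- function(tree, want, width, fixed) {
  paths <- list()
  walk <- function(node, cons) {
    if (node$type == "leaf") {
      if (node$class == want) paths[[length(paths) + 1]] <<- cons
      return(invisible())
    }
    lcons <- cons
    lcons[[node$var]] <- c(
      lcons[[node$var]][1] %||% -Inf,
      min(lcons[[node$var]][2] %||% Inf, node$threshold - width)
    )
    walk(node$left, lcons)
    rcons <- cons
    rcons[[node$var]] <- c(
      max(rcons[[node$var]][1] %||% -Inf, node$threshold + width),
      rcons[[node$var]][2] %||% Inf
    )
    walk(node$right, rcons)
  }
  walk(tree$root, list())
  if (length(paths) == 0) return(NULL)
  paths <- paths[order(lengths(paths))]

  for (cons in paths) {
    ok <- TRUE
    out <- list()
    for (v in names(cons)) {
      lo <- cons[[v]][1]
      hi <- cons[[v]][2]
      if (lo > hi) {
        ok <- FALSE
        break
      }
      if (!is.na(fixed[[v]] %||% NA_real_)) {
        if (fixed[[v]] < lo || fixed[[v]] > hi) {
          ok <- FALSE
          break
        }
        next # already satisfied; keep the fixed value
      }
      out[[v]] <- if (is.finite(lo) && is.finite(hi)) {
        (lo + hi) / 2
      } else if (is.finite(lo)) {
        lo
      } else if (is.finite(hi)) {
        hi
      } else {
        0
      }
    }
    if (ok) return(out)
  }
  NULL
}

`%||%` <- function(a, b) if (is.null(a)) b else a
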