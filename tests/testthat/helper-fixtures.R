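# Shared fixture builders. Everything is generated in code; no data files.

# A tiny hand-built Crt table: `n_samples` CSF samples over the first
# `mirnas` panel entries, values supplied row-major (one row per sample).
tiny_crt <- function(values, mirnas = head(panel_mirnas(), ncol(values)),
                     fluid = "CSF", qc_pass = TRUE) {
  n <- nrow(values)
  rows <- tidyr::expand_grid(
    s = seq_len(n),
    m = seq_along(mirnas)
  )
  tibble::tibble(
    sample_id = paste0("S", rows$s, "_", fluid, "_PBD3"),
    subject_id = paste0("S", rows$s),
    group = rep_len(c("DCV_POS", "DCV_NEG"), n)[rows$s],
    fluid = fluid,
    day = "PBD3",
    cohort = "A",
    mirna_id = mirnas[rows$m],
    crt = values[cbind(rows$s, rows$m)],
    qc_pass = qc_pass
  ) |> as_crt_tbl()
}

# Normalized table built through the public path from per-sample delta
# targets: crt = 28 + delta, so arithmetic location is exactly 28 when each
# row sums to zero. Used where tests need controlled delta values.
nm_from_delta <- function(delta, mirnas = head(panel_mirnas(), ncol(delta)),
                          groups = rep_len(c("DCV_POS", "DCV_NEG"),
                                           nrow(delta))) {
  crt <- tiny_crt(28 + delta, mirnas)
  crt$group <- groups[match(crt$subject_id, unique(crt$subject_id))]
  crt <- as_crt_tbl(crt)
  mask <- suppressWarnings(apply_detection_rules(crt))
  suppressWarnings(normalize_global_mean(crt, mask, variant = "arithmetic"))
}

# Default training cohort artifacts at a fixed seed, computed once per run.
train_fixture <- local({
  cache <- NULL
  function(seed = 42) {
    if (is.null(cache)) {
      crt <- generate_cohort(synthetic_config(seed = seed))
      mask <- apply_detection_rules(crt)
      nm <- normalize_global_mean(crt, mask)
      cache <<- list(crt = crt, mask = mask, nm = nm,
                     panel = fit_consensus_panel(nm))
    }
    cache
  }
})

# exhaustive-search oracle for the best first split (lowest weighted Gini,
# ties to earliest variable then smallest threshold)
brute_best_split <- function(X, y) {
  gini <- function(yy) {
    p <- table(yy) / length(yy)
    1 - sum(p^2)
  }
  best <- NULL
  for (j in seq_along(X)) {
    u <- sort(unique(X[[j]]))
    if (length(u) < 2) next
    for (thr in (head(u, -1) + tail(u, -1)) / 2) {
      left <- X[[j]] < thr
      imp <- (sum(left) * gini(y[left]) +
                sum(!left) * gini(y[!left])) / length(y)
      if (is.null(best) || imp < best$impurity - 1e-12) {
        best <- list(var = names(X)[j], threshold = thr, impurity = imp)
      }
    }
  }
  best
}

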