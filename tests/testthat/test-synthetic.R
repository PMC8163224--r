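test_that("cohort generation is deterministic given the seed", {
  a <- generate_cohort(synthetic_config(seed = 11))
  b <- generate_cohort(synthetic_config(seed = 11))
  expect_identical(a, b)
  pa <- withr::local_tempfile(fileext = ".csv")
  pb <- withr::local_tempfile(fileext = ".csv")
  write_table(a, pa)
  write_table(b, pb)
  expect_identical(readLines(pa), readLines(pb))
  c <- generate_cohort(synthetic_config(seed = 12))
  expect_false(identical(a, c))
})

test_that("cohort covers fluids x days for patients and fluid-only for HC", {
  cfg <- synthetic_config(seed = 3)
  crt <- generate_cohort(cfg)
  meta <- sample_meta(crt)
  pat <- meta[meta$group != "HC", ]
  expect_identical(nrow(pat),
                   (cfg$n_dcv_pos + cfg$n_dcv_neg) * 4L) # 2 fluids x 2 days
  hc <- meta[meta$group == "HC", ]
  expect_identical(nrow(hc), cfg$n_hc * 2L)
  expect_true(all(is.na(hc$day)))
})

test_that("planted separators have disjoint group ranges at CSF/PBD3", {
  cfg <- synthetic_config(seed = 5)
  crt <- generate_cohort(cfg)
  x <- tibble::as_tibble(crt)
  x <- x[x$fluid == "CSF" & !is.na(x$day) & x$day == "PBD3", ]
  for (m in cfg$perfect_separators) {
    pos <- x$crt[x$mirna_id == m & x$group == "DCV_POS"]
    neg <- x$crt[x$mirna_id == m & x$group == "DCV_NEG"]
    overlap_pairs <- sum(outer(pos, neg, function(p, n) {
      sign(p - n) != sign(mean(pos) - mean(neg))
    }))
    expect_identical(overlap_pairs, 0L)
    expect_gte(min(abs(range(pos) - rev(range(neg)))), cfg$gap)
  }
})

test_that("the detectability filter removes exactly the planted sets", {
  fx <- train_fixture()
  removed <- fx$mask$removed
  cfg <- synthetic_config()
  expect_setequal(removed$mirna_id[removed$fluid == "CSF"],
                  cfg$low_expression$CSF)
  expect_setequal(removed$mirna_id[removed$fluid == "PLASMA"],
                  cfg$low_expression$PLASMA)
})

test_that("censored fraction of low-expression miRNAs matches the target", {
  fracs <- vapply(1:20, function(s) {
    cfg <- synthetic_config(seed = 100 + s, missing_rate = 0)
    crt <- tibble::as_tibble(generate_cohort(cfg))
    low <- rbind(
      crt[crt$fluid == "CSF" & crt$mirna_id %in% cfg$low_expression$CSF, ],
      crt[crt$fluid == "PLASMA" &
            crt$mirna_id %in% cfg$low_expression$PLASMA, ]
    )
    mean(low$crt >= cfg$detection_limit)
  }, 0)
  expect_lt(abs(mean(fracs) - 0.8), 0.1)
})

test_that("planted effects are recovered with high sensitivity/specificity", {
  # sensitivity over the planted set must be near-perfect; the null
  # false-positive count is a Bernoulli(alpha) draw per null miRNA, so it
  # is checked against the central 99% binomial band at alpha = 0.05
  cfg0 <- synthetic_config()
  planted <- cfg0$effect_sizes
  n_hit <- n_planted <- n_fp <- n_null <- 0
  for (i in 1:12) {
    cfg <- synthetic_config(seed = 200 + i)
    crt <- generate_cohort(cfg)
    mask <- apply_detection_rules(crt)
    nm <- normalize_global_mean(crt, mask)
    de <- differential_expression(nm, mask)
    for (fl in c("CSF", "PLASMA")) {
      planted_fl <- planted$mirna_id[planted$fluid == fl]
      hits <- de$mirna_id[de$fluid == fl & de$comparison == "I" &
                            !is.na(de$p_value) & de$p_value < 0.05]
      nulls <- setdiff(unique(de$mirna_id[de$fluid == fl &
                                            !is.na(de$p_value)]), planted_fl)
      n_hit <- n_hit + length(intersect(hits, planted_fl))
      n_planted <- n_planted + length(planted_fl)
      n_fp <- n_fp + length(intersect(hits, nulls))
      n_null <- n_null + length(nulls)
    }
  }
  expect_gte(n_hit / n_planted, 0.95)
  bounds <- qbinom(c(0.005, 0.995), n_null, 0.05)
  expect_gte(n_fp, bounds[1])
  expect_lte(n_fp, bounds[2])
})

test_that("an impossible separator gap is rejected, not silently violated", {
  expect_error(synthetic_config(gap = -1))
  # zero within-group SD makes the default gap (4 SD) infeasible already
  # at configuration time
  expect_error(synthetic_config(baseline_crt_sd = 0))
  # and a positive gap with zero SD is caught at generation time
  cfg <- synthetic_config(baseline_crt_sd = 1)
  cfg$baseline_crt_sd <- 0
  expect_error(generate_cohort(cfg), "SD")
})

test_that("pattern cohorts realize the requested correctness exactly", {
  fx <- train_fixture()
  panel <- fx$panel
  ids <- names(panel$predictors)

  # empty pattern: everything correct
  clean <- generate_pattern_cohort(panel)
  nm <- suppressWarnings(normalize_global_mean(
    clean$crt, apply_detection_rules(clean$crt)))
  pred <- evaluate_panel(panel, nm, clean$truth)
  expect_identical(glance(pred)$accuracy_percent, 100)

  # 4 of 8 wrong on one DCV- subject: indeterminate under the >=5 rule
  pat <- list(case02 = head(ids, 4))
  truth <- stats::setNames(rep("DCV_NEG", 15), sprintf("case%02d", 1:15))
  four <- generate_pattern_cohort(panel, pat, truth = truth)
  nm4 <- suppressWarnings(normalize_global_mean(
    four$crt, apply_detection_rules(four$crt)))
  pred4 <- evaluate_panel(panel, nm4, four$truth)
  row <- pred4[pred4$subject_id == "case02", ]
  expect_identical(row$call, "INDETERMINATE")
  expect_identical(row$n_pos, 4L)
  expect_false(row$correct)
})

test_that("unknown subjects or predictors in a pattern are rejected", {
  fx <- train_fixture()
  expect_error(generate_pattern_cohort(fx$panel, list(case99 = "tree")),
               "case99")
  expect_error(generate_pattern_cohort(fx$panel, list(case01 = "nope")),
               "nope")
})
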