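test_that("detection rules censor at the limit and honor QC flags", {
  crt <- tiny_crt(matrix(c(35.0, 34.9, 34.9, 20, 20, 20), nrow = 2,
                         byrow = TRUE))
  # second sample's first cell fails QC despite Crt < 35
  crt$qc_pass[crt$sample_id == "S2_CSF_PBD3" &
                crt$mirna_id == panel_mirnas()[1]] <- FALSE
  crt <- as_crt_tbl(crt)
  mask <- suppressWarnings(apply_detection_rules(crt))
  det <- mask$detectable
  get <- function(s, j) det$detectable[det$sample_id == s &
                                         det$mirna_id == panel_mirnas()[j]]
  expect_false(get("S1_CSF_PBD3", 1)) # exactly at limit -> undetectable
  expect_true(get("S1_CSF_PBD3", 2)) # just under the limit
  expect_false(get("S2_CSF_PBD3", 1)) # QC override
  expect_false(any(det$detectable[is.na(crt$crt)]))
})

test_that("two-thirds detectability rule removes by per-fluid count", {
  # 14 CSF samples, one miRNA detected in 9 of them: 9 < ceil(2/3*14) = 10
  m <- matrix(25, nrow = 14, ncol = 2)
  m[1:5, 1] <- 36 # 5 undetectable -> 9 detected
  crt <- tiny_crt(m)
  mask <- suppressWarnings(apply_detection_rules(crt))
  expect_identical(mask$removed$mirna_id, panel_mirnas()[1])
  # 10 of 14 detected passes
  m[5, 1] <- 25
  mask2 <- suppressWarnings(apply_detection_rules(tiny_crt(m)))
  expect_identical(nrow(mask2$removed), 0L)
})

test_that("geometric and arithmetic locations match hand computation", {
  crt <- tiny_crt(matrix(c(20, 25, 30), nrow = 1))
  mask <- suppressWarnings(apply_detection_rules(crt))

  geo <- suppressWarnings(normalize_global_mean(crt, mask, "geometric"))
  expect_equal(unique(geo$location), (20 * 25 * 30)^(1 / 3),
               tolerance = 1e-12)
  expect_equal(geo$delta_crt, c(20, 25, 30) - (15000)^(1 / 3),
               tolerance = 1e-12)

  ari <- suppressWarnings(normalize_global_mean(crt, mask, "arithmetic"))
  expect_equal(unique(ari$location), 25)
  expect_equal(ari$delta_crt, c(-5, 0, 5))
  expect_equal(sum(ari$delta_crt), 0, tolerance = 1e-9)
})

test_that("a constant sample normalizes to all-zero delta", {
  crt <- tiny_crt(matrix(30, nrow = 1, ncol = 4))
  mask <- suppressWarnings(apply_detection_rules(crt))
  nm <- suppressWarnings(normalize_global_mean(crt, mask))
  expect_equal(unique(nm$location), 30)
  expect_equal(nm$delta_crt, rep(0, 4))
})

test_that("arithmetic variant is zero-sum and shift-invariant", {
  set.seed(7)
  vals <- matrix(rnorm(5 * 6, 28, 1.5), nrow = 5)
  crt <- tiny_crt(vals)
  mask <- suppressWarnings(apply_detection_rules(crt))
  nm <- suppressWarnings(normalize_global_mean(crt, mask, "arithmetic"))
  sums <- tapply(nm$delta_crt, nm$sample_id, sum)
  expect_true(all(abs(sums) < 1e-9))

  shifted <- tiny_crt(vals + 2)
  nm2 <- suppressWarnings(normalize_global_mean(
    shifted, suppressWarnings(apply_detection_rules(shifted)), "arithmetic"))
  expect_equal(nm2$delta_crt, nm$delta_crt, tolerance = 1e-9)
  expect_equal(unique(nm2$location - nm$location), 2, tolerance = 1e-9)
})

test_that("geometric location is recoverable from its own output", {
  fx <- train_fixture()
  nm <- fx$nm
  chk <- tibble::as_tibble(nm) |>
    dplyr::filter(!is.na(delta_crt)) |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(
      loc = unique(location),
      recomputed = exp(mean(log(delta_crt + loc))),
      .groups = "drop"
    )
  expect_true(all(abs(chk$loc - chk$recomputed) < 1e-9))
})

test_that("removed miRNAs are dropped and normalization is idempotent", {
  fx <- train_fixture()
  removed_csf <- fx$mask$removed$mirna_id[fx$mask$removed$fluid == "CSF"]
  csf_mirnas <- unique(fx$nm$mirna_id[fx$nm$fluid == "CSF"])
  expect_length(intersect(removed_csf, csf_mirnas), 0)

  again <- normalize_global_mean(fx$crt, fx$mask)
  expect_equal(tibble::as_tibble(again), tibble::as_tibble(fx$nm))
})

test_that("samples with fewer than two detectable values are excluded", {
  m <- matrix(25, nrow = 3, ncol = 3)
  m[1, ] <- c(25, 36, NA) # one detectable value only
  crt <- tiny_crt(m)
  mask <- suppressWarnings(apply_detection_rules(crt))
  expect_warning(nm <- normalize_global_mean(crt, mask),
                 "S1_CSF_PBD3")
  expect_false("S1_CSF_PBD3" %in% nm$sample_id)
})
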