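test_that("packaged panel definition is well-formed", {
  panel <- dcv_panel()
  expect_false(any(duplicated(panel$mirna_id)))
  expect_true(all(grepl("^[ACGU]+$", panel$sequence)))
  expect_identical(sum(!panel$analyzable), 1L)
  expect_identical(panel$mirna_id[!panel$analyzable], "mmu-miR-155-5p")
  expect_false(any(grepl("U6", panel$mirna_id)))
  expect_identical(panel_mirnas(), panel$mirna_id[panel$analyzable])
})

test_that("long CSV round-trips a Crt table including missing cells", {
  crt <- tiny_crt(matrix(c(20, 25, 30, 21, NA, 31), nrow = 2, byrow = TRUE))
  expect_identical(sum(is.na(crt$crt)), 1L)

  path <- withr::local_tempfile(fileext = ".csv")
  write_table(crt, path)
  back <- read_crt_table(path, format = "long")
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(crt))
})

test_that("the 'NA' sentinel reads as missing, never as zero", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,subject_id,group,fluid,day,cohort,mirna_id,crt,qc_pass",
    "S1_CSF_PBD3,S1,DCV_POS,CSF,PBD3,A,hsa-let-7a-5p,NA,TRUE",
    "S1_CSF_PBD3,S1,DCV_POS,CSF,PBD3,A,hsa-let-7b-5p,,TRUE",
    "S1_CSF_PBD3,S1,DCV_POS,CSF,PBD3,A,hsa-let-7c-5p,24.5,TRUE"
  ), path)
  x <- read_crt_table(path, format = "long")
  expect_identical(sum(is.na(x$crt)), 2L)
  expect_false(any(x$crt == 0, na.rm = TRUE))
})

test_that("wide and long dialects produce identical tables", {
  crt <- tiny_crt(matrix(c(20, 25, 30, 21, NA, 31), nrow = 2, byrow = TRUE))
  long_path <- withr::local_tempfile(fileext = ".csv")
  wide_path <- withr::local_tempfile(fileext = ".csv")
  write_table(crt, long_path, format = "long")
  write_table(crt, wide_path, format = "wide")
  from_long <- read_crt_table(long_path, "long")
  from_wide <- read_crt_table(wide_path, "wide")
  key <- function(x) dplyr::arrange(tibble::as_tibble(x), sample_id, mirna_id)
  expect_equal(key(from_wide), key(from_long))
})

test_that("validation rejects duplicates, bad enums, and unparseable values", {
  crt <- tibble::as_tibble(tiny_crt(matrix(c(20, 25), nrow = 1)))
  expect_error(as_crt_tbl(dplyr::bind_rows(crt, crt[1, ])),
               "Duplicate.*hsa-let-7a-5p")

  bad_group <- dplyr::mutate(crt, group = "CASE")
  expect_error(as_crt_tbl(bad_group), "group.*CASE")

  hc_with_day <- dplyr::mutate(crt, group = "HC")
  expect_error(as_crt_tbl(hc_with_day), "day = NA")

  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,subject_id,group,fluid,day,cohort,mirna_id,crt,qc_pass",
    "S1_CSF_PBD3,S1,DCV_POS,CSF,PBD3,A,hsa-let-7a-5p,twenty,TRUE"
  ), path)
  expect_error(read_crt_table(path, "long"), "Unparseable.*twenty")
})

test_that("unknown miRNA columns in wide input need the permissive flag", {
  crt <- tiny_crt(matrix(c(20, 25), nrow = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(crt)[, c(names(crt)[1:6], "mirna_id", "crt")],
    names_from = mirna_id, values_from = crt
  )
  wide$`made-up-miR` <- 22
  readr::write_csv(wide, path, na = "")
  expect_error(read_crt_table(path, "wide"), "made-up-miR")
  ok <- read_crt_table(path, "wide", permissive = TRUE)
  expect_true("made-up-miR" %in% ok$mirna_id)
})

test_that("normalized tables round-trip through CSV with missing cells", {
  fx <- train_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_table(fx$nm, path)
  back <- read_norm_table(path)
  expect_equal(attr(back, "variant"), attr(fx$nm, "variant"))
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(fx$nm),
               tolerance = 1e-9)
  expect_identical(sum(is.na(back$delta_crt)), sum(is.na(fx$nm$delta_crt)))
})

test_that("prediction tables serialize votes as per-predictor columns", {
  fx <- train_fixture()
  test <- generate_pattern_cohort(fx$panel)
  tnm <- suppressWarnings(normalize_global_mean(
    test$crt, apply_detection_rules(test$crt)))
  pred <- evaluate_panel(fx$panel, tnm, test$truth)
  path <- withr::local_tempfile(fileext = ".csv")
  write_table(pred, path)
  on_disk <- readr::read_csv(path, show_col_types = FALSE)
  expect_true(all(paste0("vote_", names(fx$panel$predictors)) %in%
                    names(on_disk)))
  expect_identical(nrow(on_disk), nrow(pred))
})
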