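test_that("the doubling rule finds the elongation onset and skips dividing cells", {
  expect_identical(detect_elongation_onset(c(5, 5, 5, 11, 13, 20)), 4L)
  # cell 3 doubles but its successor is shorter (a dividing cell): skip to 5
  expect_identical(detect_elongation_onset(c(5, 5, 12, 11, 24, 30, 40)), 5L)
  expect_error(detect_elongation_onset(rep(7, 20)),
               class = "rootkin_error_segmentation")
  expect_error(detect_elongation_onset(c(5, 10)),
               class = "rootkin_error_insufficient_data")
  # the final cell can never be the onset: doubling at the end does not count
  expect_error(detect_elongation_onset(c(5, 5, 5, 12)),
               class = "rootkin_error_segmentation")
})

test_that("the maturation rule finds where elongation ceases", {
  lens <- c(5, 5, 100, 140, 180, 182, 181, 185, 183)
  onset <- detect_elongation_onset(lens)
  expect_identical(onset, 3L)
  # first cell approximately matching its successor (182 <= 1.05 * 180)
  expect_identical(detect_maturation_onset(lens, onset), 5L)
  # a profile that keeps elongating by 10% per cell never matures at tol 5%
  ramp <- c(5, 5, 12, 15 * 1.1^(0:12))
  expect_error(detect_maturation_onset(ramp, 3L, tol = 0.05),
               class = "rootkin_error_segmentation")
})

test_that("mature cell length is the mean of the first five mature cells", {
  expect_equal(mature_cell_length(c(200, 210, 190, 205, 195), 1L), 200)
  expect_equal(mature_cell_length(c(1, 2, rep(150, 5)), 3L), 150)
  expect_error(mature_cell_length(c(1, 2, 150, 150), 3L),
               class = "rootkin_error_insufficient_data")
})

test_that("both detectors agree exactly with brute-force scans, including failures", {
  withr::with_seed(2024, {
    for (rep in 1:1000) {
      lens <- random_length_sequence()
      bf <- bf_elongation_onset(lens)
      got <- tryCatch(detect_elongation_onset(lens), error = function(e) NA_integer_)
      expect_identical(got, bf)
      if (!is.na(bf)) {
        bfm <- bf_maturation_onset(lens, bf)
        gotm <- tryCatch(detect_maturation_onset(lens, bf),
                         error = function(e) NA_integer_)
        expect_identical(gotm, bfm)
      }
    }
  })
})

test_that("a sharp-transition profile is recovered exactly", {
  lens <- sharp_profile() # 50 cells of 10 um, doubling step, mature 150 um
  onset <- detect_elongation_onset(lens)
  expect_identical(onset, 51L)
  mat <- detect_maturation_onset(lens, onset)
  expect_identical(lens[mat], 150)
  expect_equal(mature_cell_length(lens, mat), 150)

  seg <- segment_cell_file(tibble::tibble(
    root_id = "r1", file_side = "single",
    cell_index = seq_along(lens), length_um = lens
  ))
  expect_true(seg$segmented)
  expect_identical(seg$meristem_cell_count, 50L)
  expect_equal(seg$meristem_length_um, 500)
  expect_equal(seg$mature_cell_length_um, 150)
})

test_that("the elongation onset is stable under 5% length noise", {
  lens <- sharp_profile()
  sdlog <- sqrt(log(1 + 0.05^2))
  hits <- withr::with_seed(99, {
    vapply(1:1000, function(i) {
      noisy <- lens * exp(rnorm(length(lens), 0, sdlog))
      got <- tryCatch(detect_elongation_onset(noisy), error = function(e) NA_integer_)
      !is.na(got) && abs(got - 51L) <= 1L
    }, logical(1))
  })
  expect_gte(mean(hits), 0.95)
})

test_that("seedling summaries average the two files and flag partial results", {
  left <- sharp_profile(50)
  right <- sharp_profile(48)
  mk <- function(lens, side) {
    tibble::tibble(root_id = "r1", file_side = side,
                   cell_index = seq_along(lens), length_um = lens)
  }
  seg <- segment_cell_file(dplyr::bind_rows(mk(left, "left"), mk(right, "right")))
  out <- summarize_seedling(seg)
  expect_equal(out$meristem_cells, 49) # mean of 50 and 48
  expect_false(out$partial)

  # averaging is idempotent: identical files give the per-file values
  segt <- segment_cell_file(dplyr::bind_rows(mk(left, "left"), mk(left, "right")))
  outt <- summarize_seedling(segt)
  expect_equal(outt$meristem_cells, 50)
  expect_equal(outt$mature_cell_length_um, 150)

  # one failed file: the other's values are used and the row is flagged
  segb <- segment_cell_file(dplyr::bind_rows(
    mk(left, "left"),
    tibble::tibble(root_id = "r1", file_side = "right",
                   cell_index = 1:20, length_um = rep(10, 20))
  ))
  outb <- summarize_seedling(segb)
  expect_true(outb$partial)
  expect_identical(outb$n_files_used, 1L)
  expect_equal(outb$meristem_cells, 50)
})

test_that("averaging two seedling files is commutative", {
  counts <- c(30, 34)
  mk <- function(count, side) {
    lens <- sharp_profile(n_meristem = count)
    tibble::tibble(root_id = "r", file_side = side,
                   cell_index = seq_along(lens), length_um = lens)
  }
  ab <- summarize_seedling(segment_cell_file(
    dplyr::bind_rows(mk(30, "left"), mk(34, "right"))))
  ba <- summarize_seedling(segment_cell_file(
    dplyr::bind_rows(mk(34, "left"), mk(30, "right"))))
  expect_equal(ab$meristem_cells, 32)
  expect_equal(ba$meristem_cells, 32)
  expect_equal(ab$mature_cell_length_um, ba$mature_cell_length_um)
})

test_that("short profiles and missing columns are reported, not crashed on", {
  seg <- segment_cell_file(tibble::tibble(
    root_id = "r", file_side = "single", cell_index = 1:5,
    length_um = c(5, 5, 11, 13, 20)
  ))
  expect_false(seg$segmented)
  expect_match(seg$failure, "fewer than 8")
  expect_error(segment_cell_file(tibble::tibble(root_id = "r")),
               class = "rootkin_error_schema")
})
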