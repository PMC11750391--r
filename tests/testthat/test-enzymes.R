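panels <- load_activity_panels()

test_that("elongation adds C2 at the carboxyl end, shifting all positions +2", {
  expect_equal(fa_to_omega(elongate("18:3n-3")), "20:3n-3")
  expect_equal(fa_positions(elongate("18:3n-3")), c(11L, 14L, 17L))
  expect_equal(fa_to_omega(elongate("16:1n-7")), "18:1n-7")
  expect_equal(fa_to_delta(elongate("18:0")), "20:0")
  expect_error(elongate("24:5n-3"), class = "pufapath_input_error")  # cap
})

test_that("desaturation inserts one bond and rejects invalid positions", {
  expect_equal(fa_to_delta(desaturate("20:1n-9", 5)), "20:2^Δ5,11^")
  expect_equal(fa_to_omega(desaturate("20:2n-6", 8)), "20:3n-6")
  expect_error(desaturate(fatty_acid(20, c(5, 11)), 5),
               class = "pufapath_input_error")   # duplicate
  expect_error(desaturate(fatty_acid(20, c(5, 11)), 10),
               class = "pufapath_input_error")   # cumulated
  expect_error(desaturate("18:0", 19), class = "pufapath_input_error")
})

test_that("operators preserve/increase unsaturation structure as expected", {
  set.seed(7)
  for (i in 1:100) {
    fa <- rand_fa(chain = sample(8:20, 1), detectable = FALSE)
    expect_identical(fa_class(elongate(fa, cap = 26)), fa_class(fa))
    d <- setdiff(2:(fa$chain - 1), as.vector(outer(fa$db, -1:1, `+`)))
    if (length(d)) {
      d <- pick1(d)
      expect_length(fa_positions(desaturate(fa, d)), length(fa$db) + 1L)
      # elongation commutes with desaturation shifted by +2
      expect_equal(elongate(desaturate(fa, d), cap = 26),
                   desaturate(elongate(fa, cap = 26), d + 2))
    }
  }
})

test_that("the packaged panels load with the published composition", {
  expect_equal(length(unique(panels$enzyme)), 16L)
  kinds <- dplyr::distinct(panels, enzyme, kind)
  expect_equal(sum(kinds$kind == "elongase"), 13L)
  expect_equal(sum(kinds$kind == "desaturase"), 3L)
  expect_equal(sum(grepl("^Elovl6-like", kinds$enzyme)), 8L)
})

test_that("specific published records are present with their conversions", {
  row <- dplyr::filter(panels, enzyme == "FadsC2", substrate == "20:2n-6",
                       product == "20:3n-6")
  expect_equal(row$conversion, 40.5)
  expect_equal(row$activity_label, "Δ8")
  row <- dplyr::filter(panels, enzyme == "Elovl1/7-like",
                       substrate == "22:5n-3")
  expect_equal(row$conversion, 14.7)
  row <- dplyr::filter(panels, enzyme == "Elovl6-like A",
                       substrate == "22:4n-6")
  expect_equal(row$status, "not_detected")
  expect_true(is.na(row$conversion))
  # qualitative chromatogram-only records participate without a percentage
  qual <- dplyr::filter(panels, status == "qualitative")
  expect_setequal(qual$substrate, c("16:1n-7", "18:1n-7", "18:1n-9", "18:0"))
})

test_that("every fixture row equals its operator applied to its substrate", {
  for (i in seq_len(nrow(panels))) {
    sub <- fa_parse(panels$substrate[i])
    expected <- if (panels$kind[i] == "elongase") {
      elongate(sub)
    } else {
      desaturate(sub, as.integer(sub("Δ", "", panels$activity_label[i])))
    }
    expect_identical(fa_to_delta(expected), panels$product_delta[i])
  }
})

test_that("a structurally inconsistent panel is refused on load", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  bad <- data.frame(enzyme = "X", kind = "elongase", substrate = "18:2n-6",
                    product = "20:3n-6", conversion = "10",
                    activity_label = "C18->C20")
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(load_activity_panels(tmp), class = "pufapath_panel_error")
})
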