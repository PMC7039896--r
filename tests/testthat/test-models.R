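# frozen hand-evaluated oracle values (computed from the formulas by hand
# before the implementation): see each expectation's comment
test_that("logarithmic-spiral length-at-angle matches hand evaluation and is monotone", {
  # zero angle: ln(1) = 0
  expect_identical(cdl_escude(A = 9.0, theta_deg = 0), 0)
  # 2.62 * (9 - 1) * ln(1 + 360/235)
  expect_equal(cdl_escude(A = 9.0, theta_deg = 360),
               2.62 * 8.0 * log(1 + 360 / 235), tolerance = 1e-12)
  # strictly increasing in angle and in diameter
  theta <- seq(0, 900, by = 30)
  expect_true(all(diff(cdl_escude(9.0, theta)) > 0))
  expect_true(all(cdl_escude(seq(7.5, 11, 0.5), 360) ==
                    cummax(cdl_escude(seq(7.5, 11, 0.5), 360))))
  expect_gt(cdl_escude(9.4, 360), cdl_escude(9.2, 360))
})

test_that("a smaller lateral-wall offset lengthens the modelled duct", {
  # the 0.35 mm sensitivity variant vs the 0.5 mm default
  expect_gt(cdl_escude(9.0, 400, offset = 0.35), cdl_escude(9.0, 400, offset = 0.5))
  p35 <- cochlear_params(escude_offset = 0.35)
  expect_equal(cdl_escude(9.0, 400, params = p35),
               cdl_escude(9.0, 400, offset = 0.35))
})

test_that("non-positive effective diameter is a domain error naming the inputs", {
  expect_error(cdl_escude(A = 0.9, theta_deg = 100), "A = 0.9.*offset = 0.5")
  expect_error(angle_escude(A = 1.0, length_mm = 5), "offset")
})

test_that("logarithmic-spiral inversion is a closed-form exact roundtrip", {
  expect_identical(angle_escude(9.0, 0), 0)
  for (theta in c(90, 360, 630)) {
    expect_equal(angle_escude(9.0, cdl_escude(9.0, theta)), theta,
                 tolerance = 1e-12)
  }
  # the derived forward value maps back to 360 degrees
  expect_equal(angle_escude(9.0, 2.62 * 8.0 * log(1 + 360 / 235)), 360,
               tolerance = 1e-9)
  # an electrode longer than the duct at the angular limit is out of range
  expect_error(angle_escude(7.0, 26.8), "beyond the modelled duct")
})

test_that("ECA basal turn length matches hand evaluation and grows with A and B", {
  # all offset-corrected terms vanish at A = B = 0.7 with offset 0.35
  expect_equal(suppressWarnings(btl_eca(0.7, 0.7)), 0, tolerance = 1e-12)
  expect_equal(btl_eca(9.2, 6.8),
               1.18 * 8.5 + 2.69 * 6.1 - sqrt(0.72 * 8.5 * 6.1),
               tolerance = 1e-12)
  # numerically positive partial derivatives over the anatomical box
  grid <- expand.grid(A = seq(7, 11, 0.5), B = seq(5, 8, 0.5))
  h <- 1e-4
  # the box includes A <= B corners, which warn by design; silence them here
  dA <- suppressWarnings(btl_eca(grid$A + h, grid$B) - btl_eca(grid$A, grid$B))
  dB <- suppressWarnings(btl_eca(grid$A, grid$B + h) - btl_eca(grid$A, grid$B))
  expect_true(all(dA > 0))
  expect_true(all(dB > 0))
  expect_gt(btl_eca(9.4, 6.8), btl_eca(9.2, 6.8))
})

test_that("basal-turn-length percentage cubic has the stated intercept and is strictly increasing", {
  expect_identical(pbtl(0), 3.7)
  expect_equal(pbtl(360),
               8.3e-8 * 360^3 - 2.4e-4 * 360^2 + 0.34 * 360 + 3.7,
               tolerance = 1e-12)
  expect_true(all(diff(pbtl(0:900)) > 0))
  expect_error(pbtl(-1), "\\[0, 900\\]")
  expect_error(pbtl(901), "\\[0, 900\\]")
})

test_that("ECA length-at-angle is the percentage of the basal turn length", {
  expect_equal(cdl_eca(9.2, 6.8, 360),
               0.01 * pbtl(360) * btl_eca(9.2, 6.8), tolerance = 1e-12)
  theta <- seq(0, 900, by = 45)
  expect_true(all(diff(cdl_eca(9.2, 6.8, theta)) > 0))
})

test_that("ECA inversion roundtrips and refuses lengths outside the model's domain", {
  for (theta in c(45, 360, 700)) {
    expect_equal(angle_eca(9.2, 6.8, cdl_eca(9.2, 6.8, theta)), theta,
                 tolerance = 1e-6)
  }
  # the percentage intercept means depth 0 has no angle: documented error,
  # not a silent clip to zero
  expect_error(angle_eca(9.2, 6.8, 0), "intercept")
  expect_error(angle_eca(9.2, 6.8, 50), "exceeds the modelled duct")
  # the solver reproduces the requested length far inside the tolerance
  th <- angle_eca(9.2, 6.8, 26.8)
  expect_lt(abs(cdl_eca(9.2, 6.8, th) - 26.8), 1e-6)
})

test_that("ECA inversion agrees with the dense-table interpolation oracle", {
  for (geom in list(c(8.6, 6.2), c(9.2, 6.8), c(10.0, 7.3))) {
    for (L in c(15, 20, 26.8, 30)) {
      expect_equal(angle_eca(geom[1], geom[2], L),
                   invert_eca_table_oracle(geom[1], geom[2], L),
                   tolerance = 0.01)
    }
  }
})

test_that("percentage table has one unrounded row per degree and is increasing", {
  tab <- pbtl_table()
  expect_identical(nrow(tab), 900L)
  expect_identical(tab$theta_deg, 1:900)
  expect_equal(tab$pbtl_percent[1], pbtl(1), tolerance = 1e-15)
  expect_equal(tab$pbtl_percent, pbtl(1:900), tolerance = 1e-15)
  expect_true(all(diff(tab$pbtl_percent) > 0))

  f <- withr::local_tempfile(fileext = ".csv")
  pbtl_table(file = f)
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(back$pbtl_percent, tab$pbtl_percent, tolerance = 1e-12)
})
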