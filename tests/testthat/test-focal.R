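test_that("circular windows enumerate the documented offset counts", {
  expect_equal(nrow(circular_window(0)), 1L)
  expect_equal(nrow(circular_window(1, 1)), 5L)   # von Neumann cross
  # brute-force oracle: integer offsets with euclidean distance <= r
  brute <- function(r_km, cell_km) {
    r <- ceiling(r_km / cell_km)
    sum(outer(-r:r, -r:r, function(a, b)
      sqrt(a^2 + b^2) * cell_km <= r_km + 1e-9))
  }
  for (r_km in c(2, 5, 7.5)) {
    expect_equal(nrow(circular_window(r_km, 1)), brute(r_km, 1))
  }
  expect_equal(nrow(circular_window(5, 1)), 81L)
  expect_error(circular_window(-1), ">= 0")
})

make_stack <- function(..., cell_km = 1, kinds = "continuous") {
  env_stack(list(...), cell_km = cell_km, layer_kinds = kinds)
}

test_that("focal_fraction averages with edge and nodata truncation", {
  u <- matrix(0.37, 15, 15)
  st <- make_stack(u = u, kinds = "fraction")
  expect_equal(focal_fraction(st, "u", 5), u)

  z <- matrix(0, 15, 15); z[8, 8] <- 1
  st <- make_stack(z = z, kinds = "fraction")
  expect_equal(focal_fraction(st, "z", 5)[8, 8], 1 / 81)

  # all-nodata window except the center
  v <- matrix(NA_real_, 7, 7); v[4, 4] <- 0.6
  st2 <- env_stack(list(v = v), layer_kinds = "fraction",
                   nodata_mask = is.na(v))
  expect_equal(focal_fraction(st2, "v", 2)[4, 4], 0.6)
  expect_error(focal_fraction(st2, "nope", 2), "unknown layer")
})

test_that("focal_fraction preserves the layer's bounds", {
  withr::with_seed(2, {
    f <- matrix(runif(400), 20, 20)
  })
  st <- make_stack(f = f, kinds = "fraction")
  out <- focal_fraction(st, "f", 3)
  expect_true(all(out >= min(f) - 1e-12 & out <= max(f) + 1e-12))
})

test_that("focal_density divides window length by window area", {
  zero <- matrix(0, 12, 12)
  st <- make_stack(d = zero, kinds = "density_length")
  expect_true(all(focal_density(st, "d", 5) == 0))

  one <- matrix(0, 12, 12); one[6, 6] <- 2
  st <- make_stack(d = one, kinds = "density_length", cell_km = 2)
  expect_equal(focal_density(st, "d", 0)[6, 6], 2 / 4)  # 2 km per 4 km^2

  allones <- matrix(1, 25, 25)
  st <- make_stack(d = allones, kinds = "density_length")
  expect_equal(focal_density(st, "d", 5)[13, 13], 1)    # 81/81
  st_frac <- make_stack(d = allones)
  expect_error(focal_density(st_frac, "d", 5), "density_length")
})

test_that("slope and aspect match analytic planes", {
  n <- 12
  flat <- matrix(3, n, n)
  expect_equal(slope_deg(flat)[2:(n - 1), 2:(n - 1)],
               matrix(0, n - 2, n - 2))
  # z rises eastward at tan(10 deg) per km -> slope 10 deg, downslope west
  east_up <- matrix(rep((0:(n - 1)) * tanpi(10 / 180), each = n), n, n)
  s <- slope_deg(east_up)
  expect_equal(s[2:(n - 1), 2:(n - 1)],
               matrix(10, n - 2, n - 2), tolerance = 1e-6)
  expect_equal(aspect_deg(east_up)[2:(n - 1), 2:(n - 1)],
               matrix(270, n - 2, n - 2), tolerance = 1e-6)
  # dipping due east (z falls eastward) -> aspect 90
  expect_equal(aspect_deg(-east_up)[2:(n - 1), 2:(n - 1)],
               matrix(90, n - 2, n - 2), tolerance = 1e-6)
  expect_true(all(is.na(aspect_deg(flat)[2:(n - 1), 2:(n - 1)])))
  expect_error(slope_deg(matrix(0, 2, 2)), "3 x 3")
})

test_that("vrm is 0 for parallel normals and matches direct summation", {
  flat_s <- matrix(0, 9, 9)
  flat_a <- matrix(NA_real_, 9, 9)
  out <- vrm(flat_s, flat_a, 3)
  expect_equal(out, matrix(0, 9, 9))

  tilt_s <- matrix(30, 9, 9); tilt_a <- matrix(45, 9, 9)
  expect_equal(vrm(tilt_s, tilt_a, 3), matrix(0, 9, 9), tolerance = 1e-12)

  # 3x3 window: 4 cells aspect 0, 5 cells aspect 180, slope 90
  s <- matrix(90, 3, 3)
  a <- matrix(c(0, 0, 0, 0, 180, 180, 180, 180, 180), 3, 3)
  normals_y <- sin(pi / 2) * cos(a * pi / 180)
  expected <- 1 - abs(sum(normals_y)) / 9   # x and z components are 0
  expect_equal(vrm(s, a, 3)[2, 2], expected, tolerance = 1e-12)
  expect_error(vrm(s, a[1:2, 1:2], 3), "shape")
  expect_error(vrm(s, a, 4), "odd")
})

test_that("extract_table point-samples, drops nodata rows, flags bad rows", {
  w <- small_world()
  tab <- w$tab
  idx <- cbind(w$occ$row + 1, w$occ$col + 1)
  expect_equal(tab$var03, w$stack$layers$var03[idx])

  # an occurrence on a nodata cell is dropped with a count of 1
  occ_bad <- dplyr::bind_rows(
    w$occ[1, ],
    dplyr::mutate(w$occ[2, ], row = 0L, col = 0L))  # grid corner: nodata
  expect_message(out <- extract_table(w$stack, occ_bad), "1 occurrence")
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "n_dropped"), 1)

  occ_out <- dplyr::mutate(w$occ[1, ], row = 999L)
  expect_error(extract_table(w$stack, occ_out), "outside the grid")
})

test_that("focal summaries flow into the variable table via the spec", {
  w <- small_world()
  spec <- extraction_spec(layer = c("var01", "var02"),
                          summary = c("point", "fraction"),
                          radius_km = c(0, 2),
                          variable = c("v_point", "v_smooth"))
  tab <- extract_table(w$stack, w$occ[1:10, ], spec)
  expect_named(tab, c(names(w$occ), "v_point", "v_smooth"))
  sm <- focal_fraction(w$stack, "var02", 2)
  expect_equal(tab$v_smooth, sm[cbind(tab$row + 1, tab$col + 1)])
})
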