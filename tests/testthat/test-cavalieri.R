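test_that("systematic section sampling hits the target range", {
  s <- sample_sections_systematic(40, k = 4, seed = 1)
  expect_length(s$indices, 10)
  expect_true(all(diff(s$indices) == 4))

  s <- sample_sections_systematic(40, c(8, 12), seed = 2)
  expect_true(length(s$indices) >= 8 && length(s$indices) <= 12)

  expect_warning(s <- sample_sections_systematic(5, c(8, 12)), "sampling all")
  expect_identical(s$indices, 1:5)
  expect_identical(s$k, 1L)
})

test_that("the systematic start is uniform over the period", {
  starts <- vapply(1:1000, function(i) {
    sample_sections_systematic(40, k = 4, seed = i)$start
  }, integer(1))
  freq <- tabulate(starts + 1L, nbins = 4) / 1000
  expect_true(all(abs(freq - 0.25) < 0.04))
})

test_that("point counting is exact for aligned squares and unbiased for discs", {
  # 100x100 square, spacing 10: exactly 100 hits for any offset
  sq <- region_polygon(c(0, 100, 100, 0), c(0, 0, 100, 100))
  for (seed in 1:20) {
    pc <- point_count_area(sq, point_grid(10, seed = seed))
    expect_identical(pc$point_count, 100L)
    expect_identical(pc$area, 10000)
  }
  # definition: A = P * a(p)
  pc <- point_count_area(region_ellipse(c(0, 0), c(30, 20)), point_grid(10, seed = 1))
  expect_identical(pc$area, pc$point_count * 100)

  # disc radius 50, spacing 5: Monte-Carlo mean within 1% of pi * 50^2
  disc <- region_ellipse(c(0, 0), c(50, 50))
  areas <- vapply(1:500, function(s) {
    point_count_area(disc, point_grid(5, seed = s))$area
  }, numeric(1))
  expect_equal(mean(areas), pi * 50^2, tolerance = 0.01)

  # empty region
  expect_identical(
    point_count_area(region_ellipse(c(0, 0), c(0, 0)), point_grid(10, seed = 1))$point_count,
    0L
  )
})

test_that("halving the grid spacing does not increase the area-estimate spread", {
  disc <- region_ellipse(c(0, 0), c(50, 50))
  spread <- function(spacing) {
    sd(vapply(1:300, function(s) {
      point_count_area(disc, point_grid(spacing, seed = s))$area
    }, numeric(1)))
  }
  expect_lte(spread(5), spread(10))
})

test_that("the Cavalieri product-sum is exact", {
  est <- cavalieri_volume(tibble::tibble(area = c(1.0, 1.2, 0.8) * 1e6), d = 300)
  expect_identical(est$volume, 9.0e8)
  expect_identical(
    cavalieri_volume(tibble::tibble(area = rep(0, 5)), d = 100)$volume, 0)
  expect_error(cavalieri_volume(tibble::tibble(area = numeric(0)), d = 100),
               "non-empty")
  expect_error(cavalieri_volume(tibble::tibble(area = 1), d = 0), "d")
})

test_that("the SURS variance term matches a brute-force oracle", {
  P <- c(10, 12, 11, 13, 12, 11, 12, 13, 11, 12)
  expect_equal(
    gundersen_ce_volume(P, nugget = FALSE),
    sqrt(surs_var_oracle(P)) / sum(P)
  )
  # with the nugget, against the same oracle
  ratio <- 3.6
  nu <- 0.0724 * ratio * sqrt(length(P) * sum(P))
  expect_equal(
    gundersen_ce_volume(P, shape_ratio = ratio, nugget = TRUE),
    sqrt(max(0, surs_var_oracle(P, nu)) + nu) / sum(P)
  )
  # constant sequences: systematic component nearly vanishes
  expect_lt(gundersen_ce_volume(rep(7, 10), nugget = FALSE), 0.01)
  expect_error(gundersen_ce_volume(c(1, 2)), "at least 3")
})

test_that("the full Cavalieri pipeline recovers ellipsoid volume within 2%", {
  st <- geometry_stack(seed = 11)
  truth <- 4 / 3 * pi * prod(st$semi_axes)
  vols <- vapply(1:200, function(s) {
    estimate_volume(st, seed = s)$volume
  }, numeric(1))
  expect_equal(mean(vols), truth, tolerance = 0.02)
  est <- estimate_volume(st, seed = 3)
  expect_true(est$n_sections >= 8 && est$n_sections <= 12)
  expect_identical(est$volume, est$sum_area * est$d)
  expect_identical(est$d, est$k * st$BA)
})
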