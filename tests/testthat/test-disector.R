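test_that("the Z-axis histogram bins focal depths correctly", {
  h <- zaxis_histogram(data.frame(z = seq(0.1, 22.9, length.out = 1000), t = 23))
  expect_equal(sum(h$percent), 100, tolerance = 1e-8)
  expect_true(all(abs(h$percent - 10) < 2))

  h0 <- zaxis_histogram(data.frame(z = rep(0, 50), t = 23))
  expect_identical(h0$percent, c(100, rep(0, 9)))

  # lost-caps depletion: no nuclei in the top 10% -> empty first bin
  z <- runif(500, 0.1 * 23, 23 - 1e-9)
  hd <- zaxis_histogram(data.frame(z = z, t = 23))
  expect_identical(hd$percent[1], 0)

  expect_error(zaxis_histogram(data.frame(z = numeric(0), t = numeric(0))),
               "no nuclei")
  expect_error(zaxis_histogram(data.frame(z = 30, t = 23)), "0 <= z <= t")
})

test_that("counting-window selection follows the guard arithmetic", {
  w <- select_counting_window(guard_top = 0.1, guard_bottom = 0.2, t_bar = 23)
  expect_equal(w$h, 16.1)
  expect_equal(w$included_fraction, 70)

  w0 <- select_counting_window(guard_top = 0, guard_bottom = 0, t_bar = 23)
  expect_identical(w0$h, 23)
  expect_equal(w0$included_fraction, 100)

  # mid-section concentration raises the included fraction above the
  # uniform-depth value, as empirical Z-axis histograms do
  conc <- zaxis_histogram(data.frame(z = rnorm(2000, 11.5, 3), t = 23))
  wc <- select_counting_window(conc, 0.1, 0.2, 23)
  expect_gt(wc$included_fraction, 70)

  expect_error(select_counting_window(guard_top = 0.6, guard_bottom = 0.5,
                                      t_bar = 23), "guard")
})

test_that("the Nv and total-number formulas reproduce hand-computed values", {
  cfg <- disector_config("neuron")
  nv <- estimate_nv(list(sum_Q = 100, sum_P = 200, t_bar = 23), cfg,
                    window = list(h = 15))
  expect_equal(nv, 100 / (200 * 3492 * 15) * (23 / 25), tolerance = 1e-12)
  expect_equal(nv, 8.782e-6, tolerance = 1e-4)

  n <- estimate_total_number(nv, 3.0e7)
  expect_equal(n$n_total, nv * 3.0e7, tolerance = 1e-12)
  expect_equal(n$n_total, 263.5, tolerance = 1e-3)

  # linearity: doubling SumP halves Nv; zero counts give zero density
  nv2 <- estimate_nv(list(sum_Q = 100, sum_P = 400, t_bar = 23), cfg,
                     window = list(h = 15))
  expect_equal(nv2, nv / 2, tolerance = 1e-12)
  expect_identical(
    estimate_nv(list(sum_Q = 0, sum_P = 200, t_bar = 23), cfg,
                window = list(h = 15)), 0)

  # t_bar = BA reduces to the uncorrected disector formula exactly
  nv3 <- estimate_nv(list(sum_Q = 100, sum_P = 200, t_bar = 25), cfg,
                     window = list(h = 15))
  expect_identical(nv3, 100 / (200 * 3492 * 15))

  expect_identical(estimate_total_number(nv, 0)$n_total, 0)
  expect_error(estimate_nv(list(sum_Q = 1, sum_P = 0, t_bar = 23), cfg,
                           window = list(h = 15)), "sum_P")
})

test_that("the number CE combines Poisson and SURS terms correctly", {
  # constant per-section counts: the Poisson term dominates
  expect_equal(ce_number(list(sum_Q = 400), per_section_Q = rep(40, 10)),
               1 / sqrt(400), tolerance = 0.02)
  ce500 <- ce_number(list(sum_Q = 500), per_section_Q = rep(50, 10))
  expect_equal(ce500, sqrt(1 / 500 + surs_var_oracle(rep(50, 10)) / 500^2))
  expect_true(ce500 >= 0.04 && ce500 <= 0.05)
  # SURS term against the brute-force oracle
  Q <- c(40, 42, 41, 39, 40, 41, 40, 39, 41, 40)
  expect_equal(
    ce_number(list(sum_Q = sum(Q)), per_section_Q = Q),
    sqrt(1 / sum(Q) + surs_var_oracle(Q) / sum(Q)^2)
  )
  expect_error(ce_number(list(sum_Q = 0), per_section_Q = c(0, 0, 0)), "sum_Q")
})

test_that("the counting-frame rule counts interior nuclei once and respects the window", {
  # single nucleus centred in the tissue, full-depth window -> exactly 1
  st <- manual_stack(manual_profiles(x = 0, y = 0, z_depth = 11))
  cfg <- disector_config("neuron", step_x = sqrt(3492), step_y = sqrt(3492),
                         guard_top = 0, guard_bottom = 0)
  tal <- optical_disector_tally(st, cfg, seed = 1)
  expect_identical(tal$sum_Q, 1L)
  expect_gt(tal$sum_P, 0)

  # a nucleus in the guard zone is not counted
  st2 <- manual_stack(manual_profiles(x = c(0, 30), y = c(0, 30),
                                      z_depth = c(11, 1)))
  cfg2 <- disector_config("neuron", step_x = sqrt(3492), step_y = sqrt(3492),
                          guard_top = 0.1, guard_bottom = 0.2)
  tal2 <- optical_disector_tally(st2, cfg2, seed = 1)
  expect_identical(tal2$sum_Q, 1L)

  # empty stack: zero counts but fields still placed
  st3 <- manual_stack(manual_profiles(x = numeric(0), y = numeric(0),
                                      z_depth = numeric(0)))
  tal3 <- optical_disector_tally(st3, cfg, seed = 1)
  expect_identical(tal3$sum_Q, 0L)
  expect_gt(tal3$sum_P, 0)
})

test_that("exhaustive tiling counts every in-window nucleus exactly once", {
  for (seed in 1:5) {
    cfg <- small_config(n_neurons = 600, glia = 0, seed = seed)
    st <- section_phantom(generate_phantom(cfg, "control"), seed = seed + 50)
    dcfg <- disector_config("neuron", step_x = sqrt(3492), step_y = sqrt(3492),
                            guard_top = 0, guard_bottom = 0)
    tal <- optical_disector_tally(st, dcfg, seed = seed + 99)
    expect_identical(tal$sum_Q, nrow(st$profiles))
  }
})

test_that("a cell's sampling probability under sparse frames is a/f per step area", {
  # measure-theoretic property of the unbiased frame: over random grid
  # phases, any profile is counted with probability (a/f) / (step_x * step_y)
  st <- manual_stack(manual_profiles(x = 37.3, y = -12.9, z_depth = 11,
                                     radius = 6),
                     ellipse_a = 300, ellipse_b = 300)
  cfg <- disector_config("neuron", step_x = 150, step_y = 150,
                         guard_top = 0, guard_bottom = 0)
  hits <- vapply(1:2000, function(s) {
    optical_disector_tally(st, cfg, seed = s)$sum_Q
  }, integer(1))
  p_hat <- mean(hits)
  p_true <- 3492 / (150 * 150)
  expect_equal(p_hat, p_true, tolerance = 0.12)
})
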