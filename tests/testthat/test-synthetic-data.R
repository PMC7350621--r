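test_that("phantom generation is deterministic and honours empty populations", {
  cfg <- small_config(n_neurons = 1000)
  a <- generate_phantom(cfg, "control", 1)
  b <- generate_phantom(cfg, "control", 1)
  expect_identical(a$cells, b$cells)
  expect_false(identical(
    a$cells, generate_phantom(cfg, "control", 2)$cells
  ))

  empty <- generate_phantom(small_config(n_neurons = 0, glia = 2), "control")
  expect_identical(nrow(empty$cells), 0L)
  expect_equal(empty$true_volume, 4 / 3 * pi * prod(empty$semi_axes))

  expect_error(generate_phantom(cfg, "no_such_group"), "unknown group")
})

test_that("phantom truth fields are internally consistent", {
  cfg <- small_config(n_neurons = 1500, glia = 2)
  ph <- generate_phantom(cfg, "control")
  expect_equal(
    ph$true_counts$n,
    as.integer(table(ph$cells$cell_class)[ph$true_counts$cell_class])
  )
  # all cells inside the ellipsoid
  s <- ph$semi_axes
  expect_true(all((ph$cells$x / s[1])^2 + (ph$cells$y / s[2])^2 +
                    (ph$cells$z / s[3])^2 <= 1 + 1e-9))
  # realised counts within Poisson noise of the target (5 sigma)
  expect_lt(abs(sum(ph$cells$cell_class == "neuron") - 1500), 5 * sqrt(1500))
  expect_lt(abs(sum(ph$cells$cell_class == "satellite_glia") - 3000), 5 * sqrt(3000))
})

test_that("sectioning yields ceil(extent/BA) sections and realistic thickness", {
  # sphere of radius 100 um at BA = 25 -> 8 sections
  cfg <- study_config(groups = "g", ellipsoid_semi_axes = c(100, 100, 100),
                      neuron_count_true = 200, glia_per_neuron_mean = 0,
                      pattern = c(g = "random"), apoptosis_prob = c(g = 0),
                      effect_multipliers = list(g = c(volume = 1, neuron = 1, glia = 1)))
  st <- section_phantom(generate_phantom(cfg, "g"), BA = 25, seed = 1)
  expect_identical(st$n_sections, 8L)

  # shrinkage 0.92 at BA 25 -> mean measured thickness ~23 um
  big <- section_phantom(generate_phantom(small_config(), "control"), BA = 25,
                         shrinkage_factor = 0.92, seed = 2)
  expect_equal(mean(big$sections$t), 23, tolerance = 0.02)
  expect_true(all(big$sections$t <= 25))
  expect_true(all(big$profiles$z_depth >= 0 &
                    big$profiles$z_depth <= big$sections$t[big$profiles$section]))
})

test_that("sectioning conserves every cell exactly once, for several seeds", {
  for (s in 1:4) {
    cfg <- small_config(n_neurons = 800, glia = 1.5, seed = s)
    ph <- generate_phantom(cfg, "control")
    st <- section_phantom(ph, seed = s + 100)
    expect_identical(nrow(st$profiles), nrow(ph$cells))
    expect_identical(sort(st$profiles$cell_id), sort(ph$cells$cell_id))
    tal <- table(st$profiles$cell_class)
    tru <- table(ph$cells$cell_class)
    expect_identical(as.integer(tal[names(tru)]), as.integer(tru))
  }
})

test_that("empty phantoms section with a warning and an empty profile table", {
  ph <- generate_phantom(small_config(n_neurons = 0), "control")
  expect_warning(st <- section_phantom(ph), "empty phantom")
  expect_identical(nrow(st$profiles), 0L)
  expect_gt(st$n_sections, 0)
})

test_that("extract_section_points filters by class and stays inside the window", {
  cfg <- small_config(n_neurons = 1200, glia = 2)
  st <- section_phantom(generate_phantom(cfg, "control"), seed = 5)
  mid <- which.min(abs(st$sections$z_mid))
  pp <- extract_section_points(st, mid, "neuron")
  expect_identical(
    n_points(pp),
    sum(st$profiles$section == mid & st$profiles$cell_class == "neuron")
  )
  w <- pp$window
  expect_true(all(pp$points$x >= w[1] & pp$points$x <= w[2] &
                    pp$points$y >= w[3] & pp$points$y <= w[4]))
  gl <- extract_section_points(st, mid, "satellite_glia")
  expect_identical(
    n_points(gl),
    sum(st$profiles$section == mid & st$profiles$cell_class == "satellite_glia")
  )
  expect_error(extract_section_points(st, st$n_sections + 1), "out of range")
})

test_that("Poisson phantoms are CSR-dispersed and Thomas phantoms clustered", {
  vmr_pois <- vapply(1:20, function(s) {
    quadrat_vmr(generate_phantom(small_config(10000, glia = 0, "random", seed = s),
                                 "control"))
  }, numeric(1))
  expect_gte(mean(vmr_pois >= 0.8 & vmr_pois <= 1.2), 0.9)

  vmr_thomas <- vapply(1:5, function(s) {
    quadrat_vmr(generate_phantom(small_config(10000, glia = 0, "clustered", seed = s),
                                 "control"))
  }, numeric(1))
  expect_true(all(vmr_thomas > 1.5))
})

test_that("regular phantoms project to regular planar patterns", {
  # densest ~10-um focal slab of a central section, interior rectangle
  cvs <- vapply(1:25, function(s) {
    cfg <- small_config(10000, glia = 0, pattern = "regular", seed = s)
    st <- section_phantom(generate_phantom(cfg, "control"), seed = s + 300)
    mid <- which.min(abs(st$sections$z_mid))
    pat <- section_focus_pattern(st, mid, "neuron")
    ea <- st$sections$ellipse_a[mid] / sqrt(2)
    eb <- st$sections$ellipse_b[mid] / sqrt(2)
    voronoi_summary(crop_pattern(pat, c(-ea, ea, -eb, eb)))$cv
  }, numeric(1))
  expect_gte(mean(cvs < 33), 0.95)
})
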