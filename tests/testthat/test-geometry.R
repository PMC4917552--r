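test_that("default tissue thicknesses give the canonical boundary radii", {
  geom <- build_geometry(geometry_config(n_axial = 10))
  expect_equal(geom$layer_radii, c(3, 8, 18, 38, 53))
  expect_equal(unname(geom$r_out["epidermis"]), 53)
  expect_equal(unname(geom$r_in["xylem"]), 0)
  expect_true(all(diff(geom$layer_radii) > 0))
})

test_that("compartment volumes follow the annulus formula (solid-cylinder case)", {
  geom <- build_geometry(geometry_config(n_axial = 3, ez_end = 1,
                                         h_min = 10, h_max = 10))
  # xylem is a solid cylinder: V = pi r^2 h
  expect_equal(unname(geom$volumes["xylem", 1]),
               pi * (3e-6)^2 * 10e-6, tolerance = 1e-12)
  # independent loop oracle for every compartment
  for (l in 1:5) {
    r_out <- geom$r_out[l] * 1e-6; r_in <- geom$r_in[l] * 1e-6
    for (j in 1:3) {
      expect_equal(geom$volumes[l, j],
                   pi * (r_out^2 - r_in^2) * geom$cell_heights[j] * 1e-6,
                   tolerance = 1e-12)
    }
  }
})

test_that("EZ height ramp and root length match a running-sum oracle", {
  geom <- build_geometry() # n_axial = 100, 20 -> 150 um over cells 1..11
  h <- geom$cell_heights
  expect_equal(h[1], 20)
  expect_equal(h[11], 150)
  expect_equal(h[6], 85) # midpoint of the linear ramp
  expect_true(all(diff(h[1:11]) > 0))
  expect_true(all(h[12:100] == 150))
  # independent running sum
  total <- 0
  for (j in seq_along(h)) total <- total + h[j] * 1e-6
  expect_equal(geom$root_length, total, tolerance = 1e-12)
  expect_equal(sum(geom$cell_heights) * 1e-6, geom$root_length)
})

test_that("doubling cell heights doubles length, volumes and lateral areas", {
  g1 <- build_geometry(geometry_config(n_axial = 12, h_min = 20, h_max = 100,
                                       ez_end = 4))
  g2 <- build_geometry(geometry_config(n_axial = 12,
                                       cell_heights = 2 * g1$cell_heights))
  expect_equal(g2$root_length, 2 * g1$root_length)
  expect_equal(g2$volumes, 2 * g1$volumes)
  expect_equal(g2$radial_areas, 2 * g1$radial_areas)
  expect_equal(g2$axial_areas, g1$axial_areas) # horizontal areas unchanged
})

test_that("geometry configuration errors name the offending field", {
  expect_error(geometry_config(xylem_radius = -1), "xylem_radius")
  expect_error(geometry_config(layer_thicknesses = c(epidermis = 15, cortex = 0,
                                                     endodermis = 10, pericycle = 5)),
               "cortex")
  expect_error(geometry_config(n_axial = 0), "n_axial")
  expect_error(geometry_config(h_min = 200, h_max = 150), "h_min")
})

test_that("zone labels partition the axial cells and ramps interpolate linearly", {
  geom <- build_geometry(geometry_config(n_axial = 40))
  zm <- build_zone_map(geom, cs_start = 12, cs_ramp = 4, sl_start = 38)
  expect_equal(length(zm$zone), 40)
  expect_false(any(is.na(zm$zone)))
  expect_true(all(zm$zone[1:11] == "EZ"))
  expect_true(all(zm$zone[16:40] == "DZ"))
  # stated interpolation points
  expect_equal(zm$w_cs[11], 0)
  expect_equal(zm$w_cs[16], 1)
  expect_equal(zm$w_cs[14], 0.6)
  expect_true(all(zm$w_cs >= 0 & zm$w_cs <= 1))
})

test_that("shifting the xylem start moves only the xylem ramp", {
  geom <- build_geometry(geometry_config(n_axial = 40))
  zm0 <- build_zone_map(geom, xylem_start = 12)
  zm1 <- build_zone_map(geom, xylem_start = 6)
  expect_equal(zm1$w_cs, zm0$w_cs)
  expect_equal(zm1$w_xylem[6 + 4], 1)   # fully functional 6 cells earlier
  expect_equal(zm0$w_xylem[6 + 4], 0)
})

test_that("sl_start beyond the root degenerates to a CS-only layout", {
  geom <- build_geometry(geometry_config(n_axial = 20))
  expect_warning(zm <- build_zone_map(geom, cs_start = 6, sl_start = 50),
                 "sl_start")
  mask <- sample_passage_cells(zm, seed = 1)
  expect_length(mask$j, 0)
  pf_c <- suppressWarnings(
    assign_parameters(geom, zm, barrier_scenario("C"))
  )
  pf_b <- suppressWarnings(
    assign_parameters(geom, zm, barrier_scenario("B"))
  )
  expect_equal(pf_c$radial_sigma, pf_b$radial_sigma)
})

test_that("geometry is a pure function of its configuration", {
  cfg <- geometry_config(n_axial = 15)
  expect_identical(build_geometry(cfg), build_geometry(cfg))
  tab <- geometry_table(build_geometry(cfg))
  expect_equal(nrow(tab), 75)
  expect_true(all(tab$volume_m3 > 0))
})
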