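test_that("scenario A leaves every interface at the membrane baseline", {
  geom <- toy_geometry()
  zm <- toy_zone_map(geom)
  pf <- assign_parameters(geom, zm, barrier_scenario("A"))
  expect_true(all(pf$radial_Lp == 5.5e-14))
  expect_true(all(pf$radial_k == 3e-9))
  expect_true(all(pf$radial_sigma == 0.5))
})

test_that("each barrier divides permeabilities by 10 and adds 0.2 to sigma", {
  geom <- build_geometry(geometry_config(n_axial = 60))
  zm <- build_zone_map(geom) # cs 12+4, sl 38
  pf <- assign_parameters(geom, zm, barrier_scenario("D", seed = 5))
  b <- 4L # endodermis|pericycle
  # fully developed CS, before the SL region
  expect_equal(pf$radial_k[b, 20, 1], 3e-10)
  expect_equal(unname(pf$radial_Lp[b, 20]), 5.5e-15)
  expect_equal(pf$radial_sigma[b, 20, 1], 0.7)
  # CS + SL cell: two orders of magnitude, sigma 0.9
  sl_j <- which(pf$sl_cells)[1]
  expect_equal(pf$radial_k[b, sl_j, 1], 3e-11)
  expect_equal(unname(pf$radial_Lp[b, sl_j]), 5.5e-16)
  expect_equal(pf$radial_sigma[b, sl_j, 1], 0.9)
  # passage cell: exactly the CS-only values
  pj <- pf$mask$j[pf$mask$passage]
  if (length(pj) > 0) {
    expect_equal(pf$radial_k[b, pj[1], 1], 3e-10)
    expect_equal(pf$radial_sigma[b, pj[1], 1], 0.7)
  }
  # other boundaries untouched
  expect_true(all(pf$radial_k[-b, , ] == 3e-9))
})

test_that("CS ramp interpolates permeabilities geometrically, sigma arithmetically", {
  geom <- build_geometry(geometry_config(n_axial = 30))
  zm <- build_zone_map(geom, cs_start = 12, cs_ramp = 4, sl_start = 28)
  pf <- assign_parameters(geom, zm, barrier_scenario("B"))
  w <- zm$w_cs[14] # 0.6
  expect_equal(pf$radial_k[4, 14, 1], 3e-9 / 10^w)
  expect_equal(pf$radial_sigma[4, 14, 1], 0.5 + 0.2 * w)
})

test_that("scenario permeabilities are ordered A >= B >= D >= C and sigma reversed", {
  geom <- build_geometry(geometry_config(n_axial = 60))
  zm <- build_zone_map(geom)
  pfs <- lapply(c(A = "A", B = "B", C = "C", D = "D"), function(s) {
    assign_parameters(geom, zm, barrier_scenario(s, seed = 2))
  })
  ktab <- sapply(pfs, function(p) p$radial_k[4, , 1])
  stab <- sapply(pfs, function(p) p$radial_sigma[4, , 1])
  expect_true(all(ktab[, "A"] >= ktab[, "B"]))
  expect_true(all(ktab[, "B"] >= ktab[, "D"]))
  expect_true(all(ktab[, "D"] >= ktab[, "C"]))
  expect_true(all(stab[, "A"] <= stab[, "B"]))
  expect_true(all(stab[, "B"] <= stab[, "D"]))
  expect_true(all(stab[, "D"] <= stab[, "C"]))
})

test_that("sigma is clamped to [0, 1] under large user increments", {
  geom <- toy_geometry()
  zm <- toy_zone_map(geom)
  pf <- assign_parameters(geom, zm,
                          barrier_scenario("C", sigma_increment = 0.5))
  expect_true(all(pf$radial_sigma <= 1))
  expect_true(all(pf$radial_sigma >= 0))
})

test_that("removing barriers and xylem yields a spatially uniform field", {
  geom <- build_geometry(geometry_config(n_axial = 12))
  zm <- suppressWarnings(build_zone_map(geom, cs_start = 20, xylem_start = 20,
                                        sl_start = 30))
  pf <- assign_parameters(geom, zm, barrier_scenario("A"))
  expect_equal(length(unique(as.vector(pf$radial_Lp))), 1L)
  expect_equal(length(unique(as.vector(pf$axial_Lp))), 1L)
  expect_true(all(pf$w_open == 0))
})

test_that("passage-cell sampling is reproducible and respects the probability law", {
  geom <- build_geometry(geometry_config(n_axial = 45))
  zm <- build_zone_map(geom, sl_start = 38)
  m1 <- sample_passage_cells(zm, seed = 42)
  m2 <- sample_passage_cells(zm, seed = 42)
  expect_identical(m1$passage, m2$passage)
  expect_equal(m1$j, 38:45)
  # the decay -> infinity limit makes every cell a passage cell
  mInf <- sample_passage_cells(zm, seed = 1, passage_decay = 1e12)
  expect_true(all(mInf$passage))
})

test_that("empirical passage frequency at j = 38 matches exp(-38/30)", {
  # Monte-Carlo check of the stated law over 10^4 independent seeds
  geom <- build_geometry(geometry_config(n_axial = 38))
  zm <- build_zone_map(geom, sl_start = 38)
  n_rep <- 10000
  hits <- 0L
  for (s in seq_len(n_rep)) {
    hits <- hits + sample_passage_cells(zm, seed = s)$passage[1]
  }
  p <- exp(-38 / 30)
  se <- sqrt(p * (1 - p) / n_rep)
  expect_lt(abs(hits / n_rep - p), 3 * se)
})

test_that("sampling leaves the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(sample_passage_cells(toy_zone_map(toy_geometry()), seed = 7))
  expect_identical(.Random.seed, before)
})

test_that("scenario validation rejects malformed settings", {
  expect_error(barrier_scenario("E"), "arg")
  expect_error(barrier_scenario("B", cs_factor = 1), "cs_factor")
  expect_error(barrier_scenario("B", sigma_increment = 0.6), "sigma_increment")
  geom <- toy_geometry()
  expect_error(build_zone_map(geom, cs_ramp = -1), "ramp")
  expect_error(build_zone_map(geom, sl_start = 3, cs_start = 6), "sl_start")
})
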