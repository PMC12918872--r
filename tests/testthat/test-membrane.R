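test_that("leaflet assignment splits at the midplane with ties going upper", {
  fx <- build_fixture("bilayer", seed = 1, nx = 4, ny = 2, n_frames = 1)
  lf <- assign_leaflets(fx$frames[[1]], "name P", fx$atoms)
  expect_identical(sum(lf$leaflet == "upper"), 8L)
  expect_identical(sum(lf$leaflet == "lower"), 8L)
  ## construction labels: first 8 lipids were built in the upper leaflet
  expect_true(all(lf$leaflet[lf$z > 0] == "upper"))

  ## all heads at the same z: tie at midplane is assigned upper
  at <- atom_table(data.frame(name = "P", resname = "LIP", resid = 1:4,
                              segid = "MEMB", element = "P"))
  fr <- new_frame(cbind(1:4, 1, 5), box = c(10, 10, 20))
  lf2 <- assign_leaflets(fr, "name P", at)
  expect_true(all(lf2$leaflet == "upper"))
  expect_error(assign_leaflets(fr, "name XX", at), "no atoms")
})

test_that("area per lipid: lattice value, conservation, checkerboard symmetry", {
  fx <- build_fixture("bilayer", seed = 1, nx = 4, ny = 4, n_frames = 2,
                      types = "checkerboard")
  apl <- area_per_lipid(fx$frames, "name P", fx$atoms)
  expect_equal(apl$mean_apl, rep(100, nrow(apl)), tolerance = 1e-9)
  ## per-type APLs equal by symmetry of construction
  expect_equal(apl$mean_apl[apl$type == "LIPA"], apl$mean_apl[apl$type == "LIPB"],
               tolerance = 1e-9)
  ## conservation per leaflet and frame on a randomized configuration
  per <- attr(apl, "per_lipid")
  sums <- tapply(per$apl, paste(per$frame, per$leaflet), sum)
  expect_equal(unname(as.numeric(sums)), rep(1600, 4), tolerance = 1e-6)
})

test_that("S_CD hits the analytic limits exactly", {
  chain <- list(carbons = paste0("C", 2:6),
                hydrogens = lapply(2:6, function(k) paste0("H", k, c("A", "B"))))
  fz <- build_fixture("bilayer", seed = 1, nx = 2, ny = 2, ch_mode = "z")
  sz <- scd_profile(fz$frames, chain, "resname LIPA", fz$atoms)
  expect_equal(sz$scd, rep(1, 5), tolerance = 1e-12)

  fxy <- build_fixture("bilayer", seed = 1, nx = 2, ny = 2, ch_mode = "xy")
  sxy <- scd_profile(fxy$frames, chain, "resname LIPA", fxy$atoms)
  expect_equal(sxy$scd, rep(0.5, 5), tolerance = 1e-12)

  ## |S_CD| bounded in [0, 1] for random orientations
  fi <- build_fixture("bilayer", seed = 5, nx = 3, ny = 3, ch_mode = "isotropic",
                      n_frames = 3)
  si <- scd_profile(fi$frames, chain, "resname LIPA", fi$atoms)
  expect_true(all(si$scd >= 0 & si$scd <= 1))

  ## missing hydrogens is an instructive error
  bad <- list(carbons = "C2", hydrogens = list("HXX"))
  expect_error(scd_profile(fz$frames, bad, "resname LIPA", fz$atoms),
               "hydrogens")
})

test_that("membrane thickness is exact, translation-invariant, and averages jitter", {
  fx <- build_fixture("bilayer", seed = 1, nx = 4, ny = 4)
  th <- membrane_thickness(fx$frames, "name P", fx$atoms)
  expect_equal(th$dpp, 38, tolerance = 1e-12)

  shifted <- lapply(fx$frames, function(fr) {
    new_frame(sweep(fr$coords, 2L, c(0, 0, 5), "+"), box = fr$box,
              index = fr$index)
  })
  expect_equal(membrane_thickness(shifted, "name P", fx$atoms)$dpp, 38,
               tolerance = 1e-12)

  ## +-1 A uniform jitter on many atoms averages out
  fj <- build_fixture("bilayer", seed = 6, nx = 16, ny = 16, jitter = 1,
                      box = c(160, 160, 80), n_frames = 4)
  thj <- membrane_thickness(fj$frames, "name P", fj$atoms)
  expect_equal(mean(thj$dpp), 38, tolerance = 0.05)

  ## single-leaflet selection errors
  at <- atom_table(data.frame(name = "P", resname = "LIP", resid = 1:4,
                              segid = "M", element = "P"))
  fr <- new_frame(cbind(1:4, 1, 19), box = c(40, 40, 80))
  expect_error(membrane_thickness(list(fr), "name P", at), "single leaflet")
})

test_that("sterol tilt hits 0 and 90 degree limits", {
  fz <- build_fixture("bilayer", seed = 1, nx = 2, ny = 2, n_sterols = 4,
                      sterol_mode = "z")
  tz <- sterol_tilt(fz$frames, c("ST1", "ST2"), "resname STER", fz$atoms)
  expect_equal(tz$series$mean_tilt, 0, tolerance = 1e-9)

  fxy <- build_fixture("bilayer", seed = 1, nx = 2, ny = 2, n_sterols = 4,
                       sterol_mode = "xy")
  txy <- sterol_tilt(fxy$frames, c("ST1", "ST2"), "resname STER", fxy$atoms)
  expect_equal(txy$series$mean_tilt, 90, tolerance = 1e-9)
  ## histogram covers [0, 90] and counts every sterol
  expect_equal(sum(txy$histogram$count), 8)
})

test_that("K_A follows the fluctuation formula with its scaling laws", {
  kB <- 1.380649e-23
  a <- c(3980, 4020, 4000, 3990, 4010)
  res <- area_compressibility(a, 303.15)
  v <- mean((a - mean(a))^2)
  expect_equal(res$ka, kB * 303.15 * mean(a) / v * 1e23, tolerance = 1e-12)

  ## doubling the variance halves K_A (same mean)
  b <- mean(a) + (a - mean(a)) * sqrt(2)
  expect_equal(area_compressibility(b, 303.15)$ka, res$ka / 2, tolerance = 1e-9)

  ## scaling all areas by c divides K_A by c
  expect_equal(area_compressibility(3 * a, 303.15)$ka, res$ka / 3,
               tolerance = 1e-9)

  expect_error(area_compressibility(rep(4000, 5), 303.15), "constant")
  expect_error(area_compressibility(4000, 303.15), "at least 2")
})

test_that("z-density conserves counts and localizes a single atom", {
  fx <- build_fixture("ideal_gas", seed = 3, n = 500, box = c(20, 20, 50),
                      n_frames = 5)
  zd <- z_density_profile(fx$frames, list(gas = "resname GAS"), fx$atoms,
                          bin_width = 2)
  ## sum(density * bin volume) = N
  expect_equal(sum(zd$density) * 20 * 20 * 2, 500, tolerance = 1e-9)

  at <- atom_table(data.frame(name = "C1", resname = "ONE", resid = 1L,
                              segid = "X", element = "C"))
  fr <- new_frame(rbind(c(5, 5, 10)), box = c(20, 20, 50))
  z1 <- z_density_profile(list(fr), list(one = "resname ONE"), at, bin_width = 2)
  nz <- z1[z1$density > 0, ]
  expect_identical(nrow(nz), 1L)
  expect_true(nz$z > 9 - 1 & nz$z < 11)
})

test_that("lateral MSD: static, ballistic, and COM oracle", {
  at <- atom_table(data.frame(name = "P", resname = "WLK", resid = 1:3,
                              segid = "W", element = "P"))
  mk <- function(f) {
    lapply(0:9, function(t) new_frame(f(t), box = c(100, 100, 100), index = t))
  }
  static <- mk(function(t) cbind(c(10, 20, 30), 50, 50))
  expect_equal(lateral_msd(static, "resname WLK", at)$msd, rep(0, 9))

  ballistic <- mk(function(t) cbind(c(10, 20, 30) + t, 50, 50))
  msd <- lateral_msd(ballistic, "resname WLK", at)
  expect_equal(msd$msd, (1:9)^2, tolerance = 1e-9)

  ## position series matches the COM oracle per frame
  fx <- build_fixture("bilayer", seed = 7, nx = 2, ny = 2, jitter = 0.5,
                      n_frames = 3)
  pos <- position_timeseries(fx$frames, list(g = "resid 1"), fx$atoms)
  idx <- parse_selection("resid 1", fx$atoms)
  for (i in 1:3) {
    oracle <- center_of_mass(fx$frames[[i]]$coords[idx, , drop = FALSE],
                             fx$atoms$mass[idx])
    expect_no_diff(as.numeric(pos[i, c("g_x", "g_y", "g_z")]), oracle)
  }

  ## single atom at rest / arithmetic climb
  one <- atom_table(data.frame(name = "C1", resname = "ONE", resid = 1L,
                               segid = "X", element = "C"))
  climb <- lapply(0:4, function(t) new_frame(rbind(c(1, 2, 3 + t)),
                                             box = c(10, 10, 50), index = t))
  ps <- position_timeseries(climb, list(a = "resname ONE"), one)
  expect_equal(diff(ps$a_z), rep(1, 4))
  expect_equal(ps$a_x, rep(1, 5))
  expect_error(position_timeseries(climb, list(a = "resname NOPE"), one),
               "empty group")
})

test_that("shell composition matches lattice constructions", {
  ## checkerboard square lattice: shell 1 of a LIPA lipid is 4 LIPB
  fx <- build_fixture("bilayer", seed = 1, nx = 6, ny = 6,
                      types = "checkerboard")
  sc <- shell_composition(fx$frames, "name P", "LIPA", fx$atoms, n_shells = 1)
  expect_identical(nrow(sc), 1L)
  expect_identical(sc$type, "LIPB")
  expect_equal(sc$mean_count, 4, tolerance = 1e-9)

  ## two shells: shell 2 of LIPA is the 4 diagonal + 4 axial-2 LIPA... by
  ## construction shell 2 contains only LIPA on a checkerboard
  sc2 <- shell_composition(fx$frames, "name P", "LIPA", fx$atoms, n_shells = 2)
  expect_true(all(sc2$type[sc2$shell == 2] == "LIPA"))

  expect_error(shell_composition(fx$frames, "name P", "CHOL", fx$atoms),
               "center type")
})
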