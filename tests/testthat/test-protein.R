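test_that("RMSD: reference zero, rigid invariance with fit, uniform shift without", {
  fx <- build_fixture("helix", seed = 1, n_res = 10)
  at <- fx$atoms
  f0 <- fx$frames[[1]]
  set.seed(31)
  moved <- rigid_move(f0)
  shifted <- new_frame(sweep(f0$coords, 2L, c(3, 4, 0), "+"), box = f0$box,
                       index = 1L)
  frames <- list(f0, moved, shifted)

  fit <- rmsd_series(frames, "protein", 0L, at, fit = TRUE)
  raw <- rmsd_series(frames, "protein", 0L, at, fit = FALSE)
  expect_lt(fit$rmsd[1], 1e-12)
  expect_lt(fit$rmsd[2], 1e-9)          # rigid motion removed by fitting
  expect_gt(raw$rmsd[2], 1)             # but visible without fitting
  expect_equal(raw$rmsd[3], 5, tolerance = 1e-9)  # uniform (3,4,0) shift
  ## fitted RMSD never exceeds raw RMSD
  expect_true(all(fit$rmsd <= raw$rmsd + 1e-12))
})

test_that("RMSF: static zero, alternating atom 1.0, rigid motions removed", {
  fx <- build_fixture("helix", seed = 1, n_res = 6)
  at <- fx$atoms
  c0 <- fx$frames[[1]]$coords
  mk <- function(coords, i) new_frame(coords, box = c(100, 100, 100), index = i)

  static <- lapply(0:3, function(t) mk(c0, t))
  expect_no_diff(rmsf_per_residue(static, "protein", at)$rmsf, 0)

  ## one atom alternating between (0,0,0) and (2,0,0) with no global
  ## motion: its residue RMSF is exactly 1 A (hand computation)
  at3 <- atom_table(data.frame(name = "C1", resname = "TRI", resid = 1:3,
                               segid = "T", element = "C"))
  alt <- lapply(0:9, function(t) {
    new_frame(rbind(c(if (t %% 2 == 0) 0 else 2, 0, 0),
                    c(10, 0, 0), c(20, 0, 0)),
              box = c(50, 50, 50), index = t)
  })
  rf <- rmsf_per_residue(alt, "resname TRI", at3, align = FALSE)
  expect_equal(rf$rmsf, c(1, 0, 0), tolerance = 1e-12)

  ## pure rigid motions: all RMSF < 1e-6
  set.seed(32)
  rig <- lapply(0:9, function(t) rigid_move(mk(c0, t)))
  expect_lt(max(rmsf_per_residue(rig, "protein", at)$rmsf), 1e-6)
  expect_error(rmsf_per_residue(rig[1], "protein", at), "2 frames")
})

test_that("DSSP: ideal helix H, antiparallel sheet E, dipeptide blank", {
  fx <- build_fixture("helix", seed = 1, n_res = 12)
  ss <- dssp_assign(fx$frames[[1]], fx$atoms)
  ## residues with both i-1 and i 4-turns: interior is helical
  expect_true(all(ss$codes[3:10] == "H"))
  expect_identical(nchar(ss$string), 12L)
  expect_true(all(ss$codes %in% c("H", "G", "I", "E", "B", "T", "S", "-")))

  sh <- build_fixture("sheet", seed = 1, n_res = 6)
  ss2 <- dssp_assign(sh$frames[[1]], sh$atoms)
  expect_true(all(ss2$codes[c(2:4, 8:10)] == "E"))

  pep <- build_peptide(2)
  ss3 <- dssp_assign(peptide_frame(pep), pep$atoms)
  expect_identical(ss3$string, "--")

  ## invariance under rigid motion of the whole structure
  set.seed(33)
  for (i in 1:5) {
    moved <- rigid_move(fx$frames[[1]])
    expect_identical(dssp_assign(moved, fx$atoms)$string, ss$string)
  }
})

test_that("pore radius: ring values, per-bin independence, clamping", {
  fx <- build_fixture("pore", seed = 1, radii = c(5, 4))
  pr <- pore_radius_profile(fx$frames, "resname POR", fx$atoms, bin_width = 1)
  got <- pr$radius[!is.na(pr$radius)]
  expect_equal(sort(got), c(4 - 1.7, 5 - 1.7), tolerance = 1e-9)

  ## atom on the axis clamps to zero
  at <- atom_table(data.frame(name = "C1", resname = "POR", resid = 1L,
                              segid = "P", element = "C"))
  fr <- new_frame(rbind(c(0, 0, 0)), box = c(10, 10, 10))
  p0 <- pore_radius_profile(list(fr), "resname POR", at, bin_width = 1,
                            axis = c(0, 0))
  expect_equal(p0$radius[!is.na(p0$radius)], 0)
})

test_that("covariance: zero for static, +-1 normalized cross-covariance, PSD", {
  at <- atom_table(data.frame(name = c("C1", "C2"), resname = "DUO",
                              resid = 1:2, segid = "D", element = "C"))
  mk <- function(dx1, dx2, t) {
    new_frame(rbind(c(dx1, 0, 0), c(10 + dx2, 0, 0)), box = c(50, 50, 50),
              index = t)
  }
  static <- lapply(0:4, function(t) mk(0, 0, t))
  cv0 <- covariance_analysis(static, "resname DUO", at, fit = FALSE)
  expect_no_diff(cv0$covariance, 0)

  dx <- c(-1, 1, -1, 1, 0, 0)
  same <- lapply(seq_along(dx), function(i) mk(dx[i], dx[i], i - 1L))
  cvs <- covariance_analysis(same, "resname DUO", at, fit = FALSE)
  r_same <- cvs$covariance[1, 4] / sqrt(cvs$covariance[1, 1] * cvs$covariance[4, 4])
  expect_equal(r_same, 1, tolerance = 1e-12)

  opp <- lapply(seq_along(dx), function(i) mk(dx[i], -dx[i], i - 1L))
  cvo <- covariance_analysis(opp, "resname DUO", at, fit = FALSE)
  r_opp <- cvo$covariance[1, 4] / sqrt(cvo$covariance[1, 1] * cvo$covariance[4, 4])
  expect_equal(r_opp, -1, tolerance = 1e-12)

  ## PSD and trace identity against per-atom fluctuations
  fx <- build_fixture("helix", seed = 2, n_res = 8, n_frames = 6,
                      motion = "rigid")
  frames <- lapply(seq_along(fx$frames), function(i) {
    fr <- fx$frames[[i]]
    set.seed(100 + i)
    new_frame(fr$coords + matrix(stats::rnorm(length(fr$coords), 0, 0.2),
                                 nrow(fr$coords)), box = fr$box, index = fr$index)
  })
  cv <- covariance_analysis(frames, "name CA", fx$atoms, fit = TRUE)
  expect_true(all(cv$eigenvalues >= -1e-8))
  expect_no_diff(cv$covariance, t(cv$covariance))
  rf <- rmsf_per_residue(frames, "name CA", fx$atoms)
  expect_equal(sum(diag(cv$covariance)), sum(rf$rmsf^2), tolerance = 1e-6)
})
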