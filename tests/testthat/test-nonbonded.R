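test_that("hydrogen-bond gates: canonical geometry passes, distance/angle fail", {
  pass <- build_fixture("hbond_motif", seed = 1, d = 2.8, angle = 180)
  hb <- hydrogen_bonds(pass$frames, "resname DON", "resname ACC", pass$atoms)
  expect_identical(nrow(hb), length(pass$frames))
  expect_equal(hb$distance[1], 2.8, tolerance = 1e-9)
  expect_equal(hb$angle[1], 180, tolerance = 1e-9)
  expect_identical(hb$frame, sort(hb$frame))   # sorted by frame

  far <- build_fixture("hbond_motif", seed = 1, d = 5.0, angle = 180)
  expect_identical(nrow(hydrogen_bonds(far$frames, "resname DON",
                                       "resname ACC", far$atoms)), 0L)

  bent <- build_fixture("hbond_motif", seed = 1, d = 2.8, angle = 90)
  expect_identical(nrow(hydrogen_bonds(bent$frames, "resname DON",
                                       "resname ACC", bent$atoms)), 0L)

  ## relaxing both cutoffs to the permissive limit counts every D-H/A pair
  all_pairs <- hydrogen_bonds(pass$frames, "resname DON", "resname ACC",
                              pass$atoms, d_cut = 1e6, angle_cut = 0)
  expect_identical(nrow(all_pairs), length(pass$frames) * 1L)
})

test_that("salt-bridge gates and frequency ordering", {
  near <- build_fixture("salt_motif", seed = 1, d = 3.5)
  sb <- salt_bridges(near$frames, near$atoms)
  expect_identical(nrow(sb), 1L)
  expect_match(sb$resA, "LYS")
  expect_match(sb$resB, "GLU")

  far <- build_fixture("salt_motif", seed = 1, d = 6.0)
  expect_identical(nrow(salt_bridges(far$frames, far$atoms)), 0L)

  ## two pairs with different frequencies sort descending
  mk <- function(resname, resid, xyz_nz) {
    list(df = data.frame(name = c("N", "CA", "C", "O",
                                  if (resname == "LYS") "NZ" else "OE1"),
                         resname = resname, resid = resid, segid = "PROA",
                         element = c("N", "C", "C", "O",
                                     if (resname == "LYS") "N" else "O"),
                         stringsAsFactors = FALSE),
         xyz = rbind(xyz_nz$bb, xyz_nz$bb + c(1, 0, 0), xyz_nz$bb + c(2, 0, 0),
                     xyz_nz$bb + c(2, 1, 0), xyz_nz$tip))
  }
  l1 <- mk("LYS", 1, list(bb = c(-30, 0, 0), tip = c(0, 0, 0)))
  e1 <- mk("GLU", 2, list(bb = c(30, 0, 0), tip = c(3, 0, 0)))
  l2 <- mk("LYS", 3, list(bb = c(-30, 30, 0), tip = c(0, 30, 0)))
  e2 <- mk("GLU", 4, list(bb = c(30, 30, 0), tip = c(3, 30, 0)))
  at <- atom_table(rbind(l1$df, e1$df, l2$df, e2$df))
  base <- rbind(l1$xyz, e1$xyz, l2$xyz, e2$xyz)
  frames <- lapply(0:9, function(t) {
    cc <- base
    if (t >= 7) cc[20, ] <- cc[20, ] + c(20, 0, 0)  # pair 2 leaves after 7/10
    if (t >= 3) cc[10, ] <- cc[10, ] + c(20, 0, 0)  # pair 1 leaves after 3/10
    new_frame(cc, box = c(200, 200, 200), index = t)
  })
  sb2 <- salt_bridges(frames, at)
  expect_identical(nrow(sb2), 2L)
  expect_true(all(diff(sb2$frequency) <= 0))
  expect_equal(sb2$frequency, c(0.7, 0.3))
})

test_that("pi-stacking classes and distance gate", {
  par <- build_fixture("pi_motif", seed = 1, arrangement = "parallel")
  ps <- pi_stacking(par$frames, par$atoms)
  expect_identical(ps$class, "pi_parallel")

  tsh <- build_fixture("pi_motif", seed = 1, arrangement = "tshaped")
  expect_identical(pi_stacking(tsh$frames, tsh$atoms)$class, "pi_tshaped")

  far <- build_fixture("pi_motif", seed = 1, arrangement = "far")
  expect_identical(nrow(pi_stacking(far$frames, far$atoms)), 0L)
})

test_that("water bridges: single-water motif detected, chains and distance rejected", {
  yes <- build_fixture("water_bridge_motif", seed = 1)
  wb <- water_bridges(yes$frames, "resname GRA", "resname GRB", yes$atoms)
  expect_identical(nrow(wb), length(yes$frames))
  expect_match(wb$water[1], "TIP3")
  expect_identical(wb$frame, sort(wb$frame))

  no <- build_fixture("water_bridge_motif", seed = 1, bridged = FALSE)
  expect_identical(nrow(water_bridges(no$frames, "resname GRA", "resname GRB",
                                      no$atoms)), 0L)

  two <- build_fixture("water_bridge_motif", seed = 1, two_waters = TRUE)
  expect_identical(nrow(water_bridges(two$frames, "resname GRA", "resname GRB",
                                      two$atoms)), 0L)

  dry <- build_fixture("salt_motif", seed = 1)
  expect_error(water_bridges(dry$frames, "resname LYS", "resname GLU",
                             dry$atoms), "no water")
})

test_that("detectors are invariant under rigid motion and atom reordering", {
  set.seed(51)
  hbm <- build_fixture("hbond_motif", seed = 1, d = 2.9, angle = 170)
  pim <- build_fixture("pi_motif", seed = 1, arrangement = "parallel")
  for (i in 1:5) {
    moved <- lapply(hbm$frames, rigid_move, R = random_rotation(),
                    t = stats::runif(3, -5, 5))
    hb <- hydrogen_bonds(moved, "resname DON", "resname ACC", hbm$atoms)
    expect_identical(nrow(hb), length(moved))
    expect_equal(hb$distance[1], 2.9, tolerance = 1e-6)

    movedp <- lapply(pim$frames, rigid_move, R = random_rotation(),
                     t = stats::runif(3, -5, 5))
    expect_identical(pi_stacking(movedp, pim$atoms)$class, "pi_parallel")
  }

  ## atom reordering (within residues, preserving the residue-order
  ## invariant of the atom table) leaves the record set unchanged
  perm <- c(2L, 1L, 3L)
  at_perm <- atom_table(as.data.frame(hbm$atoms)[perm, ])
  frames_perm <- lapply(hbm$frames, function(fr) {
    new_frame(fr$coords[perm, , drop = FALSE], box = fr$box, index = fr$index)
  })
  hb_perm <- hydrogen_bonds(frames_perm, "resname DON", "resname ACC", at_perm)
  hb_orig <- hydrogen_bonds(hbm$frames, "resname DON", "resname ACC", hbm$atoms)
  expect_equal(hb_perm[, c("frame", "donor", "acceptor", "distance", "angle")],
               hb_orig[, c("frame", "donor", "acceptor", "distance", "angle")])
})
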