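duo_atoms <- function(n = 2L, resname = "GRP") {
  atom_table(data.frame(name = "C1", resname = resname, resid = seq_len(n),
                        segid = "X", element = "C"))
}

test_that("bond statistics: distance, angle, and periodic COM distance", {
  at <- duo_atoms(3)
  fr <- function(coords) new_frame(coords, box = c(10, 10, 10))
  f1 <- lapply(1:4, function(i) fr(rbind(c(0, 0, 0), c(3, 4, 0), c(0, 4, 0))))
  d <- bond_statistics(f1, list("resid 1", "resid 2"), at)
  expect_equal(d$mean, 5); expect_equal(d$sd, 0)

  ang <- bond_statistics(f1, list("resid 1", "resid 3", "resid 2"), at)
  expect_equal(ang$mean, 90, tolerance = 1e-9)

  ## minimum image for the two-group distance
  f2 <- list(fr(rbind(c(1, 5, 5), c(9, 5, 5), c(0, 0, 0))))
  pbc <- bond_statistics(f2, list("resid 1", "resid 2"), at)
  expect_equal(pbc$mean, 2, tolerance = 1e-9)

  expect_error(bond_statistics(f1, list("resid 1"), at), "2-4 groups")
  expect_error(bond_statistics(f1, list("resid 1", "resname NO"), at), "empty")
})

test_that("residue contacts: frequencies, ordering, and alternating series", {
  at <- duo_atoms(3)
  near <- rbind(c(0, 0, 0), c(3, 0, 0), c(30, 0, 0))
  far <- rbind(c(0, 0, 0), c(20, 0, 0), c(30, 0, 0))
  frames <- lapply(0:9, function(t) {
    new_frame(if (t %% 2 == 0) near else far, box = c(100, 100, 100), index = t)
  })
  rc <- residue_contacts(frames, "resid 1", "resid 2:3", at, cutoff = 4.5)
  expect_identical(nrow(rc), 1L)         # the 20 A pair never appears
  expect_equal(rc$frequency, 0.5)        # contact in 5 of 10 frames
  expect_identical(rc$frames, "0,2,4,6,8")

  ## always-contact pair has frequency 1 and sorts first
  rc2 <- residue_contacts(list(frames[[1]]), "resid 1", "resid 2:3", at, 4.5)
  expect_equal(rc2$frequency, 1)

  ## frequency in [0, 1] and descending order
  expect_true(all(rc$frequency >= 0 & rc$frequency <= 1))
})

test_that("residence times equal the independent run-length oracle", {
  ## hand examples
  rt <- contact_residence_time(list(p = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)))
  expect_equal(rt$n_events, 2L)
  expect_equal(rt$mean_frames, 2.5)
  expect_equal(rt$sd_frames, 0.5)

  rt2 <- contact_residence_time(list(p = rep(TRUE, 10)))
  expect_equal(rt2[, c("n_events", "mean_frames", "sd_frames")],
               data.frame(n_events = 1L, mean_frames = 10, sd_frames = 0))

  ## all-false series is omitted
  expect_identical(nrow(contact_residence_time(list(p = rep(FALSE, 5)))), 0L)

  ## 1000 random series against the position-by-position scanner
  set.seed(41)
  for (i in 1:1000) {
    s <- stats::runif(sample(3:40, 1)) < 0.45
    durations <- runs_oracle(s)
    rt <- contact_residence_time(list(x = s))
    if (length(durations) == 0L) {
      expect_identical(nrow(rt), 0L)
    } else {
      expect_equal(rt$n_events, length(durations))
      expect_equal(rt$mean_frames, mean(durations))
      expect_equal(rt$sd_frames, sqrt(mean((durations - mean(durations))^2)))
      ## residence-time identity: total contact frames
      expect_equal(rt$total_frames, sum(s))
    }
  }
})

test_that("gap tolerance merges runs separated by short gaps", {
  s <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
  expect_identical(runs_oracle(bridge_contact_gaps(s, 0L)), c(2L, 1L, 1L))
  expect_identical(runs_oracle(bridge_contact_gaps(s, 1L)), c(4L, 1L))
  expect_identical(runs_oracle(bridge_contact_gaps(s, 2L)), c(7L))
})

test_that("RDF: isolated pair bin, counting identity, ideal gas plateau", {
  at <- duo_atoms(2)
  fr <- new_frame(rbind(c(5, 5, 5), c(10, 5, 5)), box = c(30, 30, 30))
  rdf <- radial_distribution(list(fr), "resid 1", "resid 2", at,
                             bin_width = 0.5, r_max = 14)
  nz <- rdf[rdf$g > 0, ]
  expect_identical(nrow(nz), 1L)
  expect_lt(abs(nz$r - 5), 0.5)

  expect_error(radial_distribution(list(fr), "resid 1", "resid 2", at,
                                   bin_width = 0.5, r_max = 16), "r_max")

  ## counting identity on a small gas
  fx <- build_fixture("ideal_gas", seed = 5, n = 300, box = c(30, 30, 30),
                      n_frames = 10)
  g <- radial_distribution(fx$frames, "resname GAS", "resname GAS", fx$atoms,
                           bin_width = 0.3, r_max = 12)
  rho <- 300 / 30^3
  integral <- sum(g$g * 4 * pi * g$r^2 * 0.3) * rho
  expect_equal(integral, attr(g, "mean_neighbors"), tolerance = 0.01)
  expect_true(all(g$g >= 0))
  expect_equal(mean(g$g[g$r > 2]), 1, tolerance = 0.05)
})
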