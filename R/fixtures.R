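## Seeded synthetic-fixture generators.  Every generator produces a
## structure + trajectory with analytically known ground truth, written
## as PDB + DCD + a metadata TSV of expected values; the same spec and
## seed always reproduce byte-identical files.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## ---------------------------------------------------------------------
## peptide construction by internal-coordinate chain extension

## place x with |x-p3| = bond, angle(p2,p3,x) = ang, dihedral(p1,p2,p3,x) = tors
place_atom <- function(p1, p2, p3, bond, ang, tors) {
  angr <- ang * pi / 180
  torsr <- tors * pi / 180
  bc <- p3 - p2
  bc <- bc / sqrt(sum(bc^2))
  n <- cross3(p2 - p1, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d <- bond * c(-cos(angr), sin(angr) * cos(torsr), sin(angr) * sin(torsr))
  p3 + d[1] * bc + d[2] * m + d[3] * n
}

#' Build an ideal polypeptide backbone
#'
#' Chains N-CA-C repeats with standard bond lengths/angles and the given
#' backbone dihedrals (omega fixed at 180); carbonyl O and amide H are
#' placed from the local frame.  Residues are alanine-like (backbone
#' only).
#'
#' @param n_res number of residues.
#' @param phi,psi backbone dihedrals in degrees (scalar or per-residue).
#' @param segid,resid_start identifiers.
#' @return list with `atoms` ([atom_table()]) and `coords` (N x 3).
#' @export
build_peptide <- function(n_res, phi = -57, psi = -47, segid = "PROA",
                          resid_start = 1L) {
  phi <- rep_len(phi, n_res); psi <- rep_len(psi, n_res)
  b_NCA <- 1.458; b_CAC <- 1.525; b_CN <- 1.329
  a_NCAC <- 111.2; a_CACN <- 116.2; a_CNCA <- 121.7

  N <- matrix(NA_real_, n_res, 3); CA <- N; C <- N; O <- N; H <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(b_NCA, 0, 0)
  ar <- a_NCAC * pi / 180
  C[1, ] <- CA[1, ] + b_CAC * c(-cos(ar), sin(ar), 0)
  for (r in seq_len(n_res)) {
    if (r > 1L) {
      N[r, ]  <- place_atom(N[r - 1, ], CA[r - 1, ], C[r - 1, ], b_CN, a_CACN, psi[r - 1])
      CA[r, ] <- place_atom(CA[r - 1, ], C[r - 1, ], N[r, ], b_NCA, a_CNCA, 180)
      C[r, ]  <- place_atom(C[r - 1, ], N[r, ], CA[r, ], b_CAC, a_NCAC, phi[r])
    }
  }
  for (r in seq_len(n_res)) {
    ## carbonyl O anti to the next amide nitrogen
    psi_eff <- psi[r]
    O[r, ] <- place_atom(N[r, ], CA[r, ], C[r, ], 1.231, 120.5, psi_eff + 180)
    if (r > 1L) {
      v <- C[r - 1, ] - O[r - 1, ]
      H[r, ] <- N[r, ] + 1.01 * v / sqrt(sum(v^2))
    }
  }

  per_res <- function(r) {
    nm <- c("N", "CA", "C", "O"); xyz <- rbind(N[r, ], CA[r, ], C[r, ], O[r, ])
    if (r > 1L) { nm <- c(nm, "HN"); xyz <- rbind(xyz, H[r, ]) }
    list(nm = nm, xyz = xyz)
  }
  parts <- lapply(seq_len(n_res), per_res)
  atoms <- atom_table(data.frame(
    name = unlist(lapply(parts, `[[`, "nm")),
    resname = rep("ALA", sum(vapply(parts, function(p) length(p[["nm"]]), 1L))),
    resid = rep(resid_start + seq_len(n_res) - 1L,
                vapply(parts, function(p) length(p[["nm"]]), 1L)),
    segid = segid, stringsAsFactors = FALSE))
  list(atoms = atoms, coords = do.call(rbind, lapply(parts, `[[`, "xyz")))
}

#' Build an ideal antiparallel beta sheet (two strands)
#'
#' Strand 1 uses the given dihedrals; strand 2 is the 180-degree rotation
#' of strand 1 about the axis normal to the strand plane, and its offset
#' along/across the strand is chosen (deterministically, on a fixed grid)
#' to maximize the number of Kabsch-Sander inter-strand hydrogen bonds.
#'
#' @param n_res residues per strand.
#' @param phi,psi strand dihedrals (degrees).
#' @return list with `atoms` and `coords` for the two-strand system.
#' @export
build_sheet <- function(n_res = 6L, phi = -139, psi = 135) {
  s1 <- build_peptide(n_res, phi, psi, segid = "PROA")
  n1 <- nrow(s1$coords)

  ## principal strand axis ~ x after aligning CA vector to x
  ca_idx <- which(s1$atoms$name == "CA")
  axis <- s1$coords[ca_idx[n_res], ] - s1$coords[ca_idx[1], ]
  axis <- axis / sqrt(sum(axis^2))
  ## rotate so the strand runs along +x, centered at the origin
  R <- rotation_onto(axis, c(1, 0, 0))
  c1 <- s1$coords %*% t(R)
  c1 <- sweep(c1, 2L, colMeans(c1))

  rot180z <- diag(c(-1, -1, 1))
  best <- NULL
  for (dy in seq(4.0, 5.6, by = 0.1)) {
    for (dx in seq(-4, 4, by = 0.1)) {
      c2 <- c1 %*% t(rot180z)
      c2 <- sweep(c2, 2L, c(dx, dy, 0), "+")
      sc <- count_interstrand_hbonds(s1$atoms, c1, c2)
      if (is.null(best) || sc > best$score) best <- list(score = sc, dx = dx, dy = dy)
    }
  }
  c2 <- sweep(c1 %*% t(rot180z), 2L, c(best$dx, best$dy, 0), "+")

  a2 <- s1$atoms
  a2$segid <- "PROB"
  atoms <- atom_table(rbind(as.data.frame(s1$atoms), as.data.frame(a2)))
  list(atoms = atoms, coords = rbind(c1, c2), hbond_score = best$score)
}

rotation_onto <- function(u, v) {
  ## rotation matrix sending unit vector u to unit vector v
  w <- cross3(u, v)
  s <- sqrt(sum(w^2)); cth <- sum(u * v)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w <- cross3(u, p); w <- w / sqrt(sum(w^2))
    return(2 * outer(w, w) - diag(3))
  }
  K <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0), 3, 3, byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - cth) / s^2)
}

count_interstrand_hbonds <- function(atoms1, c1, c2) {
  fr <- new_frame(rbind(c1, c2), box = NULL)
  a2 <- atoms1; a2$segid <- "PROB"
  at <- atom_table(rbind(as.data.frame(atoms1), as.data.frame(a2)))
  res <- backbone_atoms(fr, at)
  n <- length(res) / 2L
  cnt <- 0L
  for (i in seq_len(n)) {
    for (j in (n + 1L):(2L * n)) {
      if (ks_energy(res, i, j) < -0.5) cnt <- cnt + 1L
      if (ks_energy(res, j, i) < -0.5) cnt <- cnt + 1L
    }
  }
  cnt
}

## ---------------------------------------------------------------------
## fixture kinds

fixture_bilayer <- function(p) {
  nx <- p[["nx"]] %||% 4L; ny <- p[["ny"]] %||% 4L
  box <- p[["box"]] %||% c(40, 40, 80)
  z0 <- p[["z_head"]] %||% 19
  n_carbons <- p[["n_carbons"]] %||% 5L
  ch_mode <- p[["ch_mode"]] %||% "z"
  types <- p[["types"]] %||% "single"     # "single" or "checkerboard"
  n_frames <- p[["n_frames"]] %||% 1L
  jitter <- p[["jitter"]] %||% 0
  n_sterols <- p[["n_sterols"]] %||% 0L
  sterol_mode <- p[["sterol_mode"]] %||% "z"

  ax <- box[1] / nx; ay <- box[2] / ny
  rows <- list(); resid <- 0L
  lipid_xyz0 <- list()
  meta <- list()
  for (leaflet in c(1, -1)) {
    for (iy in seq_len(ny) - 1L) {
      for (ix in seq_len(nx) - 1L) {
        resid <- resid + 1L
        x <- (ix + 0.5) * ax; y <- (iy + 0.5) * ay
        resname <- if (types == "checkerboard" && (ix + iy) %% 2L == 1L) "LIPB" else "LIPA"
        nm <- "P"; el <- "P"
        xyz <- matrix(c(x, y, leaflet * z0), 1L)
        for (ci in seq_len(n_carbons)) {
          cz <- leaflet * (z0 - 1.5 * ci)
          nm <- c(nm, paste0("C", ci + 1L),
                  paste0("H", ci + 1L, "A"), paste0("H", ci + 1L, "B"))
          el <- c(el, "C", "H", "H")
          xyz <- rbind(xyz, c(x, y, cz), c(NA, NA, NA), c(NA, NA, NA))
        }
        rows[[resid]] <- data.frame(name = nm, resname = resname,
                                    resid = resid, segid = "MEMB",
                                    element = el, stringsAsFactors = FALSE)
        lipid_xyz0[[resid]] <- xyz
      }
    }
  }
  n_lipids <- resid
  ## sterols: two-atom molecules on an offset sublattice
  sterol_first <- resid + 1L
  if (n_sterols > 0L) {
    for (leaflet in c(1, -1)) {
      for (k in seq_len(n_sterols)) {
        resid <- resid + 1L
        x <- (k %% nx) * ax + 0.11 * ax
        y <- ((k %/% nx) %% ny) * ay + 0.13 * ay
        rows[[resid]] <- data.frame(name = c("ST1", "ST2"), resname = "STER",
                                    resid = resid, segid = "MEMB",
                                    element = "C", stringsAsFactors = FALSE)
        lipid_xyz0[[resid]] <- rbind(c(x, y, leaflet * 8), c(NA, NA, NA))
      }
    }
  }
  atoms <- atom_table(do.call(rbind, rows))

  box_fluct <- p[["box_fluct"]] %||% 0   # relative sigma of lateral box scaling

  make_frame <- function(t) {
    xyz <- do.call(rbind, lipid_xyz0)
    fbox <- box
    if (box_fluct > 0) {
      f <- 1 + stats::rnorm(1, 0, box_fluct)
      fbox[1:2] <- box[1:2] * f
      xyz[, 1:2] <- xyz[, 1:2] * f
    }
    if (jitter > 0) {
      base <- !is.na(xyz[, 1])
      xyz[base, 3] <- xyz[base, 3] + stats::runif(sum(base), -jitter, jitter)
    }
    ## fill hydrogens: within a lipid block, carbon ci sits at row
    ## 1 + 3*(ci-1) + 1 and its two hydrogens follow it
    i <- 0L
    for (r in seq_len(n_lipids)) {
      for (ci in seq_len(n_carbons)) {
        crow <- i + 2L + 3L * (ci - 1L)
        cpos <- xyz[crow, ]
        dirs <- switch(ch_mode,
          z = list(c(0, 0, 1), c(0, 0, -1)),
          xy = list(c(1, 0, 0), c(0, 1, 0)),
          isotropic = {
            v1 <- stats::rnorm(3); v2 <- stats::rnorm(3)
            list(v1 / sqrt(sum(v1^2)), v2 / sqrt(sum(v2^2)))
          },
          stop("unknown ch_mode: ", ch_mode))
        xyz[crow + 1L, ] <- cpos + 1.09 * dirs[[1]]
        xyz[crow + 2L, ] <- cpos + 1.09 * dirs[[2]]
      }
      i <- i + nrow(lipid_xyz0[[r]])
    }
    ## sterol orientation vectors (tail at fixed site, head 8 A along u)
    if (n_sterols > 0L) {
      idx <- i
      for (r in sterol_first:length(lipid_xyz0)) {
        tail_pos <- xyz[idx + 1L, ]
        u <- switch(sterol_mode,
          z = c(0, 0, if (tail_pos[3] >= 0) 1 else -1),
          xy = c(1, 0, 0),
          isotropic = { v <- stats::rnorm(3); v / sqrt(sum(v^2)) },
          stop("unknown sterol_mode: ", sterol_mode))
        xyz[idx + 2L, ] <- tail_pos + 8 * u
        idx <- idx + 2L
      }
    }
    new_frame(xyz, box = fbox, index = t - 1L)
  }
  frames <- lapply(seq_len(n_frames), make_frame)

  apl <- box[1] * box[2] / (nx * ny)
  scd_expect <- switch(ch_mode, z = 1.0, xy = 0.5, isotropic = 0.0)
  truth <- data.frame(
    observable = c("apl", "dpp", "scd", "box_area"),
    expected = c(apl, 2 * z0, scd_expect, box[1] * box[2]),
    tolerance = c(1e-6, if (jitter > 0) 0.05 else 1e-6,
                  if (ch_mode == "isotropic") 0.01 else 1e-9, 1e-6))
  list(atoms = atoms, frames = frames, truth = truth)
}

fixture_ideal_gas <- function(p) {
  n <- p[["n"]] %||% 1000L
  box <- p[["box"]] %||% c(30, 30, 30)
  n_frames <- p[["n_frames"]] %||% 100L
  atoms <- atom_table(data.frame(name = "C1", resname = "GAS",
                                 resid = seq_len(n), segid = "BULK",
                                 element = "C", stringsAsFactors = FALSE))
  frames <- lapply(seq_len(n_frames), function(t) {
    new_frame(cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]),
                    stats::runif(n, 0, box[3])), box = box, index = t - 1L)
  })
  truth <- data.frame(observable = c("g_r", "number_density"),
                      expected = c(1.0, n / prod(box)),
                      tolerance = c(0.05, NA))
  list(atoms = atoms, frames = frames, truth = truth)
}

fixture_random_walk <- function(p) {
  n <- p[["n"]] %||% 200L
  sigma <- p[["sigma"]] %||% 0.5
  n_frames <- p[["n_frames"]] %||% 500L
  box <- p[["box"]] %||% c(100, 100, 100)
  dims <- p[["dims"]] %||% 2L
  atoms <- atom_table(data.frame(name = "P", resname = "WLK",
                                 resid = seq_len(n), segid = "WALK",
                                 element = "P", stringsAsFactors = FALSE))
  pos <- cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]),
               if (dims == 3L) stats::runif(n, 0, box[3]) else rep(box[3] / 2, n))
  frames <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    if (t > 1L) {
      step <- matrix(stats::rnorm(n * dims, 0, sigma), n, dims)
      pos[, seq_len(dims)] <- pos[, seq_len(dims)] + step
    }
    wrapped <- pos
    for (d in 1:3) wrapped[, d] <- pos[, d] %% box[d]
    frames[[t]] <- new_frame(wrapped, box = box, index = t - 1L)
  }
  D <- sigma^2 / 2  # per-frame Einstein: MSD(tau) = 2 d D tau with dt = 1
  truth <- data.frame(observable = "D", expected = D, tolerance = 0.1 * D)
  list(atoms = atoms, frames = frames, truth = truth)
}

fixture_helix <- function(p) {
  n_res <- p[["n_res"]] %||% 12L
  pep <- build_peptide(n_res, p[["phi"]] %||% -57, p[["psi"]] %||% -47)
  box <- p[["box"]] %||% c(100, 100, 100)
  n_frames <- p[["n_frames"]] %||% 1L
  motion <- p[["motion"]] %||% "static"   # static | rigid (deterministic tumble)
  ## center in the box
  xyz <- sweep(pep$coords, 2L, colMeans(pep$coords))
  frames <- lapply(seq_len(n_frames), function(t) {
    m <- xyz
    if (motion == "rigid" && t > 1L) {
      th <- (t - 1L) * 10 * pi / 180
      Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                   3L, 3L, byrow = TRUE)
      m <- m %*% Rz + matrix(c(t - 1, 0.5 * (t - 1), 0), nrow(m), 3L, byrow = TRUE)
    }
    new_frame(sweep(m, 2L, box / 2, "+"), box = box, index = t - 1L)
  })
  truth <- data.frame(observable = "interior_code", expected = NA,
                      tolerance = NA)
  truth$expected_chr <- "H"
  list(atoms = pep$atoms, frames = frames, truth = truth)
}

fixture_sheet <- function(p) {
  sh <- build_sheet(p[["n_res"]] %||% 6L, p[["phi"]] %||% -139, p[["psi"]] %||% 135)
  box <- p[["box"]] %||% c(100, 100, 100)
  xyz <- sweep(sh$coords, 2L, colMeans(sh$coords))
  xyz <- sweep(xyz, 2L, box / 2, "+")
  truth <- data.frame(observable = "interior_code", expected = NA, tolerance = NA)
  truth$expected_chr <- "E"
  list(atoms = sh$atoms, frames = list(new_frame(xyz, box = box)), truth = truth)
}

fixture_hbond_motif <- function(p) {
  d <- p[["d"]] %||% 2.8
  angle <- p[["angle"]] %||% 180
  n_frames <- p[["n_frames"]] %||% 3L
  box <- p[["box"]] %||% c(30, 30, 30)
  atoms <- atom_table(data.frame(
    name = c("OD", "HD", "OA"),
    resname = c("DON", "DON", "ACC"),
    resid = c(1L, 1L, 2L), segid = "MOTF",
    element = c("O", "H", "O"), stringsAsFactors = FALSE))
  b_oh <- 0.96
  acc <- if (abs(angle - 180) < 1e-9) {
    c(d, 0, 0)
  } else {
    ## acceptor at distance d from donor with the requested D-H...A angle
    th <- angle * pi / 180
    ## solve for A on the plane: A = H + r * (cos(pi - th), sin(pi - th), 0)
    ## with |A - D| = d
    f <- function(r) {
      a <- c(b_oh, 0, 0) + r * c(cos(pi - th), sin(pi - th), 0)
      sqrt(sum(a^2)) - d
    }
    r <- stats::uniroot(f, c(0.1, d + 2), tol = 1e-12)$root
    c(b_oh, 0, 0) + r * c(cos(pi - th), sin(pi - th), 0)
  }
  xyz <- rbind(c(0, 0, 0), c(b_oh, 0, 0), acc)
  xyz <- sweep(xyz, 2L, box / 2, "+")
  frames <- lapply(seq_len(n_frames), function(t) new_frame(xyz, box = box, index = t - 1L))
  truth <- data.frame(observable = "hbond_per_frame",
                      expected = as.numeric(d <= 3.5 && angle >= 150),
                      tolerance = 0)
  list(atoms = atoms, frames = frames, truth = truth)
}

fixture_salt_motif <- function(p) {
  d <- p[["d"]] %||% 3.5
  n_frames <- p[["n_frames"]] %||% 3L
  box <- p[["box"]] %||% c(40, 40, 40)
  mk <- function(resname, resid, names, elements, xyz) {
    data.frame(name = names, resname = resname, resid = resid, segid = "PROA",
               element = elements, stringsAsFactors = FALSE)
  }
  atoms <- atom_table(rbind(
    mk("LYS", 1L, c("N", "CA", "C", "O", "NZ"), c("N", "C", "C", "O", "N")),
    mk("GLU", 2L, c("N", "CA", "C", "O", "OE1"), c("N", "C", "C", "O", "O"))))
  ## backbones parked far apart; only NZ...OE1 is near
  lys <- rbind(c(-12, 0, 0), c(-11, 0, 0), c(-10, 0, 0), c(-10, 1, 0), c(0, 0, 0))
  glu <- rbind(c(12, 8, 0), c(11, 8, 0), c(10, 8, 0), c(10, 9, 0), c(d, 0, 0))
  xyz <- sweep(rbind(lys, glu), 2L, box / 2, "+")
  frames <- lapply(seq_len(n_frames), function(t) new_frame(xyz, box = box, index = t - 1L))
  truth <- data.frame(observable = "salt_bridge_detected",
                      expected = as.numeric(d <= 4.0), tolerance = 0)
  list(atoms = atoms, frames = frames, truth = truth)
}

hexagon <- function(center, radius = 1.39, normal = c(0, 0, 1)) {
  R <- rotation_onto(c(0, 0, 1), normal / sqrt(sum(normal^2)))
  ang <- seq(0, 2 * pi, length.out = 7L)[-7L]
  ring <- cbind(radius * cos(ang), radius * sin(ang), 0)
  sweep(ring %*% t(R), 2L, center, "+")
}

fixture_pi_motif <- function(p) {
  kind <- p[["arrangement"]] %||% "parallel"   # parallel | tshaped | far
  n_frames <- p[["n_frames"]] %||% 3L
  box <- p[["box"]] %||% c(40, 40, 40)
  ring_names <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  atoms <- atom_table(data.frame(
    name = rep(ring_names, 2L), resname = "PHE",
    resid = rep(c(1L, 2L), each = 6L), segid = "PROA",
    element = "C", stringsAsFactors = FALSE))
  r1 <- hexagon(c(0, 0, 0))
  r2 <- switch(kind,
    parallel = hexagon(c(0, 0, 3.8)),
    tshaped = hexagon(c(0, 0, 5.0), normal = c(1, 0, 0)),
    far = hexagon(c(0, 0, 9.0)),
    stop("unknown arrangement: ", kind))
  xyz <- sweep(rbind(r1, r2), 2L, box / 2, "+")
  frames <- lapply(seq_len(n_frames), function(t) new_frame(xyz, box = box, index = t - 1L))
  cls <- switch(kind, parallel = "pi_parallel", tshaped = "pi_tshaped", far = "none")
  truth <- data.frame(observable = "pi_class", expected = NA, tolerance = NA)
  truth$expected_chr <- cls
  list(atoms = atoms, frames = frames, truth = truth)
}

fixture_water_bridge_motif <- function(p) {
  bridged <- p[["bridged"]] %||% TRUE
  chain2 <- p[["two_waters"]] %||% FALSE
  n_frames <- p[["n_frames"]] %||% 3L
  box <- p[["box"]] %||% c(40, 40, 40)
  b_oh <- 0.96
  mkres <- function(resname, resid, names, elements) {
    data.frame(name = names, resname = resname, resid = resid, segid = "MOTF",
               element = elements, stringsAsFactors = FALSE)
  }
  grpA <- mkres("GRA", 1L, c("OG", "HG"), c("O", "H"))
  grpB <- mkres("GRB", 2L, "OB", "O")
  w1 <- mkres("TIP3", 3L, c("OH2", "H1", "H2"), c("O", "H", "H"))
  a_pos <- rbind(c(0, 0, 0), c(b_oh, 0, 0))
  if (!chain2) {
    w1_o <- if (bridged) c(2.8, 0, 0) else c(8, 0, 0)
    w1_pos <- rbind(w1_o, w1_o + c(0, b_oh, 0), w1_o + c(-0.3, -0.91, 0))
    b_pos <- rbind(w1_o + c(0, 2.8, 0))
    atoms <- atom_table(rbind(grpA, grpB, w1))
    xyz <- rbind(a_pos, b_pos, w1_pos)
  } else {
    ## A - w1 - w2 - B chain: no single water touches both sides
    w2 <- mkres("TIP3", 4L, c("OH2", "H1", "H2"), c("O", "H", "H"))
    w1_o <- c(2.8, 0, 0)
    w1_pos <- rbind(w1_o, w1_o + c(b_oh, 0, 0), w1_o + c(-0.3, -0.91, 0))
    w2_o <- c(2.8 + 2.8, 0, 0)
    w2_pos <- rbind(w2_o, w2_o + c(b_oh, 0, 0), w2_o + c(-0.3, 0.91, 0))
    b_pos <- rbind(w2_o + c(2.8, 0, 0))
    atoms <- atom_table(rbind(grpA, grpB, w1, w2))
    xyz <- rbind(a_pos, b_pos, w1_pos, w2_pos)
  }
  xyz <- sweep(xyz, 2L, box / 2, "+")
  frames <- lapply(seq_len(n_frames), function(t) new_frame(xyz, box = box, index = t - 1L))
  truth <- data.frame(observable = "water_bridge_detected",
                      expected = as.numeric(bridged && !chain2), tolerance = 0)
  list(atoms = atoms, frames = frames, truth = truth)
}

fixture_pore <- function(p) {
  radii <- p[["radii"]] %||% c(5, 4)
  z_levels <- p[["z_levels"]] %||% seq(0, by = 4, length.out = length(radii))
  n_ring <- p[["n_ring"]] %||% 12L
  box <- p[["box"]] %||% c(60, 60, 60)
  rows <- list(); xyz <- list()
  for (k in seq_along(radii)) {
    ang <- seq(0, 2 * pi, length.out = n_ring + 1L)[-(n_ring + 1L)]
    rows[[k]] <- data.frame(name = "C1", resname = "POR",
                            resid = k, segid = "PORE", element = "C",
                            stringsAsFactors = FALSE)[rep(1, n_ring), ]
    xyz[[k]] <- cbind(box[1] / 2 + radii[k] * cos(ang),
                      box[2] / 2 + radii[k] * sin(ang),
                      box[3] / 2 + z_levels[k])
  }
  atoms <- atom_table(do.call(rbind, rows))
  frames <- list(new_frame(do.call(rbind, xyz), box = box))
  truth <- data.frame(observable = paste0("radius_ring", seq_along(radii)),
                      expected = pmax(0, radii - 1.7), tolerance = 1e-6)
  list(atoms = atoms, frames = frames, truth = truth)
}

#' Build a synthetic fixture with known ground truth
#'
#' Deterministic, seeded generators for every analysis in the registry:
#' flat bilayers with prescribed C-H orientations (optionally with
#' sterols), ideal-gas boxes, periodic random walks with known diffusion,
#' ideal helices and antiparallel sheets, hand-placed hydrogen-bond /
#' salt-bridge / pi-stacking / water-bridge motifs, and atom-ring pores.
#'
#' @param kind one of `"bilayer"`, `"ideal_gas"`, `"random_walk"`,
#'   `"helix"`, `"sheet"`, `"hbond_motif"`, `"salt_motif"`, `"pi_motif"`,
#'   `"water_bridge_motif"`, `"pore"`.
#' @param out_dir directory for `structure.pdb`, `traj.dcd`, and
#'   `ground_truth.tsv` (created); `NULL` keeps everything in memory.
#' @param seed integer RNG seed; the same spec and seed reproduce
#'   byte-identical files.
#' @param ... kind-specific parameters (see the fixture functions).
#' @return invisible list with `atoms`, `frames`, `truth`, and (when
#'   written) `structure_path`, `trajectory_path`, `truth_path`.
#' @export
build_fixture <- function(kind, out_dir = NULL, seed = 1L, ...) {
  p <- list(...)
  fx <- with_seed(seed, switch(kind,
    bilayer = fixture_bilayer(p),
    ideal_gas = fixture_ideal_gas(p),
    random_walk = fixture_random_walk(p),
    helix = fixture_helix(p),
    sheet = fixture_sheet(p),
    hbond_motif = fixture_hbond_motif(p),
    salt_motif = fixture_salt_motif(p),
    pi_motif = fixture_pi_motif(p),
    water_bridge_motif = fixture_water_bridge_motif(p),
    pore = fixture_pore(p),
    stop("unknown fixture kind: ", kind)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fx$structure_path <- file.path(out_dir, "structure.pdb")
    fx$trajectory_path <- file.path(out_dir, "traj.dcd")
    fx$truth_path <- file.path(out_dir, "ground_truth.tsv")
    write_pdb(fx$atoms, fx$frames[[1]], fx$structure_path)
    write_dcd(fx$frames, fx$trajectory_path,
              title = paste("fixture", kind, "seed", seed))
    write_tsv_table(fx$truth, fx$truth_path)
  }
  invisible(fx)
}

#' Ground-truth table for a fixture spec
#'
#' @inheritParams build_fixture
#' @return data frame (`observable`, `expected`, `tolerance`, and
#'   `expected_chr` for string-valued observables).
#' @export
emit_ground_truth <- function(kind, seed = 1L, ...) {
  build_fixture(kind, out_dir = NULL, seed = seed, ...)$truth
}
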