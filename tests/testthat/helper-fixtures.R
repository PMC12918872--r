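## shared test helpers: in-code fixtures and small oracles

## build a fixture on disk and return a project config path for it
make_project <- function(kind, ..., seed = 1L) {
  td <- withr::local_tempdir(.local_envir = parent.frame())
  build_fixture(kind, out_dir = td, seed = seed, ...)
  cfg <- file.path(td, "project.json")
  jsonlite::write_json(list(structure_path = file.path(td, "structure.pdb"),
                            trajectory_pattern = file.path(td, "traj.dcd"),
                            output_dir = file.path(td, "out")),
                       cfg, auto_unbox = TRUE)
  cfg
}

## random proper rotation matrix
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3L, 3L, byrow = TRUE)
}

## apply a random rigid motion to a frame
rigid_move <- function(frame, R = random_rotation(),
                       t = stats::runif(3, -10, 10)) {
  new_frame(frame$coords %*% R + matrix(t, nrow(frame$coords), 3L, byrow = TRUE),
            box = frame$box, index = frame$index, time = frame$time)
}

## independent run-length scanner (position-by-position, no rle)
runs_oracle <- function(s) {
  durations <- integer(0)
  cur <- 0L
  for (x in s) {
    if (x) {
      cur <- cur + 1L
    } else if (cur > 0L) {
      durations <- c(durations, cur)
      cur <- 0L
    }
  }
  if (cur > 0L) durations <- c(durations, cur)
  durations
}

## hand natural-sort oracle: split into runs, pad integers, sort
natural_sort_oracle <- function(paths) {
  key <- vapply(paths, function(p) {
    parts <- regmatches(p, gregexpr("[0-9]+|[^0-9]+", p))[[1]]
    paste(vapply(parts, function(s) {
      if (grepl("^[0-9]+$", s)) sprintf("%020.0f", as.numeric(s)) else s
    }, character(1)), collapse = "")
  }, character(1))
  paths[order(key, paths)]
}

## minimal peptide frame wrapper
peptide_frame <- function(pep, box = c(100, 100, 100)) {
  new_frame(pep$coords, box = box)
}

expect_no_diff <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a - b)), tol)
}

## fixture-backed CLI invocation for every analysis in the registry;
## returns a named list of argv vectors (without the analysis name)
all_analysis_runs <- function(envir = parent.frame()) {
  mk <- function(kind, ...) make_project(kind, ..., seed = 1L)
  ## make_project uses withr::local_tempdir in *its* caller frame; wrap
  local_mk <- function(kind, ...) {
    td <- withr::local_tempdir(.local_envir = envir)
    build_fixture(kind, out_dir = td, seed = 1L, ...)
    cfg <- file.path(td, "project.json")
    jsonlite::write_json(list(structure_path = file.path(td, "structure.pdb"),
                              trajectory_pattern = file.path(td, "traj.dcd"),
                              output_dir = file.path(td, "out")),
                         cfg, auto_unbox = TRUE)
    cfg
  }
  bil <- local_mk("bilayer", nx = 4, ny = 4, n_frames = 3,
                  types = "checkerboard", n_sterols = 3, jitter = 0.2,
                  box_fluct = 0.01)
  hel <- local_mk("helix", n_res = 12, n_frames = 4, motion = "rigid")
  walk <- local_mk("random_walk", n = 20, n_frames = 50)
  gas <- local_mk("ideal_gas", n = 200, n_frames = 5)
  pore <- local_mk("pore")
  hbm <- local_mk("hbond_motif")
  slm <- local_mk("salt_motif")
  pim <- local_mk("pi_motif")
  wbm <- local_mk("water_bridge_motif")
  list(
    sterol_tilt = c("--project", bil, "--sel", "resname STER"),
    z_density = c("--project", bil, "--sel", "name P"),
    msd_membrane = c("--project", walk, "--sel", "resname WLK"),
    scd = c("--project", bil, "--sel", "resname LIPA"),
    thickness = c("--project", bil, "--sel", "name P"),
    apl = c("--project", bil, "--sel", "name P"),
    shell_composition = c("--project", bil, "--sel", "name P",
                          "--center-type", "LIPA"),
    area_compressibility = c("--project", bil),
    position = c("--project", bil, "--sel", "name P"),
    system_size = c("--project", bil),
    secondary_structure = c("--project", hel),
    pore_radius = c("--project", pore, "--sel", "resname POR"),
    rmsd = c("--project", hel, "--sel", "protein"),
    rmsf = c("--project", hel, "--sel", "protein"),
    bond_statistics = c("--project", hel, "--groups",
                        "resid 1;resid 6;resid 12"),
    residence_time = c("--project", hel, "--sel-a", "resid 1:3",
                       "--sel-b", "resid 4:6"),
    residue_contacts = c("--project", hel, "--sel-a", "resid 1:3",
                         "--sel-b", "resid 4:6"),
    rdf = c("--project", gas, "--sel-a", "resname GAS", "--sel-b",
            "resname GAS", "--bin-width", "0.5"),
    hbond = c("--project", hbm, "--donor-sel", "resname DON",
              "--acceptor-sel", "resname ACC"),
    pi_stacking = c("--project", pim, "--sel", "resname PHE"),
    salt_bridge = c("--project", slm),
    water_bridge = c("--project", wbm, "--sel-a", "resname GRA",
                     "--sel-b", "resname GRB"),
    covariance = c("--project", hel, "--sel", "protein"),
    msd_solution = c("--project", walk, "--sel", "resname WLK")
  )
}
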