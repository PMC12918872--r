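test_that("project config loads, defaults, and override precedence", {
  td <- withr::local_tempdir()
  build_fixture("bilayer", out_dir = td, seed = 1, nx = 2, ny = 2, n_frames = 2)
  cfg <- file.path(td, "project.json")
  full <- list(structure_path = file.path(td, "structure.pdb"),
               trajectory_pattern = file.path(td, "traj.dcd"),
               output_dir = file.path(td, "out"), time_step = 2.0)
  jsonlite::write_json(full, cfg, auto_unbox = TRUE)

  st <- load_project_config(cfg)
  expect_identical(st$structure_path, full$structure_path)
  expect_equal(st$time_step, 2)

  ## optional time_step absent -> frames carry NA times
  jsonlite::write_json(full[names(full) != "time_step"], cfg, auto_unbox = TRUE)
  st2 <- load_project_config(cfg)
  expect_null(st2$time_step)
  at <- read_pdb(st2$structure_path)$atoms
  expect_true(all(is.na(vapply(iterate_frames(st2, at),
                               function(fr) fr$time, numeric(1)))))

  ## explicit override wins over the file value
  other <- file.path(td, "other_out")
  st3 <- load_project_config(cfg, overrides = list(output_dir = other))
  expect_identical(st3$output_dir, other)

  ## unknown key warns, missing required key errors, missing file errors
  jsonlite::write_json(c(full, list(bogus_key = 1)), cfg, auto_unbox = TRUE)
  expect_warning(load_project_config(cfg), "bogus_key")
  jsonlite::write_json(full[-1], cfg, auto_unbox = TRUE)
  expect_error(load_project_config(cfg), "structure_path")
  expect_error(load_project_config(file.path(td, "nope.json")), "no project config")
})

test_that("trajectory resolution uses multi-integer natural order", {
  td <- withr::local_tempdir()
  names <- c("a1b2.dcd", "a1b10.dcd", "a2b1.dcd", "t10.dcd", "t2.dcd", "x.dcd")
  for (nm in names) writeLines("x", file.path(td, nm))
  got <- resolve_trajectory_files(file.path(td, "*.dcd"))
  expect_identical(basename(got), natural_sort_oracle(names))
  expect_identical(natural_sort(c("t10.dcd", "t2.dcd")), c("t2.dcd", "t10.dcd"))
  expect_identical(natural_sort("only.dcd"), "only.dcd")
  expect_error(resolve_trajectory_files(file.path(td, "*.xtz")),
               "no trajectory files")

  ## property: agrees with the hand oracle on random names
  set.seed(11)
  for (i in 1:20) {
    rand <- paste0(sample(c("run", "seg", "t"), 8, TRUE),
                   sample(c(1:12, 90:110), 8, TRUE), ".dcd")
    expect_identical(natural_sort(rand), natural_sort_oracle(rand))
  }
})

test_that("frame iteration concatenates files and honors the half-open window", {
  td <- withr::local_tempdir()
  fx1 <- build_fixture("bilayer", out_dir = td, seed = 1, nx = 2, ny = 2, n_frames = 5)
  file.rename(file.path(td, "traj.dcd"), file.path(td, "part1.dcd"))
  build_fixture("bilayer", out_dir = td, seed = 2, nx = 2, ny = 2, n_frames = 5,
                jitter = 0.1)
  file.rename(file.path(td, "traj.dcd"), file.path(td, "part2.dcd"))
  st <- project_settings(list(structure_path = file.path(td, "structure.pdb"),
                              trajectory_pattern = file.path(td, "part*.dcd"),
                              output_dir = td))
  at <- read_pdb(st$structure_path)$atoms

  fr <- iterate_frames(st, at)
  expect_identical(vapply(fr, function(x) x$index, integer(1)), 0:9)

  st$frame_start <- 2L; st$frame_stop <- 8L; st$frame_stride <- 3L
  fr2 <- iterate_frames(st, at)
  expect_identical(vapply(fr2, function(x) x$index, integer(1)), c(2L, 5L))

  st$frame_stride <- 0L
  expect_error(iterate_frames(st, at), "frame_stride")

  ## topology mismatch
  at_bad <- at[1:10, ]
  class(at_bad) <- class(at)
  st$frame_stride <- 1L
  expect_error(iterate_frames(st, at_bad), "topology mismatch")

  ## frame indices strictly increasing and reproducible
  fr3 <- iterate_frames(st, at)
  idx <- vapply(fr3, function(x) x$index, integer(1))
  expect_true(all(diff(idx) > 0))
  expect_identical(idx, vapply(iterate_frames(st, at),
                               function(x) x$index, integer(1)))
})

test_that("invocation records append, quote, and replay", {
  td <- withr::local_tempdir()
  rec1 <- record_invocation("system_size", c("--project", "p.json"), td)
  rec2 <- record_invocation("system_size", c("--out", "my out.tsv"), td)
  log <- readLines(file.path(td, "commands.log"))
  expect_length(log, 2L)
  expect_match(log[2], "'my out.tsv'", fixed = TRUE)
  ## quoting round-trips through the splitter
  expect_identical(simtraj:::shell_split(rec2$line),
                   c("simtraj", "system_size", "--out", "my out.tsv"))
  expect_identical(simtraj:::shell_split(rec1$line),
                   c("simtraj", "system_size", "--project", "p.json"))
})

test_that("TSV tables round-trip with a # header", {
  td <- withr::local_tempdir()
  df <- data.frame(frame = 0:2, value = c(1.5, 2.25, 3.125))
  p <- file.path(td, "t.tsv")
  write_tsv_table(df, p)
  expect_identical(substr(readLines(p, n = 1L), 1, 1), "#")
  back <- read_tsv_table(p)
  expect_equal(back, df)
})
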