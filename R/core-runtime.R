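## Project configuration, trajectory cataloging, frame iteration, and the
## reproducibility log.

.settings_keys <- c("structure_path", "trajectory_pattern", "output_dir",
                    "time_step", "frame_start", "frame_stop", "frame_stride")

#' Load a project configuration file
#'
#' The project file is flat JSON holding the keys of the project settings:
#' `structure_path`, `trajectory_pattern`, `output_dir` (required) and
#' `time_step` (ps per frame), `frame_start`, `frame_stop`, `frame_stride`
#' (optional).  Explicit overrides (e.g. from command-line options) win
#' over file values.  Unknown keys warn but do not fail.
#'
#' @param path path to the JSON project file.
#' @param overrides named list of values that take precedence.
#' @return a `project_settings` list.
#' @export
load_project_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("no project config: ", path)
  cfg <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stop("project config syntax error in ",
                                           path, ": ", conditionMessage(e)))
  unknown <- setdiff(names(cfg), .settings_keys)
  if (length(unknown) > 0L) {
    warning("ignoring unknown project config key(s): ",
            paste(unknown, collapse = ", "))
  }
  cfg <- cfg[intersect(names(cfg), .settings_keys)]
  for (k in names(overrides)) if (!is.null(overrides[[k]])) cfg[[k]] <- overrides[[k]]
  project_settings(cfg)
}

#' Validate project settings
#'
#' @param cfg named list of settings values.
#' @return validated `project_settings` list.
#' @export
project_settings <- function(cfg) {
  for (k in c("structure_path", "trajectory_pattern", "output_dir")) {
    if (is.null(cfg[[k]])) stop("missing required project config key: ", k)
  }
  if (!file.exists(cfg$structure_path)) {
    stop("structure file does not exist: ", cfg$structure_path)
  }
  if (length(Sys.glob(cfg$trajectory_pattern)) == 0L) {
    stop("no trajectory files match pattern: ", cfg$trajectory_pattern)
  }
  if (!is.null(cfg$time_step) && cfg$time_step <= 0) stop("time_step must be > 0")
  if (!is.null(cfg$frame_stride) && cfg$frame_stride < 1) {
    stop("frame_stride must be >= 1")
  }
  structure(cfg, class = "project_settings")
}

#' Natural-order sort of file paths
#'
#' Embedded integers compare numerically (run2 before run10), segment by
#' segment; ties fall back to lexicographic order.
#'
#' @param paths character vector.
#' @return sorted character vector.
#' @export
natural_sort <- function(paths) {
  if (length(paths) <= 1L) return(paths)
  keys <- lapply(paths, function(p) {
    regmatches(p, gregexpr("[0-9]+|[^0-9]+", p))[[1]]
  })
  ## zero-pad every integer run so lexicographic order equals numeric order
  pad <- vapply(keys, function(k) {
    padded <- vapply(k, function(s) {
      if (grepl("^[0-9]+$", s)) {
        s <- sub("^0+(?=[0-9])", "", s, perl = TRUE)
        paste0(strrep("0", max(0L, 30L - nchar(s))), s)
      } else s
    }, character(1))
    paste(padded, collapse = "\001")
  }, character(1))
  paths[order(pad, paths, method = "radix")]
}

#' Resolve a trajectory glob pattern to an ordered file list
#'
#' @param pattern glob pattern (e.g. `"traj/run*.dcd"`).
#' @return character vector of paths in natural order.
#' @export
resolve_trajectory_files <- function(pattern) {
  if (is.null(pattern) || !nzchar(pattern)) stop("empty trajectory pattern")
  files <- Sys.glob(pattern)
  if (length(files) == 0L) stop("no trajectory files match pattern: ", pattern)
  natural_sort(files)
}

read_trajectory_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "dcd") {
    read_dcd(path)
  } else if (ext %in% c("pdb", "ent")) {
    read_pdb(path)$frames
  } else {
    stop("unsupported trajectory format: ", path)
  }
}

#' Iterate trajectory frames
#'
#' Reads every file matched by the trajectory pattern (natural order),
#' concatenates them with a continuous global 0-based frame index, and
#' applies the half-open `[frame_start, frame_stop)` window with
#' `frame_stride`.  Frame times are `index * time_step` when a time step
#' is configured.
#'
#' @param settings a `project_settings` object.
#' @param atoms the [atom_table()]; atom counts are validated per file.
#' @return list of frames.
#' @export
iterate_frames <- function(settings, atoms) {
  stride <- settings$frame_stride %||% 1L
  if (stride < 1L) stop("frame_stride must be >= 1")
  start <- settings$frame_start %||% 0L
  files <- resolve_trajectory_files(settings$trajectory_pattern)
  frames <- list()
  gidx <- 0L
  for (f in files) {
    fr <- read_trajectory_file(f)
    for (x in fr) {
      if (nrow(x$coords) != nrow(atoms)) {
        stop("topology mismatch: ", f, " has ", nrow(x$coords),
             " atoms, structure has ", nrow(atoms))
      }
      x$index <- gidx
      frames[[length(frames) + 1L]] <- x
      gidx <- gidx + 1L
    }
  }
  stop_ <- settings$frame_stop %||% gidx
  keep <- seq(from = start, to = gidx - 1L)
  keep <- keep[keep < stop_ & (keep - start) %% stride == 0L]
  frames <- frames[keep + 1L]
  if (!is.null(settings$time_step)) {
    frames <- lapply(frames, function(x) {
      x$time <- x$index * settings$time_step
      x
    })
  }
  frames
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quote a command-line argument for the reproducibility log
#' @keywords internal
shell_quote <- function(x) {
  vapply(x, function(s) {
    if (grepl("[^A-Za-z0-9_./:=@+-]", s) || !nzchar(s)) {
      paste0("'", gsub("'", "'\\\\''", s), "'")
    } else s
  }, character(1), USE.NAMES = FALSE)
}

#' Split a logged command line back into arguments
#' @keywords internal
shell_split <- function(line) {
  out <- character(0)
  i <- 1L; n <- nchar(line); cur <- ""; have <- FALSE
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch == " ") {
      if (have) { out <- c(out, cur); cur <- ""; have <- FALSE }
    } else if (ch == "'") {
      j <- i + 1L
      while (j <= n && substr(line, j, j) != "'") j <- j + 1L
      cur <- paste0(cur, substr(line, i + 1L, j - 1L)); have <- TRUE
      ## handle the '\'' escape produced by shell_quote
      if (substr(line, j + 1L, j + 2L) == "\\'") {
        cur <- paste0(cur, "'"); j <- j + 2L
      }
      i <- j
    } else {
      cur <- paste0(cur, ch); have <- TRUE
    }
    i <- i + 1L
  }
  if (have) out <- c(out, cur)
  out
}

#' Record an analysis invocation
#'
#' Appends one shell-quoted, replayable command line to `commands.log` in
#' the output directory.  The file is append-only so the log accumulates a
#' complete history of how every output in the directory was produced.
#'
#' @param name analysis name.
#' @param argv character vector of arguments as invoked.
#' @param out_dir output directory (must be writable).
#' @return a `command_record` list (`analysis`, `argv`, `timestamp`,
#'   `line`, `log_path`), invisibly.
#' @export
record_invocation <- function(name, argv, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  if (file.access(out_dir, 2L) != 0L) stop("output directory not writable: ", out_dir)
  line <- paste(shell_quote(c("simtraj", name, argv)), collapse = " ")
  log_path <- file.path(out_dir, "commands.log")
  cat(line, "\n", sep = "", file = log_path, append = TRUE)
  invisible(structure(list(analysis = name, argv = argv,
                           timestamp = Sys.time(), line = line,
                           log_path = log_path),
                      class = "command_record"))
}
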