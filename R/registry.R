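## Analysis registry: every built-in analysis is an entry with a unique
## name, an option schema (name -> default; NA means required), and a
## unary main(settings) entry point.  The CLI and the reproducibility log
## are driven entirely by this table.

an_option <- function(default, type, help = "") {
  list(default = default, type = type, help = help)
}

## load atoms + frames for an analysis invocation
analysis_context <- function(settings) {
  prj <- settings[["project"]]
  for (k in c("frame_start", "frame_stop", "frame_stride")) {
    if (!is.null(settings[[k]])) prj[[k]] <- settings[[k]]
  }
  atoms <- read_pdb(prj$structure_path)$atoms
  frames <- iterate_frames(prj, atoms)
  out_dir <- prj$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  list(atoms = atoms, frames = frames, out_dir = out_dir, project = prj)
}

out_path <- function(ctx, settings, default_name) {
  p <- settings[["out"]] %||% default_name
  if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(ctx$out_dir, p)
  p
}

split_groups <- function(s) trimws(strsplit(s, ";", fixed = TRUE)[[1]])

scd_chain_spec <- function(settings) {
  carbons <- trimws(strsplit(settings[["carbons"]], ",", fixed = TRUE)[[1]])
  hydrogens <- if (!is.null(settings[["hydrogens"]]) && nzchar(settings[["hydrogens"]])) {
    lapply(split_groups(settings[["hydrogens"]]), function(g) {
      trimws(strsplit(g, ",", fixed = TRUE)[[1]])
    })
  } else {
    ## derive from carbon names: C<k> -> H<k>A, H<k>B
    lapply(carbons, function(cn) {
      k <- sub("^[A-Za-z]+", "", cn)
      paste0("H", k, c("A", "B"))
    })
  }
  list(carbons = carbons, hydrogens = hydrogens, chain = settings[["chain"]] %||% "sn-1")
}

common_options <- function() {
  list(sel = an_option("protein", "character", "atom selection"),
       out = an_option(NULL, "character", "output file"),
       frame_start = an_option(NULL, "integer", "first frame (0-based)"),
       frame_stop = an_option(NULL, "integer", "stop frame (exclusive)"),
       frame_stride = an_option(NULL, "integer", "frame stride"))
}

build_registry <- function() {
  reg <- list()
  add <- function(name, category, options, main) {
    if (!is.null(reg[[name]])) stop("duplicate analysis name: ", name)
    reg[[name]] <<- list(name = name, category = category,
                         options = c(common_options(), options), main = main)
  }

  ## -- Membrane ------------------------------------------------------
  add("sterol_tilt", "Membrane",
      list(tail_atom = an_option("ST1", "character", "sterol tail atom name"),
           head_atom = an_option("ST2", "character", "sterol head atom name"),
           bin_width = an_option(2, "numeric", "histogram bin (deg)")),
      function(settings) {
        ctx <- analysis_context(settings)
        res <- sterol_tilt(ctx$frames, c(settings[["tail_atom"]], settings[["head_atom"]]),
                           settings[["sel"]], ctx$atoms, settings[["bin_width"]])
        p1 <- out_path(ctx, settings, "sterol_tilt.tsv")
        p2 <- sub("\\.tsv$", "_hist.tsv", p1)
        write_tsv_table(res$series, p1)
        write_tsv_table(res$histogram, p2)
        c(p1, p2)
      })
  add("z_density", "Membrane",
      list(bin_width = an_option(1, "numeric", "bin width (A)"),
           mode = an_option("number", "character", "number|mass|electron"),
           center = an_option(NULL, "character", "midplane selection")),
      function(settings) {
        ctx <- analysis_context(settings)
        df <- z_density_profile(ctx$frames, list(sel = settings[["sel"]]), ctx$atoms,
                                settings[["bin_width"]], settings[["mode"]],
                                center_sel = settings[["center"]])
        p <- out_path(ctx, settings, "z_density.tsv")
        write_tsv_table(df, p)
        p
      })
  add("msd_membrane", "Membrane",
      list(subtract_com = an_option(FALSE, "logical", "remove drift")),
      function(settings) {
        ctx <- analysis_context(settings)
        df <- lateral_msd(ctx$frames, settings[["sel"]], ctx$atoms,
                          subtract_com = settings[["subtract_com"]])
        p <- out_path(ctx, settings, "msd_membrane.tsv")
        write_tsv_table(df, p)
        p
      })
  add("scd", "Membrane",
      list(carbons = an_option("C2,C3,C4,C5,C6", "character", "chain carbons"),
           hydrogens = an_option(NULL, "character",
                                 "semicolon-separated H names per carbon"),
           chain = an_option("sn-1", "character", "chain label")),
      function(settings) {
        ctx <- analysis_context(settings)
        df <- scd_profile(ctx$frames, scd_chain_spec(settings), settings[["sel"]],
                          ctx$atoms)
        p <- out_path(ctx, settings, "scd.tsv")
        write_tsv_table(df, p)
        p
      })
  add("thickness", "Membrane", list(),
      function(settings) {
        ctx <- analysis_context(settings)
        df <- membrane_thickness(ctx$frames, settings[["sel"]], ctx$atoms)
        p <- out_path(ctx, settings, "thickness.tsv")
        write_tsv_table(df, p)
        p
      })
  add("apl", "Membrane", list(),
      function(settings) {
        ctx <- analysis_context(settings)
        df <- area_per_lipid(ctx$frames, settings[["sel"]], ctx$atoms)
        p <- out_path(ctx, settings, "apl.tsv")
        write_tsv_table(df, p)
        p
      })
  add("shell_composition", "Membrane",
      list(center_type = an_option(NA_character_, "character", "central lipid type"),
           n_shells = an_option(1L, "integer", "number of shells")),
      function(settings) {
        ctx <- analysis_context(settings)
        df <- shell_composition(ctx$frames, settings[["sel"]], settings[["center_type"]],
                                ctx$atoms, settings[["n_shells"]])
        p <- out_path(ctx, settings, "shell_composition.tsv")
        write_tsv_table(df, p)
        p
      })
  add("area_compressibility", "Membrane",
      list(temperature = an_option(303.15, "numeric", "temperature (K)")),
      function(settings) {
        ctx <- analysis_context(settings)
        areas <- vapply(ctx$frames, function(fr) fr$box[1] * fr$box[2], numeric(1))
        res <- area_compressibility(areas, settings[["temperature"]])
        p <- out_path(ctx, settings, "area_compressibility.tsv")
        write_tsv_table(data.frame(ka_mN_per_m = res$ka, mean_area = res$mean_area,
                                   var_area = res$var_area, ka_se = res$ka_se), p)
        p
      })
  add("position", "Membrane",
      list(groups = an_option(NULL, "character",
                              "semicolon-separated selections (default: sel)")),
      function(settings) {
        ctx <- analysis_context(settings)
        sels <- if (!is.null(settings[["groups"]])) as.list(split_groups(settings[["groups"]]))
                else list(settings[["sel"]])
        names(sels) <- paste0("group", seq_along(sels))
        df <- position_timeseries(ctx$frames, sels, ctx$atoms)
        p <- out_path(ctx, settings, "position.tsv")
        write_tsv_table(df, p)
        p
      })

  ## -- System Dimensions ---------------------------------------------
  add("system_size", "System Dimensions", list(),
      function(settings) {
        ctx <- analysis_context(settings)
        p <- out_path(ctx, settings, "system_size.tsv")
        write_tsv_table(system_size(ctx$frames), p)
        p
      })

  ## -- Proteins and Nucleic Acids ------------------------------------
  add("secondary_structure", "Proteins and Nucleic Acids", list(),
      function(settings) {
        ctx <- analysis_context(settings)
        ss <- lapply(ctx$frames, dssp_assign, atoms = ctx$atoms)
        p <- out_path(ctx, settings, "secondary_structure.tsv")
        write_tsv_table(data.frame(
          frame = vapply(ctx$frames, function(fr) fr$index, integer(1)),
          ss = vapply(ss, function(s) s$string, character(1))), p)
        p2 <- sub("\\.tsv$", "_residues.tsv", p)
        long <- do.call(rbind, lapply(seq_along(ss), function(i) {
          data.frame(frame = ctx$frames[[i]]$index, segid = ss[[i]]$segid,
                     resid = ss[[i]]$resid, code = ss[[i]]$codes)
        }))
        write_tsv_table(long, p2)
        c(p, p2)
      })
  add("pore_radius", "Proteins and Nucleic Acids",
      list(bin_width = an_option(1, "numeric", "z bin width (A)")),
      function(settings) {
        ctx <- analysis_context(settings)
        df <- pore_radius_profile(ctx$frames, settings[["sel"]], ctx$atoms,
                                  settings[["bin_width"]])
        p <- out_path(ctx, settings, "pore_radius.tsv")
        write_tsv_table(df, p)
        p
      })
  add("rmsd", "Proteins and Nucleic Acids",
      list(fit = an_option(TRUE, "logical", "superpose before RMSD"),
           reference = an_option(0L, "integer", "reference frame index")),
      function(settings) {
        ctx <- analysis_context(settings)
        df <- rmsd_series(ctx$frames, settings[["sel"]], settings[["reference"]],
                          ctx$atoms, fit = settings[["fit"]])
        p <- out_path(ctx, settings, "rmsd.tsv")
        write_tsv_table(df, p)
        p
      })
  add("rmsf", "Proteins and Nucleic Acids", list(),
      function(settings) {
        ctx <- analysis_context(settings)
        df <- rmsf_per_residue(ctx$frames, settings[["sel"]], ctx$atoms)
        p <- out_path(ctx, settings, "rmsf.tsv")
        write_tsv_table(df, p)
        p
      })

  ## -- Geometry ------------------------------------------------------
  add("bond_statistics", "Geometry",
      list(groups = an_option(NA_character_, "character",
                              "2-4 semicolon-separated selections")),
      function(settings) {
        ctx <- analysis_context(settings)
        res <- bond_statistics(ctx$frames, as.list(split_groups(settings[["groups"]])),
                               ctx$atoms)
        p <- out_path(ctx, settings, "bond_statistics.tsv")
        write_tsv_table(res$series, p)
        p2 <- sub("\\.tsv$", "_summary.tsv", p)
        write_tsv_table(data.frame(mean = res$mean, sd = res$sd), p2)
        c(p, p2)
      })

  ## -- Contacts ------------------------------------------------------
  add("residence_time", "Contacts",
      list(sel_a = an_option(NA_character_, "character", "side A selection"),
           sel_b = an_option(NA_character_, "character", "side B selection"),
           cutoff = an_option(4.5, "numeric", "contact cutoff (A)"),
           gap_tolerance = an_option(0L, "integer", "merge gaps <= k frames")),
      function(settings) {
        ctx <- analysis_context(settings)
        rc <- residue_contacts(ctx$frames, settings[["sel_a"]], settings[["sel_b"]],
                               ctx$atoms, settings[["cutoff"]])
        series <- attr(rc, "series")
        if (settings[["gap_tolerance"]] > 0L) {
          series <- lapply(series, bridge_contact_gaps,
                           gap_tolerance = settings[["gap_tolerance"]])
        }
        rt <- contact_residence_time(series)
        parts <- strsplit(rt$pair, "|", fixed = TRUE)
        rt$resA <- vapply(parts, `[`, "", 1L)
        rt$resB <- vapply(parts, `[`, "", 2L)
        p <- out_path(ctx, settings, "residence_time.tsv")
        write_tsv_table(rt[, c("resA", "resB", "n_events", "mean_frames",
                               "sd_frames", "total_frames")], p)
        p
      })
  add("residue_contacts", "Contacts",
      list(sel_a = an_option(NA_character_, "character", "side A selection"),
           sel_b = an_option(NA_character_, "character", "side B selection"),
           cutoff = an_option(4.5, "numeric", "contact cutoff (A)")),
      function(settings) {
        ctx <- analysis_context(settings)
        df <- residue_contacts(ctx$frames, settings[["sel_a"]], settings[["sel_b"]],
                               ctx$atoms, settings[["cutoff"]])
        p <- out_path(ctx, settings, "residue_contacts.tsv")
        write_tsv_table(df, p)
        p
      })
  add("rdf", "Contacts",
      list(sel_a = an_option(NA_character_, "character", "selection A"),
           sel_b = an_option(NA_character_, "character", "selection B"),
           bin_width = an_option(0.1, "numeric", "bin width (A)"),
           r_max = an_option(NULL, "numeric", "max distance (A)")),
      function(settings) {
        ctx <- analysis_context(settings)
        df <- radial_distribution(ctx$frames, settings[["sel_a"]], settings[["sel_b"]],
                                  ctx$atoms, settings[["bin_width"]], settings[["r_max"]])
        p <- out_path(ctx, settings, "rdf.tsv")
        write_tsv_table(df, p)
        p
      })

  ## -- Non-bond Interactions -----------------------------------------
  add("hbond", "Non-bond Interactions",
      list(donor_sel = an_option(NA_character_, "character", "donor selection"),
           acceptor_sel = an_option(NA_character_, "character", "acceptor selection"),
           d_cut = an_option(3.5, "numeric", "D-A distance cutoff (A)"),
           angle_cut = an_option(150, "numeric", "D-H-A angle cutoff (deg)")),
      function(settings) {
        ctx <- analysis_context(settings)
        df <- hydrogen_bonds(ctx$frames, settings[["donor_sel"]],
                             settings[["acceptor_sel"]], ctx$atoms,
                             settings[["d_cut"]], settings[["angle_cut"]])
        p <- out_path(ctx, settings, "hbond.tsv")
        write_tsv_table(df, p)
        p
      })
  add("pi_stacking", "Non-bond Interactions",
      list(centroid_cut = an_option(6.0, "numeric", "centroid cutoff (A)")),
      function(settings) {
        ctx <- analysis_context(settings)
        df <- pi_stacking(ctx$frames, ctx$atoms, settings[["centroid_cut"]],
                          sel = settings[["sel"]])
        p <- out_path(ctx, settings, "pi_stacking.tsv")
        write_tsv_table(df, p)
        p
      })
  add("salt_bridge", "Non-bond Interactions",
      list(d_cut = an_option(4.0, "numeric", "N-O distance cutoff (A)")),
      function(settings) {
        ctx <- analysis_context(settings)
        df <- salt_bridges(ctx$frames, ctx$atoms, settings[["d_cut"]],
                           sel = settings[["sel"]])
        p <- out_path(ctx, settings, "salt_bridge.tsv")
        write_tsv_table(df, p)
        p
      })
  add("water_bridge", "Non-bond Interactions",
      list(sel_a = an_option(NA_character_, "character", "side A selection"),
           sel_b = an_option(NA_character_, "character", "side B selection"),
           d_cut = an_option(3.5, "numeric", "H-bond distance cutoff (A)"),
           angle_cut = an_option(150, "numeric", "H-bond angle cutoff (deg)")),
      function(settings) {
        ctx <- analysis_context(settings)
        df <- water_bridges(ctx$frames, settings[["sel_a"]], settings[["sel_b"]],
                            ctx$atoms, settings[["d_cut"]], settings[["angle_cut"]])
        p <- out_path(ctx, settings, "water_bridge.tsv")
        write_tsv_table(df, p)
        p
      })

  ## -- Others --------------------------------------------------------
  add("covariance", "Others",
      list(fit = an_option(TRUE, "logical", "superpose before covariance")),
      function(settings) {
        ctx <- analysis_context(settings)
        res <- covariance_analysis(ctx$frames, settings[["sel"]], ctx$atoms,
                                   fit = settings[["fit"]])
        p <- out_path(ctx, settings, "covariance.tsv")
        write_tsv_table(data.frame(mode = seq_along(res$eigenvalues),
                                   eigenvalue = res$eigenvalues), p)
        p
      })
  add("msd_solution", "Others",
      list(fit_lo = an_option(0.2, "numeric", "fit window start fraction"),
           fit_hi = an_option(0.8, "numeric", "fit window end fraction")),
      function(settings) {
        ctx <- analysis_context(settings)
        res <- solution_msd(ctx$frames, settings[["sel"]], ctx$atoms,
                            fit_window = c(settings[["fit_lo"]], settings[["fit_hi"]]),
                            time_step = ctx$project$time_step %||% 1)
        p <- out_path(ctx, settings, "msd_solution.tsv")
        write_tsv_table(res$msd, p)
        p2 <- sub("\\.tsv$", "_diffusion.tsv", p)
        write_tsv_table(data.frame(D_A2_per_ps = res$D, D_cm2_per_s = res$D_cm2_s), p2)
        c(p, p2)
      })

  reg
}

.registry_cache <- new.env(parent = emptyenv())

#' The built-in analysis registry
#'
#' @return named list of analysis specs, each with `name`, `category`,
#'   `options` (schema of defaults), and `main` (unary entry point taking
#'   a settings list).
#' @export
discover_analyses <- function() {
  if (is.null(.registry_cache$reg)) .registry_cache$reg <- build_registry()
  .registry_cache$reg
}

#' Look up one analysis by name
#' @param name analysis name.
#' @return the analysis spec.
#' @export
get_analysis <- function(name) {
  reg <- discover_analyses()
  if (is.null(reg[[name]])) {
    stop("unknown analysis '", name, "'; valid names: ",
         paste(names(reg), collapse = ", "))
  }
  reg[[name]]
}

#' Run a registered analysis
#'
#' Fills unset options with their schema defaults, checks required
#' options, executes the entry point, and returns the written file paths.
#'
#' @param name analysis name.
#' @param settings list with `project` (a `project_settings`) plus options.
#' @return character vector of output paths, invisibly.
#' @export
run_analysis <- function(name, settings) {
  spec <- get_analysis(name)
  if (is.null(settings[["project"]])) stop("settings$project is required")
  for (opt in names(spec$options)) {
    if (is.null(settings[[opt]])) settings[[opt]] <- spec$options[[opt]]$default
    if (length(settings[[opt]]) == 1L && is.na(settings[[opt]]) &&
        length(spec$options[[opt]]$default) == 1L &&
        is.na(spec$options[[opt]]$default)) {
      stop("analysis '", name, "' requires option --",
           gsub("_", "-", opt))
    }
  }
  invisible(spec$main(settings))
}
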