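default_config <- function() {
  list(
    fel = list(bin_size = 0.3, temperature = 300, min_count = 5,
               merge_radius = 0.6),
    thresholds = list(cap_open = 10, adomet_open = 11,
                      closed_cv1 = 9, closed_cv2 = 10),
    network = list(cutoff = 4.5, occupancy = 0.75, exclusion = 1),
    pocket = list(iterations = 10000, r_min = 3, r_max = 6, spacing = 1,
                  n_reference = 2000)
  )
}

known_keys <- list(
  top = c("seed", "output_dir", "stages", "cv_model", "fel", "thresholds",
          "beads", "network", "cavity", "pocket", "amd"),
  fel = c("bin_size", "temperature", "min_count", "merge_radius"),
  thresholds = c("cap_open", "adomet_open", "closed_cv1", "closed_cv2"),
  network = c("cutoff", "occupancy", "exclusion"),
  pocket = c("iterations", "r_min", "r_max", "spacing", "n_reference"),
  cv_model = c("states", "switch_prob", "n_samples"),
  beads = c("blocks", "rho", "n_frames", "contacts", "spacing", "fluct_sd"),
  cavity = c("radius", "bead_radius"),
  amd = c("mode", "E_P", "alpha_P", "E_D", "alpha_D", "potential", "langevin")
)

#' Validate and normalise a pipeline configuration
#'
#' Reads a YAML file (or accepts a list), checks keys and ranges, and fills
#' defaults: 0.3 A landscape bins at 300 K, 4.5 A / 75% contact criteria,
#' 10 000 Monte-Carlo iterations with 3-6 A probe radii and 2000 reference
#' snapshots. A global `seed` is mandatory. All detected problems are
#' reported together.
#'
#' @param config Path to a YAML file, or a named list.
#' @return The normalised configuration (class `run_config`).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_config(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_config("config must be a YAML file or a list.")
  problems <- character(0)
  unknown <- setdiff(names(config), known_keys$top)
  if (length(unknown) > 0) {
    problems <- c(problems, sprintf("unknown key(s): %s",
                                    paste(unknown, collapse = ", ")))
  }
  for (sec in intersect(names(config), names(known_keys)[-1])) {
    bad <- setdiff(names(config[[sec]]), known_keys[[sec]])
    if (length(bad) > 0) {
      problems <- c(problems, sprintf("unknown key(s) in %s: %s", sec,
                                      paste(bad, collapse = ", ")))
    }
  }
  if (is.null(config$seed)) {
    problems <- c(problems, "a global `seed` is required.")
  }
  cfg <- modifyList(default_config(), config)
  if (cfg$fel$bin_size <= 0) problems <- c(problems, "fel.bin_size must be > 0.")
  if (cfg$fel$temperature <= 0) problems <- c(problems, "fel.temperature must be > 0.")
  if (cfg$network$occupancy <= 0 || cfg$network$occupancy > 1) {
    problems <- c(problems, "network.occupancy must lie in (0, 1].")
  }
  if (cfg$network$cutoff <= 0) problems <- c(problems, "network.cutoff must be > 0.")
  if (cfg$pocket$iterations < 1000) {
    problems <- c(problems, "pocket.iterations must be >= 1000.")
  }
  if (!(cfg$pocket$r_min > 0 && cfg$pocket$r_min < cfg$pocket$r_max)) {
    problems <- c(problems, "pocket radii must satisfy 0 < r_min < r_max.")
  }
  if (length(problems) > 0) {
    stop_config(paste0("invalid configuration:\n  - ",
                       paste(problems, collapse = "\n  - ")))
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = c("run_config", "list"))
}

write_tsv_units <- function(df, path, units) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units: %s", units), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

stage_record <- function(status, seconds, outputs = character(0),
                         detail = NULL) {
  out <- list(status = status, seconds = round(seconds, 3),
              outputs = as.list(outputs))
  if (!is.null(detail)) out$detail <- detail
  out
}

#' Run the configured analysis pipeline
#'
#' Executes the requested stages in dependency order -- synthetic generation,
#' landscape/state analysis, network/community analysis, pocket volumes and
#' the toy boosted-dynamics run -- writing TSV/JSON artifacts plus a
#' machine-readable manifest (`manifest.json`) with the config hash, per-file
#' md5 sums and per-stage wall time. All randomness derives from the global
#' seed through fixed per-stage offsets. A failing stage is recorded in the
#' manifest (status `"failed"`) without discarding completed stages.
#'
#' @param config A [validate_config()] result, list, or YAML path.
#' @param output_dir Output directory (created if needed); overrides the
#'   config's `output_dir`.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  out_dir <- output_dir %||% cfg$output_dir %||% stop_config("no output_dir given.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- cfg$stages %||% c(
    if (!is.null(cfg$cv_model)) "fel",
    if (!is.null(cfg$beads)) "network",
    if (!is.null(cfg$cavity)) "pocket",
    if (!is.null(cfg$amd)) "amd"
  )
  manifest <- list(
    package_version = as.character(utils::packageVersion("allostera")),
    config_hash = rlang::hash(unclass(cfg)),
    seed = cfg$seed,
    stages = list()
  )
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) e)
    dt <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- stage_record("failed", dt,
                                               detail = conditionMessage(res))
    } else {
      sums <- as.list(tools::md5sum(res))
      names(sums) <- basename(res)
      manifest$stages[[name]] <<- stage_record("ok", dt, sums)
    }
  }

  if ("fel" %in% stages) run_stage("fel", function() {
    if (is.null(cfg$cv_model)) stop_config("fel stage needs a cv_model section.")
    states <- bind_rows(lapply(cfg$cv_model$states, as_tibble))
    model <- state_model(states, switch_prob = cfg$cv_model$switch_prob %||% 0.1)
    cv <- gen_cv_series(model, n = cfg$cv_model$n_samples %||% 100000,
                        seed = cfg$seed + 101L)
    th <- do.call(state_thresholds, cfg$thresholds)
    fel <- build_fel(cv, fel_spec(bin_size = cfg$fel$bin_size,
                                  temperature = cfg$fel$temperature,
                                  min_count = cfg$fel$min_count))
    minima <- find_minima(fel, merge_radius = cfg$fel$merge_radius,
                          thresholds = th)
    cls <- classify_states(cv, th)
    f_cv <- file.path(out_dir, "cv_series.tsv")
    write_tsv_units(cv, f_cv, "frame: index; cv1, cv2: Angstrom; state: generator label")
    f_grid <- file.path(out_dir, "fel_grid.tsv")
    write_tsv_units(tidy(fel), f_grid,
                    "cv1, cv2: Angstrom (bin centres); F: kcal/mol; count: samples")
    f_meta <- file.path(out_dir, "fel_meta.json")
    jsonlite::write_json(list(
      spec = list(bin_size_A = cfg$fel$bin_size,
                  temperature_K = cfg$fel$temperature),
      minima = minima,
      state_fractions = state_fractions(cls)
    ), f_meta, auto_unbox = TRUE, digits = NA)
    c(f_cv, f_grid, f_meta)
  })

  if ("network" %in% stages) run_stage("network", function() {
    if (is.null(cfg$beads)) stop_config("network stage needs a beads section.")
    nb <- sum(lengths(cfg$beads$blocks))
    spacing <- cfg$beads$spacing %||% 8
    rest <- cbind(seq_len(nb) * spacing, 0, 0)
    contacts <- if (!is.null(cfg$beads$contacts)) {
      bind_rows(lapply(cfg$beads$contacts, as_tibble))
    } else NULL
    spec <- bead_system_spec(
      rest, lapply(cfg$beads$blocks, as.integer),
      rho = cfg$beads$rho %||% 0.9, contacts = contacts,
      n_frames = cfg$beads$n_frames %||% 1000, seed = cfg$seed + 202L,
      fluct_sd = cfg$beads$fluct_sd %||% 0.25)
    gen <- gen_bead_trajectory(spec)
    cc <- cross_correlation(gen$trajectory, superpose = FALSE)
    net <- contact_network(gen$trajectory,
                           contact_criteria(cfg$network$cutoff,
                                            cfg$network$occupancy,
                                            cfg$network$exclusion),
                           correlations = cc)
    part <- girvan_newman(net)
    cg <- community_graph(part, net)
    f_edges <- file.path(out_dir, "network_edges.tsv")
    write_tsv_units(tidy(net), f_edges,
                    "i, j: residue ids; occupancy: fraction; length: -log|C| (dimensionless)")
    f_part <- file.path(out_dir, "communities.json")
    jsonlite::write_json(list(
      membership = as.list(setNames(as.integer(part$membership),
                                    names(part$membership))),
      sizes = part$sizes, Q = part$Q,
      coarse_edges = cg$edges, ground_truth_blocks = gen$blocks
    ), f_part, auto_unbox = TRUE, digits = NA)
    c(f_edges, f_part)
  })

  if ("pocket" %in% stages) run_stage("pocket", function() {
    if (is.null(cfg$cavity)) stop_config("pocket stage needs a cavity section.")
    cav <- gen_cavity_system(cavity_spec(
      cavity_radius = cfg$cavity$radius,
      bead_radius = cfg$cavity$bead_radius %||% 1.7))
    ps <- pocket_spec(seed = cfg$seed + 303L,
                      iterations = cfg$pocket$iterations,
                      r_min = cfg$pocket$r_min, r_max = cfg$pocket$r_max,
                      spacing = cfg$pocket$spacing,
                      n_reference = cfg$pocket$n_reference)
    env <- build_reference_envelope(NULL, rbind(c(0, 0, 0)), ps)
    vs <- volume_series(cav$trajectory, env, ps)
    f_vol <- file.path(out_dir, "pocket_volumes.tsv")
    write_tsv_units(as_tibble(vs), f_vol, "frame: index; volume: Angstrom^3")
    f_sum <- file.path(out_dir, "pocket_summary.json")
    jsonlite::write_json(list(summary = glance(vs),
                              analytic_volume_A3 = cav$analytic_volume),
                         f_sum, auto_unbox = TRUE, digits = NA)
    c(f_vol, f_sum)
  })

  if ("amd" %in% stages) run_stage("amd", function() {
    if (is.null(cfg$amd)) stop_config("amd stage needs an amd section.")
    pot_cfg <- cfg$amd$potential %||% list(form = "double_well_1d", barrier = 4)
    pot <- do.call(make_potential, pot_cfg)
    lv <- cfg$amd$langevin %||% list()
    settings <- langevin_settings(
      timestep = lv$timestep %||% 0.005, n_steps = lv$n_steps %||% 50000,
      x0 = lv$x0 %||% if (pot$dim == 1) -1 else c(-1, 0),
      seed = cfg$seed + 404L)
    params <- if ((cfg$amd$mode %||% "none") == "none") {
      amd_params("none")
    } else {
      amd_params(cfg$amd$mode, E_P = cfg$amd$E_P, alpha_P = cfg$amd$alpha_P,
                 E_D = cfg$amd$E_D, alpha_D = cfg$amd$alpha_D)
    }
    rec <- run_langevin(pot, params, settings)
    prof <- reweight_profile(rec, breaks = 60)
    f_rec <- file.path(out_dir, "amd_records.tsv")
    write_tsv_units(rec, f_rec,
                    "step: index; x: Angstrom; V, V_D, dV: kcal/mol")
    f_prof <- file.path(out_dir, "amd_profile.tsv")
    write_tsv_units(prof, f_prof, "x: Angstrom; F: kcal/mol")
    c(f_rec, f_prof)
  })

  f_manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE, digits = NA)
  invisible(structure(manifest, class = "run_manifest"))
}
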