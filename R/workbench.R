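# Run configuration and pipeline orchestration.
#
# A run is described by a YAML/JSON config with a sample-composition
# block, input file paths, analysis options and a mandatory seed.  The
# pipeline executes the requested stages in dependency order
# (peaks -> phase -> density -> diff -> locate -> inplane), writes
# per-stage delimited-text outputs, and collects a single JSON summary.

#' Validate a run configuration
#'
#' Performs a full schema check and returns either the validated config
#' or the complete list of problems -- never a partially valid config.
#'
#' @param x Path to a YAML/JSON config file, or an already-parsed list.
#' @return List with `valid` (logical), `config` (the list, only when
#'   valid) and `errors` (character vector).
#' @export
validate_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  errors <- character()
  err <- function(...) errors <<- c(errors, paste0(...))
  if (!is.list(cfg)) {
    return(list(valid = FALSE, config = NULL,
                errors = "config must be a mapping"))
  }
  if (is.null(cfg$seed)) err("missing required field: seed")
  else if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))
    err("seed must be an integer")
  s <- cfg$sample
  if (is.null(s)) err("missing required block: sample")
  else {
    if (is.null(s$lipids) || !length(s$lipids))
      err("sample$lipids must name at least one lipid with its mole fraction")
    else {
      fr <- unlist(s$lipids)
      if (!is.numeric(fr)) err("sample$lipids fractions must be numeric")
      else if (abs(sum(fr) - 1) > 1e-9)
        err("lipid mole fractions must sum to 1 (got ",
            format(sum(fr), digits = 10), ")")
      reg <- default_species()
      user <- character()
      for (sp in s$species %||% list()) {
        if (is.null(sp$name) || is.null(sp$formula))
          err("each sample$species entry needs 'name' and 'formula'")
        else user <- c(user, sp$name)
      }
      for (nm in c(names(s$lipids), names(s$additives %||% list())))
        if (!nm %in% c(names(reg), user))
          err("unknown species '", nm,
              "' (not built-in; supply a formula under sample$species)")
    }
    if (!is.null(s$waters_per_lipid) &&
        (!is.numeric(s$waters_per_lipid) || s$waters_per_lipid < 0))
      err("sample$waters_per_lipid must be non-negative")
    if (is.null(s$area_per_lipid) || s$area_per_lipid <= 0)
      err("sample$area_per_lipid (A^2) is required and must be positive")
  }
  o <- cfg$options %||% list()
  if (!is.null(o$lorentz_exponent) &&
      !o$lorentz_exponent %in% c(0.5, 1))
    err("options$lorentz_exponent must be 0.5 or 1")
  if (!is.null(o$center_density) &&
      (o$center_density < 0.1 || o$center_density > 0.5))
    err("options$center_density outside the physical range 0.1-0.5 e/A^3")
  if (!is.null(o$k_components) &&
      (o$k_components < 1 || o$k_components > 6))
    err("options$k_components must be between 1 and 6")
  if (!is.null(o$signs) && !all(unlist(o$signs) %in% c(-1, 1)))
    err("options$signs must be a list of -1/+1")
  for (f in unlist(cfg$files %||% list()))
    if (!file.exists(f)) err("input file not found: ", f)
  if (length(errors)) list(valid = FALSE, config = NULL, errors = errors)
  else list(valid = TRUE, config = cfg, errors = character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a membrane_composition from the config sample block.
.config_composition <- function(cfg, d_spacing) {
  s <- cfg$sample
  reg <- default_species()
  for (sp in s$species %||% list())
    reg[[sp$name]] <- molecular_species(
      sp$name, sp$formula,
      molar_mass_override = sp$molar_mass %||% NULL)
  lipids <- lapply(names(s$lipids), function(nm)
    list(species = reg[[nm]], fraction = s$lipids[[nm]]))
  additives <- lapply(names(s$additives %||% list()), function(nm)
    list(species = reg[[nm]], ratio = s$additives[[nm]]))
  membrane_composition(lipids, additives,
                       waters_per_lipid = s$waters_per_lipid %||% 0,
                       area_per_lipid = s$area_per_lipid,
                       lamellar_spacing = d_spacing)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order and writes
#' per-stage outputs plus `summary.json` under `output_dir`.  Stages:
#' `peaks` (Bragg-series and chain-peak fits), `phase` (sign assignment
#' by swelling, or user-supplied signs), `density` (Fourier synthesis
#' and absolute scaling), `diff` (difference profile against a
#' reference profile plus component decomposition), `locate` (rigid-
#' body pose fit of a PDB structure), `inplane` (area per lipid,
#' lattice fit and plaque intensity change).  Re-running with identical
#' inputs and seed reproduces identical outputs.
#'
#' @param config Validated config list (or path; validated internally).
#' @param stages Character subset of
#'   `c("peaks","phase","density","diff","locate","inplane")`.
#' @param output_dir Output directory.
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("peaks", "phase", "density"),
                         output_dir = tempfile("memxrd_run_")) {
  v <- validate_config(config)
  if (!v$valid)
    stop("invalid config:\n  ", paste(v$errors, collapse = "\n  "))
  cfg <- v$config
  o <- cfg$options %||% list()
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- match.arg(stages,
                      c("peaks", "phase", "density", "diff", "locate",
                        "inplane"), several.ok = TRUE)
  order_all <- c("peaks", "phase", "density", "diff", "locate", "inplane")
  stages <- order_all[order_all %in% stages]
  summary <- list(seed = cfg$seed, warnings = character())
  note <- function(w) summary$warnings <<- c(summary$warnings, w)
  state <- list()

  with_notes <- function(expr) withCallingHandlers(expr, warning = function(w) {
    note(conditionMessage(w)); invokeRestart("muffleWarning")
  })

  for (st in stages) {
    if (st == "peaks") {
      if (is.null(cfg$files$reflectivity))
        stop("stage 'peaks' needs files$reflectivity")
      curve <- read_intensity_curve(cfg$files$reflectivity)
      pk <- with_notes(fit_bragg_series(curve,
                                        d_hint = o$d_hint %||% NULL,
                                        max_order = o$max_order %||% 10))
      if (!nrow(pk)) stop("stage 'peaks': no Bragg peaks found")
      d <- lamellar_spacing(pk)
      state$peaks <- pk; state$d <- d
      utils::write.table(format(as.data.frame(pk), digits = 8),
                         file.path(output_dir, "bragg_peaks.tsv"),
                         quote = FALSE, row.names = FALSE, sep = "\t")
      summary$d_spacing <- d
    } else if (st == "phase") {
      if (is.null(state$peaks))
        stop("stage 'phase' needs the output of stage 'peaks'")
      ff <- form_factor_magnitudes(state$peaks, state$d,
                                   o$lorentz_exponent %||% 0.5)
      if (!is.null(cfg$files$swelling)) {
        ffsets <- list(ff)
        for (p in cfg$files$swelling) {
          cv <- read_intensity_curve(p)
          pk2 <- with_notes(fit_bragg_series(cv,
                                             max_order = o$max_order %||% 10))
          ffsets[[length(ffsets) + 1L]] <-
            form_factor_magnitudes(pk2, lamellar_spacing(pk2),
                                   o$lorentz_exponent %||% 0.5)
        }
        sa <- with_notes(assign_signs(ffsets, reference = 1))
        state$ffset <- sa$ffset
        summary$signs <- sa$signs
        summary$sign_misfit <- sa$misfit
        if (sa$degenerate) note("sign assignment is degenerate")
      } else if (!is.null(o$signs)) {
        state$ffset <- apply_signs(ff, unlist(o$signs))
        summary$signs <- unlist(o$signs)
      } else {
        stop("stage 'phase' needs either files$swelling (>= 1 extra ",
             "hydration state) or options$signs")
      }
    } else if (st == "density") {
      if (is.null(state$ffset))
        stop("stage 'density' needs the output of stage 'phase'")
      prof <- fourier_synthesis(state$ffset, o$grid_points %||% 1024)
      comp <- .config_composition(cfg, state$d)
      budget <- leaflet_electron_budget(comp)
      abs_prof <- with_notes(scale_to_absolute(
        prof, budget, comp$area_per_lipid,
        center_density = o$center_density %||% 0.22))
      state$profile <- abs_prof
      write_density_profile(abs_prof,
                            file.path(output_dir, "density_profile.tsv"))
      lm <- with_notes(landmark_report(abs_prof))
      summary$budget <- budget
      summary$head_peak_z <- lm$head_peak_z
      summary$center_density <- lm$center_value
    } else if (st == "diff") {
      if (is.null(state$profile))
        stop("stage 'diff' needs the output of stage 'density'")
      if (is.null(cfg$files$reference_profile))
        stop("stage 'diff' needs files$reference_profile")
      ref <- read_density_profile(cfg$files$reference_profile)
      dp <- with_notes(difference_profile(state$profile, ref))
      cm <- fit_components(dp, k = o$k_components %||% 4,
                           A_L = cfg$sample$area_per_lipid)
      state$diff <- dp; state$components <- cm
      write_component_table(cm, file.path(output_dir, "components.tsv"))
      summary$components <- cm$components
      summary$fractions <- cm$components$fraction
      if (!is.null(o$boundary_z))
        summary$embedded_pct <- embedded_fraction(cm, o$boundary_z)
    } else if (st == "locate") {
      if (is.null(state$diff))
        stop("stage 'locate' needs the output of stage 'diff'")
      if (is.null(cfg$files$pdb)) stop("stage 'locate' needs files$pdb")
      mdl <- load_atomic_model(cfg$files$pdb)
      pf <- with_notes(fit_pose(
        mdl, state$diff, d_spacing = state$d,
        z_grid = seq(0, state$d / 4, by = o$pose_z_step %||% 0.5),
        angle_grid = seq(0, 345, by = o$pose_angle_step %||% 15)))
      summary$pose <- list(z_shift = pf$pose$z_shift,
                           angles = pf$pose$angles,
                           scale = pf$scale, score = pf$score,
                           degenerate = pf$degenerate)
    } else if (st == "inplane") {
      if (!is.null(cfg$files$inplane)) {
        cv <- read_intensity_curve(cfg$files$inplane,
                                   axis = "in_plane_qpar")
        cp <- chain_peak(cv)
        ap <- area_per_lipid_hex(cp$q_T)
        summary$q_T <- cp$q_T
        summary$a_T <- ap$a_T
        summary$A_L_chain <- ap$A_L
      }
      if (!is.null(cfg$files$peak_table_before) &&
          !is.null(cfg$files$peak_table_after)) {
        bt <- read_peak_table(cfg$files$peak_table_before)
        at <- read_peak_table(cfg$files$peak_table_after)
        ch <- plaque_intensity_change(bt, at)
        summary$plaque_change_pct <- ch$monoclinic_pct
        summary$chain_change_pct <- ch$chain_pct
        obs <- data.frame(h = c(1, 2), k = c(1, 0),
                          q = c(bt$position[.norm_label(bt$label) == "110"][1],
                                bt$position[.norm_label(bt$label) == "200"][1]))
        lat <- fit_lattice(obs, fixed = list(gamma = o$gamma %||% 103))
        summary$lattice <- unclass(lat)
      }
    }
  }
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(summary)
}
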