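#' Default run configuration
#'
#' A flat key-value configuration tying the stages together
#' (simulate -> trajectory analysis -> structure factor -> optional
#' comparison against measured curves). Physical defaults mirror the
#' coarse-grained model: 298 K, bead radius 2 A, r0 = 4.1 A, k = 0.4 N/m,
#' generic / sticky attraction 0.6e4 / 3.0e4 kJ A^6/mol, 150 mM ionic
#' strength, ten subdivisions.
#'
#' @param peptide Variant name (see [hst5_variants()]).
#' @param zinc Logical: implicit-zinc sticky interactions on?
#' @param concentration mg/mL (or give `n_chains`).
#' @param n_chains Optional explicit chain count.
#' @param box_length Box edge, A.
#' @param ionic_strength mM.
#' @param equilibration,production MC passes.
#' @param seed Integer seed.
#' @param q_grid q values for the structure factor (NULL for none).
#' @param frame_stride Frame sampling stride (0 disables frames and S(q)).
#' @param saxs_file Optional measured SAXS .dat to compare against (chi2).
#' @return A named list of class `"run_config"`.
#' @export
run_config <- function(peptide = "WT", zinc = TRUE, concentration = 1,
                       n_chains = NULL, box_length = 450,
                       ionic_strength = 150, equilibration = 2e4,
                       production = 1e5, seed = 1, q_grid = NULL,
                       frame_stride = 0, saxs_file = NULL) {
  cfg <- list(peptide = peptide, zinc = zinc, concentration = concentration,
              n_chains = n_chains, box_length = box_length,
              ionic_strength = ionic_strength,
              equilibration = equilibration, production = production,
              seed = seed, q_grid = q_grid, frame_stride = frame_stride,
              saxs_file = saxs_file)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$saxs_file) && !file.exists(vals$saxs_file)) {
    stop("referenced SAXS file does not exist: ", vals$saxs_file,
         call. = FALSE)
  }
  do.call(run_config, vals)
}

#' Run the simulate-and-analyse pipeline
#'
#' Builds the system, runs the Monte Carlo simulation, extracts
#' conformational and oligomer observables, optionally computes the Debye
#' structure factor from sampled frames and a chi-square comparison
#' against a measured curve, and (when `out_dir` is given) writes tidy CSV
#' results plus a JSON manifest recording parameters, seeds and a
#' configuration hash.
#'
#' @param config A `"run_config"` (or path to a YAML file).
#' @param out_dir Optional output directory.
#' @return A manifest list with elements `config`, `config_hash`,
#'   `observables` (tibble), `oligomers` (tibble), `acceptance`,
#'   `structure_factor` (tibble or NULL), `chi2` (or NULL), `files`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  pep <- build_peptide(config$peptide)
  params <- energy_params(ionic_strength = config$ionic_strength)
  if (config$box_length >= 200) {
    params$cutoff <- max(60, config$r0 %||% 4.1 + 12 / max(params$kappa, 1e-6))
  }
  sys <- build_system(pep, box_length = config$box_length,
                      concentration = if (is.null(config$n_chains)) config$concentration else NULL,
                      n_chains = config$n_chains,
                      zinc_present = config$zinc, seed = config$seed)
  run <- run_simulation(sys, params, mc_config(
    equilibration = config$equilibration, production = config$production,
    frame_stride = config$frame_stride, seed = config$seed
  ))
  olig <- oligomer_distribution(run)
  sq <- NULL
  if (!is.null(config$q_grid) && length(run$frames)) {
    sq <- structure_factor(run, q = config$q_grid)
  }
  chi2 <- NULL
  if (!is.null(config$saxs_file) && !is.null(sq)) {
    meas <- read_saxs_dat(config$saxs_file)
    sim_i <- stats::approx(sq$q, sq$s_total, xout = meas$q, rule = 2)$y
    i0_sim <- stats::approx(sq$q, sq$s_total, xout = min(meas$q), rule = 2)$y
    gf <- guinier_fit(meas)
    chi2 <- chi_square(meas$I, sim_i, scale = gf$i0 / i0_sim)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("histazinc")),
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    n_chains = sys$n_chains,
    acceptance = run$acceptance,
    observables = run$summary,
    oligomers = olig,
    n_ass = attr(olig, "n_ass"),
    structure_factor = sq,
    chi2 = chi2
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character()
    write_tagged_csv <- function(df, path) {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines(paste("# config:", manifest$config_hash), con)
      utils::write.csv(df, con, row.names = FALSE)
      path
    }
    obs_path <- write_tagged_csv(run$summary,
                                 file.path(out_dir, "observables.csv"))
    files <- c(files, obs_path)
    olig_path <- write_tagged_csv(as.data.frame(olig),
                                  file.path(out_dir, "oligomers.csv"))
    files <- c(files, olig_path)
    if (!is.null(sq)) {
      sq_path <- file.path(out_dir, "structure_factor.dat")
      write_saxs_dat(scattering_curve(sq$q, sq$s_total),
                     sq_path, header = paste("config:", manifest$config_hash))
      files <- c(files, sq_path)
    }
    if (length(run$frames)) {
      xyz_path <- file.path(out_dir, "trajectory.xyz")
      write_xyz(run$frames, xyz_path, sys$chain$n_beads,
                comment = paste("config:", manifest$config_hash))
      files <- c(files, xyz_path)
    }
    manifest$files <- basename(files)
    json_path <- file.path(out_dir, "manifest.json")
    keep <- manifest[c("package_version", "config", "config_hash",
                       "n_chains", "acceptance", "n_ass", "chi2", "files")]
    jsonlite::write_json(keep, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  manifest
}
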