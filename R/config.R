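#' Default calibrated line-tension table
#'
#' Differential adhesion of the thyroid model, in the line-tension
#' encoding (lower values = stronger adhesion). Epithelial--epithelial
#' tension is kept relatively high (reduced cohesion): endothelial
#' invasion of the mass only succeeds when epithelial cells adhere
#' weakly to each other, while tip/stalk cells adhere strongly to each
#' other so the nascent vessel stays coherent. The tissue boundary acts
#' as a surface tension keeping the blob compact.
#'
#' @return Symmetric 6 x 6 matrix over `c(CELL_TYPES, "BOUNDARY")`.
#' @export
default_lambda_table <- function() {
  all_t <- c(CELL_TYPES, BOUNDARY_TYPE)
  L <- matrix(0.12, 6, 6, dimnames = list(all_t, all_t))
  set <- function(a, b, v) { L[a, b] <<- v; L[b, a] <<- v }
  epi <- c("epithelial_central", "epithelial_peripheral")
  endo <- c("endothelial_tip", "endothelial_stalk")
  for (a in epi) for (b in epi) set(a, b, 0.12)         # weak epithelial cohesion
  for (a in endo) for (b in endo) set(a, b, 0.01)       # coherent vessel
  for (a in epi) for (b in endo) set(a, b, 0.065)
  for (a in epi) set(a, BOUNDARY_TYPE, 0.25)            # tissue surface tension
  for (a in endo) set(a, BOUNDARY_TYPE, 0.15)
  for (a in c(epi, endo)) set("lumen", a, 0.05)         # lumina wet epithelium
  set("lumen", "lumen", 0.05)
  set("lumen", BOUNDARY_TYPE, 0.25)
  L
}

#' Default calibrated energy parameters
#'
#' Area elasticity `K` per type (endothelial cells are stiffer, keeping
#' thin nascent vessels from being squeezed flat by the surrounding
#' epithelium), perimeter contractility `gamma`, and the differential
#' adhesion table of [default_lambda_table()].
#'
#' @return An [energy_params()] object.
#' @export
default_energy_params <- function() {
  energy_params(
    K = c(epithelial_central = 1, epithelial_peripheral = 1,
          endothelial_tip = 5, endothelial_stalk = 5, lumen = 5),
    gamma = c(epithelial_central = 0.04, epithelial_peripheral = 0.04,
              endothelial_tip = 0.04, endothelial_stalk = 0.04,
              lumen = 0.005),
    lambda = default_lambda_table())
}

#' Simulation run configuration
#'
#' Bundles every tunable of the simulator: run length and time step,
#' seed, module toggles, the parameter blocks of all modules, and the
#' scheduling cadences. Serialisable to YAML ([write_run_config()]) with
#' a lossless round trip.
#'
#' @param duration simulated hours.
#' @param dt time step in hours (default 0.001).
#' @param seed RNG seed for the run.
#' @param chemotaxis,polarity,proliferation,branch_addition,stalk_division
#'   module toggles.
#' @param vegfa_ko in-silico VEGFA knockout: forces the morphogen source
#'   to zero.
#' @param energy an [energy_params()].
#' @param prolif a [proliferation_params()].
#' @param endo an [endothelial_params()].
#' @param morphogen a [morphogen_params()].
#' @param chemo a [chemotaxis_params()].
#' @param pol a [polarity_params()].
#' @param lumen a [lumen_params()].
#' @param thresholds a [rearrangement_thresholds()].
#' @param macro_every steps between R-level orchestration (morphogen
#'   recompute, polarity update, divisions); the mechanical substeps in
#'   between run in compiled code.
#' @param stats_every hours between summary-statistics rows.
#' @param snapshot_every hours between snapshots (`Inf` = none).
#' @param endo_A0 target area of newly added endothelial cells.
#' @param n_epithelial size of the synthetic initial condition when none
#'   is supplied to [simulate_tissue()].
#' @return list of class `run_config`.
#' @export
run_config <- function(duration = 72, dt = 0.001, seed = 1,
                       chemotaxis = TRUE, vegfa_ko = FALSE, polarity = TRUE,
                       proliferation = TRUE, branch_addition = TRUE,
                       stalk_division = TRUE,
                       energy = default_energy_params(),
                       prolif = proliferation_params(),
                       endo = endothelial_params(),
                       morphogen = morphogen_params(),
                       chemo = chemotaxis_params(),
                       pol = polarity_params(),
                       lumen = lumen_params(),
                       thresholds = rearrangement_thresholds(),
                       macro_every = 20L, stats_every = 0.5,
                       snapshot_every = Inf, endo_A0 = 0.3,
                       n_epithelial = 200) {
  stopifnot(duration >= 0, dt > 0, macro_every >= 1)
  structure(list(duration = duration, dt = dt, seed = as.integer(seed),
                 chemotaxis = chemotaxis, vegfa_ko = vegfa_ko,
                 polarity = polarity, proliferation = proliferation,
                 branch_addition = branch_addition,
                 stalk_division = stalk_division,
                 energy = energy, prolif = prolif, endo = endo,
                 morphogen = morphogen, chemo = chemo, pol = pol,
                 lumen = lumen, thresholds = thresholds,
                 macro_every = as.integer(macro_every),
                 stats_every = stats_every, snapshot_every = snapshot_every,
                 endo_A0 = endo_A0, n_epithelial = n_epithelial),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `read_run_config` returns a `run_config`; the writer returns
#'   `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$energy <- list(K = as.list(config$energy$K),
                   gamma = as.list(config$energy$gamma),
                   lambda = as.vector(config$energy$lambda))
  for (f in c("prolif", "endo", "morphogen", "chemo", "pol", "lumen"))
    x[[f]] <- unclass(x[[f]])
  x$thresholds <- unclass(x$thresholds)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  all_t <- c(CELL_TYPES, BOUNDARY_TYPE)
  lam <- matrix(as.numeric(x$energy$lambda), 6, 6,
                dimnames = list(all_t, all_t))
  cfg <- run_config(
    duration = x$duration, dt = x$dt, seed = x$seed,
    chemotaxis = x$chemotaxis, vegfa_ko = x$vegfa_ko, polarity = x$polarity,
    proliferation = x$proliferation, branch_addition = x$branch_addition,
    stalk_division = x$stalk_division,
    energy = energy_params(K = unlist(x$energy$K),
                           gamma = unlist(x$energy$gamma), lambda = lam),
    prolif = do.call(proliferation_params, x$prolif),
    endo = do.call(endothelial_params, x$endo),
    morphogen = do.call(morphogen_params,
                        x$morphogen[setdiff(names(x$morphogen), "boundary_value")]),
    chemo = do.call(chemotaxis_params, x$chemo),
    pol = do.call(polarity_params, x$pol),
    lumen = do.call(lumen_params, x$lumen),
    thresholds = do.call(rearrangement_thresholds, x$thresholds),
    macro_every = x$macro_every, stats_every = x$stats_every,
    snapshot_every = x$snapshot_every, endo_A0 = x$endo_A0,
    n_epithelial = x$n_epithelial)
  cfg
}
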