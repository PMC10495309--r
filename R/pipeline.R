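# Experiment orchestration: run the (configurable subset of the) full
# condition grid - nuclide x geometry x arrangement x internalization x
# source level - with hierarchical seed derivation, assemble dose-effect
# datasets, fit both damage stages, and derive RBE models per condition.

#' Pipeline run configuration
#'
#' The full study grid is 2 nuclides x 5 geometries x 2 arrangements x
#' 2 internalizations x 10 source levels = 400 setups, each simulated with
#' 10 seeds (4000 simulations) and 10 repair repetitions. The default
#' desk profile keeps the dataset shape (levels x runs) but reduces the
#' number of runs and repetitions; the full design is available via
#' `profile = "paper"`.
#'
#' @param geometries Subset of 1:5.
#' @param arrangements Subset of `c("planar_2d", "lattice_3d")`.
#' @param internalizations Subset of `c("internalized", "membrane_bound")`.
#' @param nuclides Subset of `c("Lu177", "Ac225")`.
#' @param levels_lu,levels_ac Per-cell source-count grids.
#' @param runs_per_level Independent damage simulations per source level.
#' @param repair_repetitions Repair repetitions per damage simulation.
#' @param master_seed Master seed from which all other seeds derive.
#' @param damage A `damage_params` list.
#' @param repair A `repair_params` list.
#' @param profile `"desk"` (default) or `"paper"`; `"paper"` sets 10 runs
#'   and 10 repetitions.
#' @return List of class `run_config`.
#' @export
run_config <- function(geometries = 1L,
                       arrangements = "lattice_3d",
                       internalizations = "internalized",
                       nuclides = c("Lu177", "Ac225"),
                       levels_lu = source_count_grid()$lu_counts,
                       levels_ac = source_count_grid()$ac_counts,
                       runs_per_level = 3L,
                       repair_repetitions = 3L,
                       master_seed = 1L,
                       damage = damage_params(),
                       repair = repair_params(),
                       profile = c("desk", "paper")) {
  profile <- match.arg(profile)
  if (profile == "paper") {
    geometries <- 1:5
    arrangements <- c("planar_2d", "lattice_3d")
    internalizations <- c("internalized", "membrane_bound")
    nuclides <- c("Lu177", "Ac225")
    runs_per_level <- 10L
    repair_repetitions <- 10L
  }
  stopifnot(all(geometries %in% 1:5),
            all(arrangements %in% c("planar_2d", "lattice_3d")),
            all(internalizations %in% c("internalized", "membrane_bound")),
            all(nuclides %in% c("Lu177", "Ac225")),
            runs_per_level >= 1, repair_repetitions >= 1)
  repair$repetitions <- as.integer(repair_repetitions)
  structure(list(geometries = as.integer(geometries),
                 arrangements = arrangements,
                 internalizations = internalizations,
                 nuclides = nuclides,
                 levels_lu = levels_lu, levels_ac = levels_ac,
                 runs_per_level = as.integer(runs_per_level),
                 master_seed = as.integer(master_seed),
                 damage = damage, repair = repair, profile = profile),
            class = "run_config")
}

#' Simulate the dose-effect dataset for one condition
#'
#' Builds the cluster for the condition, then for every source level and
#' run seed simulates damage and repeated repair, producing one row per
#' (level, run) with the absorbed dose, initial DSB count and mean/SD
#' post-repair DSB count.
#'
#' @param nuclide `"Lu177"` or `"Ac225"`.
#' @param geometry Cell geometry id (1..5).
#' @param arrangement `"planar_2d"` or `"lattice_3d"`.
#' @param internalization `"internalized"` or `"membrane_bound"`.
#' @param config A `run_config`.
#' @return data.frame with columns `level`, `run`, `dose_Gy`, `n_init`,
#'   `n_post_mean`, `n_post_sd`.
#' @export
simulate_condition <- function(nuclide, geometry, arrangement,
                               internalization, config = run_config()) {
  cluster <- build_cluster(cell_geometry(geometry), arrangement, nuclide)
  levels <- if (nuclide == "Lu177") config$levels_lu else config$levels_ac
  rows <- list()
  for (li in seq_along(levels)) {
    for (run in seq_len(config$runs_per_level)) {
      seed <- derive_seed(config$master_seed, nuclide, geometry, arrangement,
                          internalization, li, run)
      damage <- if (nuclide == "Lu177") {
        simulate_lu_run(cluster, levels[li], internalization,
                        config$damage, rng_seed = seed)
      } else {
        src <- plan_sources(cluster, internalization, levels[li],
                            rng_seed = seed)
        simulate_ac_run(cluster, src, config$damage,
                        rng_seed = derive_seed(seed, "transport"))
      }
      rep_out <- mean_post_repair(damage, config$repair,
                                  rng_seed = derive_seed(seed, "rep"))
      rows[[length(rows) + 1L]] <- data.frame(
        level = levels[li], run = run, dose_Gy = damage$dose_Gy,
        n_init = nrow(damage$dsbs),
        n_post_mean = rep_out$mean, n_post_sd = rep_out$sd)
    }
  }
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' For each condition in the configured grid: build the cluster, place
#' sources, simulate damage and repair, assemble the dose-effect dataset,
#' fit initial and post-repair stages with the stage-appropriate model,
#' and - where both nuclides were simulated - derive the RBE model per
#' (geometry, arrangement, internalization) cell.
#'
#' @param config A `run_config`.
#' @return List of class `result_bundle` with elements `datasets` (named
#'   list of per-condition data.frames), `fits` (data.frame of fitted
#'   parameters), `rbe` (data.frame of RBE summaries, one row per paired
#'   condition and damage stage), and `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  datasets <- list()
  fit_rows <- list()
  for (nuc in config$nuclides) {
    for (g in config$geometries) {
      for (arr in config$arrangements) {
        for (int in config$internalizations) {
          key <- paste(nuc, g, arr, int, sep = "|")
          ds <- simulate_condition(nuc, g, arr, int, config)
          datasets[[key]] <- ds
          for (stage in c("initial", "post_repair")) {
            y <- if (stage == "initial") ds$n_init else ds$n_post_mean
            model <- select_model(nuc, stage)
            fit <- fit_dose_effect(ds$dose_Gy, y, model)
            fit_rows[[length(fit_rows) + 1L]] <- data.frame(
              nuclide = nuc, geometry = g, arrangement = arr,
              internalization = int, stage = stage, model = model,
              b = fit$b, b_sd = fit$b_sd, a = fit$a, a_sd = fit$a_sd,
              r_squared = fit$r_squared)
          }
        }
      }
    }
  }
  fits <- do.call(rbind, fit_rows)
  rbe_rows <- list()
  if (all(c("Lu177", "Ac225") %in% config$nuclides)) {
    for (g in config$geometries) {
      for (arr in config$arrangements) {
        for (int in config$internalizations) {
          for (stage in c("initial", "post_repair")) {
            flu <- fits[fits$nuclide == "Lu177" & fits$geometry == g &
                          fits$arrangement == arr &
                          fits$internalization == int & fits$stage == stage, ]
            fac <- fits[fits$nuclide == "Ac225" & fits$geometry == g &
                          fits$arrangement == arr &
                          fits$internalization == int & fits$stage == stage, ]
            if (nrow(flu) != 1 || nrow(fac) != 1) next
            m <- rbe_model(fac$b, flu$b, max(flu$a, 0),
                           fac$b_sd, flu$b_sd,
                           ifelse(is.na(flu$a_sd), 0, flu$a_sd))
            cross <- if (m$a_lu > 0 && m$b_ac > m$b_lu) {
              crossover_dose(m)$dose
            } else NA_real_
            rbe_rows[[length(rbe_rows) + 1L]] <- data.frame(
              geometry = g, arrangement = arr, internalization = int,
              stage = stage, rbe_at_0 = m$b_ac / m$b_lu,
              rbe_at_0_sigma = propagate_rbe_sigma(m, 0, "dose_ac"),
              rbe_at_1Gy_ac = rbe_vs_dose_ac(m, 1),
              crossover_Gy = cross)
          }
        }
      }
    }
  }
  structure(list(datasets = datasets, fits = fits,
                 rbe = if (length(rbe_rows)) do.call(rbind, rbe_rows) else NULL,
                 config = config),
            class = "result_bundle")
}

#' @export
print.result_bundle <- function(x, ...) {
  cat("Pipeline result: ", length(x$datasets), " condition datasets, ",
      nrow(x$fits), " fits\n", sep = "")
  invisible(x)
}

#' Load the packaged fitted-parameter tables
#'
#' The published dose-effect fit parameters for both nuclides (20 condition
#' rows each: 5 geometries x 2 internalizations x 2 arrangements), shipped
#' as package fixtures. Used by the RBE calculus in fixture mode and by the
#' validation tests.
#'
#' @return List with data.frames `lu177` (b_init, b_repair, a_repair with
#'   SDs) and `ac225` (b_init, b_repair with SDs).
#' @export
load_fixture_tables <- function() {
  lu <- utils::read.csv(system.file("extdata", "fit_params_lu177.csv",
                                    package = "rbesim", mustWork = TRUE))
  ac <- utils::read.csv(system.file("extdata", "fit_params_ac225.csv",
                                    package = "rbesim", mustWork = TRUE))
  if (nrow(lu) != 20L || nrow(ac) != 20L) {
    stop("fixture tables corrupted: expected 20 rows per nuclide")
  }
  list(lu177 = lu, ac225 = ac)
}

#' RBE model for one fixture condition
#'
#' Builds an [rbe_model()] from the packaged fitted-parameter tables for a
#' given condition and damage stage.
#'
#' @param geometry Cell geometry id (1..5).
#' @param internalization `"internalized"` or `"membrane_bound"`.
#' @param arrangement `"planar_2d"` or `"lattice_3d"`.
#' @param stage `"initial"` or `"post_repair"`.
#' @param tables Fixture tables, as from [load_fixture_tables()].
#' @return An `rbe_model`.
#' @examples
#' m <- rbe_from_fixtures(1, "internalized", "lattice_3d", "post_repair")
#' rbe_vs_dose_lu(m, 0)  # 9.38
#' @export
rbe_from_fixtures <- function(geometry, internalization, arrangement,
                              stage = c("initial", "post_repair"),
                              tables = load_fixture_tables()) {
  stage <- match.arg(stage)
  pick <- function(tab) {
    r <- tab[tab$geometry == geometry &
               tab$internalization == internalization &
               tab$arrangement == arrangement, ]
    if (nrow(r) != 1) stop("condition not found in fixture tables")
    r
  }
  lu <- pick(tables$lu177)
  ac <- pick(tables$ac225)
  if (stage == "initial") {
    rbe_model(ac$b_init, lu$b_init, 0, ac$b_init_sd, lu$b_init_sd, 0)
  } else {
    rbe_model(ac$b_repair, lu$b_repair, lu$a_repair,
              ac$b_repair_sd, lu$b_repair_sd, lu$a_repair_sd)
  }
}
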