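#' Per-specimen gas-exchange capacities and required PO2 gradients
#'
#' Sums each specimen's eight spiracles (doubled for both sides) into total
#' diffusive conductance (nmol s^-1 kPa^-1) and total advective conductance
#' (m^3 s^-1 kPa^-1), then evaluates the PO2 gradient each metabolic
#' scenario would require to run entirely on diffusion, flagging gradients
#' above the 21 kPa atmospheric ceiling. Incomplete specimens are collected
#' as errors and reported via the `errors` attribute; the run continues.
#'
#' @param x a measurement table.
#' @param constants a [physical_constants()] object.
#' @param scenarios list of [metabolic_scenario()]s.
#' @param impute passed to [specimen_totals()].
#' @return Data frame, one row per complete specimen: identifiers, mass,
#'   `total_g_diff`, `total_g_adv`, and per scenario `dpo2_<name>` +
#'   `exceeds_<name>`. Attribute `errors`: named character vector of
#'   per-specimen failures.
#' @export
run_capacities <- function(x, constants = physical_constants(),
                           scenarios = default_scenarios(), impute = FALSE) {
  validate_measurements(x)
  ids <- unique(x$specimen_id)
  errors <- character(0)
  keep <- list()
  for (id in ids) {
    res <- tryCatch(
      specimen_totals(x[x$specimen_id == id, , drop = FALSE], impute = impute),
      error = function(e) conditionMessage(e))
    if (is.character(res)) errors[id] <- res else keep[[id]] <- res
  }
  if (length(errors))
    message("run_capacities: skipped ", length(errors), " incomplete specimen(s): ",
            paste(names(errors), collapse = ", "))
  tot <- do.call(rbind, keep)
  out <- tot[, c("specimen_id", "species", "sex", "mass_g")]
  # total_diff_cm is 2*sum(area/depth) in cm; conductances via the unit layer
  out$total_g_diff <- tot$total_diff_cm * constants$D * constants$beta_cap
  out$total_g_adv <- tot$total_adv_cm3 * 1e-6 / (8 * constants$mu)  # cm^3 -> m^3
  for (sc in scenarios) {
    d <- required_dpo2(out$mass_g, out$total_g_diff, sc, constants)
    out[[paste0("dpo2_", sc$name)]] <- d
    out[[paste0("exceeds_", sc$name)]] <- exceeds_atmosphere(d)
  }
  rownames(out) <- NULL
  attr(out, "errors") <- errors
  out
}

# metric extractor used by run_scaling: returns data.frame(mass, value)
.metric_values <- function(morph, totals, spiracle, metric) {
  if (spiracle == "total") {
    val <- switch(metric,
                  total_diff = totals$total_g_diff,
                  total_adv = totals$total_g_adv)
    data.frame(mass = totals$mass_g, value = val)
  } else {
    s <- morph[morph$spiracle == spiracle, ]
    val <- switch(metric,
                  depth = s$depth_cm, area = s$area_cm2,
                  diff_index = s$diff_index_cm, adv_index = s$adv_index_cm3)
    data.frame(mass = s$mass_g, value = val)
  }
}

#' Full allometric fit report over spiracles, metrics and totals
#'
#' For each of the 8 spiracles x 4 metrics (depth, area, area/depth,
#' area^2/depth) plus the two whole-animal conductance totals (34 rows):
#' OLS log-log fit, bootstrap percentile CI and isometry p-value, the
#' relative-variability statistic, and (optionally) the Bayesian posterior
#' median and HPD interval and a pGLS slope. Metrics that fail (e.g. a
#' spiracle absent from every specimen) are reported in the `errors`
#' attribute and the run continues.
#'
#' @param x a measurement table.
#' @param B bootstrap replicates.
#' @param seed base RNG seed; each (spiracle, metric) gets a distinct
#'   deterministic sub-seed.
#' @param bayes run the Bayesian regression per metric.
#' @param draws posterior draws when `bayes = TRUE`.
#' @param tree,species_col optional phylogeny for pGLS columns.
#' @param pgls add pGLS slope/intercept columns (requires `tree`).
#' @param lambda Pagel's lambda for the pGLS covariance.
#' @param constants a [physical_constants()] object.
#' @return Data frame with one row per (spiracle, metric); attribute
#'   `errors`.
#' @export
run_scaling <- function(x, B = 10000, seed = 1, bayes = TRUE, draws = 2000,
                        tree = NULL, pgls = FALSE, lambda = 1,
                        constants = physical_constants()) {
  morph <- spiracle_morphometrics(x)
  totals <- run_capacities(x, constants = constants, scenarios = list())
  jobs <- rbind(expand.grid(spiracle = spiracle_labels(),
                            metric = c("depth", "area", "diff_index", "adv_index"),
                            stringsAsFactors = FALSE),
                data.frame(spiracle = "total",
                           metric = c("total_diff", "total_adv")))
  errors <- character(0)
  rows <- vector("list", nrow(jobs))
  for (i in seq_len(nrow(jobs))) {
    sp <- jobs$spiracle[i]; met <- jobs$metric[i]
    rows[[i]] <- tryCatch({
      d <- .metric_values(morph, totals, sp, met)
      d <- d[is.finite(d$value), , drop = FALSE]
      boot <- bootstrap_fit(d$mass, d$value, B = B, seed = seed + 1000L * i,
                            metric = met)
      ref <- unname(isometric_slope(met))
      row <- data.frame(spiracle = sp, metric = met, n = boot$fit$n,
                        slope = boot$fit$slope, intercept = boot$fit$intercept,
                        residual_sd = boot$fit$residual_sd,
                        ci_low = boot$ci["slope", "lower"],
                        ci_high = boot$ci["slope", "upper"],
                        isometric_ref = ref,
                        p_isometry = isometry_test(boot, ref),
                        relative_variability = relative_variability(boot$fit))
      if (bayes) {
        post <- bayes_loglog(d$mass, d$value, draws = draws,
                             seed = seed + 1000L * i)
        row$bayes_slope <- post$medians["slope"]
        row$bayes_hpd94_low <- post$hpd94["slope", 1]
        row$bayes_hpd94_high <- post$hpd94["slope", 2]
        row$bayes_converged <- post$converged
      }
      if (pgls) {
        if (is.null(tree)) stop("pgls = TRUE requires a tree")
        sp_of <- if (sp == "total") totals$species else
          morph$species[morph$spiracle == sp]
        V <- phylo_covariance(tree, sp_of, lambda = lambda)
        g <- pgls_fit(d$mass, d$value, unclass(V), metric = met)
        row$pgls_slope <- g$slope
        row$pgls_intercept <- g$intercept
      }
      row
    }, error = function(e) {
      errors[paste(sp, met)] <<- conditionMessage(e)
      NULL
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "errors") <- errors
  out
}

#' Required-PO2 curves over a mass grid from the fitted conductance line
#'
#' Evaluates, for each metabolic scenario, the PO2 gradient required for
#' purely diffusive gas exchange along the fitted total-diffusive-conductance
#' regression line `log10 G = intercept + slope * log10 mass`, on a
#' log-spaced mass grid. In log10 space the resulting curve is itself a line
#' with slope `EXP - slope(G)`. Grid points where the required gradient
#' exceeds the 21 kPa atmospheric ceiling are flagged.
#'
#' @param fit_report result of [run_scaling()] (its `total_diff` row is
#'   used), or a `scaling_fit` of total diffusive conductance on mass.
#' @param mass_range range of masses, g.
#' @param scenarios list of [metabolic_scenario()]s.
#' @param n_grid number of log-spaced grid points.
#' @param constants a [physical_constants()] object.
#' @return Long data frame: `scenario`, `mass_g`, `g_diff`, `dpo2_kpa`,
#'   `exceeds_atmosphere`.
#' @export
run_dpo2_curves <- function(fit_report, mass_range = c(0.097, 18),
                            scenarios = default_scenarios(), n_grid = 200,
                            constants = physical_constants()) {
  if (inherits(fit_report, "scaling_fit")) {
    slope <- fit_report$slope; intercept <- fit_report$intercept
  } else {
    row <- fit_report[fit_report$metric == "total_diff", , drop = FALSE]
    if (nrow(row) != 1L)
      stop("run_dpo2_curves: fit report lacks a total_diff row")
    slope <- row$slope; intercept <- row$intercept
  }
  mass <- 10^seq(log10(mass_range[1]), log10(mass_range[2]),
                 length.out = n_grid)
  g <- 10^(intercept + slope * log10(mass))
  out <- do.call(rbind, lapply(scenarios, function(sc) {
    d <- required_dpo2(mass, g, sc, constants)
    data.frame(scenario = sc$name, mass_g = mass, g_diff = g,
               dpo2_kpa = d, exceeds_atmosphere = exceeds_atmosphere(d))
  }))
  rownames(out) <- NULL
  out
}

#' Run the whole analysis and persist its report tables
#'
#' Orchestrates [run_capacities()], [run_scaling()] and [run_dpo2_curves()]
#' over a measurement table (and optional tree) and writes
#' `capacities.csv`, `fit_report.csv`, `curves.csv`, an echo of the input
#' measurements, and a JSON run manifest with seeds and package version.
#' Reruns with identical inputs and seeds produce byte-identical outputs.
#'
#' @param x a measurement table.
#' @param out_dir output directory (created if needed).
#' @param tree optional phylogeny (enables pGLS columns when `pgls = TRUE`).
#' @param B,seed,bayes,draws,pgls,lambda passed to [run_scaling()].
#' @param scenarios list of [metabolic_scenario()]s.
#' @param constants a [physical_constants()] object.
#' @param n_grid grid size for the PO2 curves.
#' @return Invisibly, a list with the three tables and the output paths.
#' @export
run_pipeline <- function(x, out_dir, tree = NULL, B = 10000, seed = 1,
                         bayes = TRUE, draws = 2000, pgls = FALSE, lambda = 1,
                         scenarios = default_scenarios(),
                         constants = physical_constants(), n_grid = 200) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  caps <- run_capacities(x, constants = constants, scenarios = scenarios)
  fits <- run_scaling(x, B = B, seed = seed, bayes = bayes, draws = draws,
                      tree = tree, pgls = pgls, lambda = lambda,
                      constants = constants)
  curves <- run_dpo2_curves(fits, mass_range = range(x$mass_g),
                            scenarios = scenarios, constants = constants,
                            n_grid = n_grid)
  paths <- c(measurements = file.path(out_dir, "measurements.csv"),
             capacities = file.path(out_dir, "capacities.csv"),
             fit_report = file.path(out_dir, "fit_report.csv"),
             curves = file.path(out_dir, "curves.csv"),
             manifest = file.path(out_dir, "manifest.json"))
  write_measurement_table(x, paths["measurements"])
  for (nm in c("capacities", "fit_report", "curves")) {
    tab <- switch(nm, capacities = caps, fit_report = fits, curves = curves)
    utils::write.csv(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
                     paths[nm], row.names = FALSE, quote = FALSE)
  }
  manifest <- list(package = "spirascale",
                   version = as.character(utils::packageVersion("spirascale")),
                   seed = seed, B = B, bayes = bayes, draws = draws,
                   pgls = pgls, lambda = lambda,
                   scenarios = lapply(scenarios, unclass),
                   n_specimens = length(unique(x$specimen_id)))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(capacities = caps, fit_report = fits, curves = curves,
                 paths = paths))
}
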