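#' Configuration for the synthetic spiracle-measurement generator
#'
#' The generator emulates the structure of a scarab morphometric study:
#' 10 species, 17 specimens (1-2 per species), body masses log-uniform over
#' 0.097-18 g, and per-spiracle dimensions following power laws in mass with
#' lognormal noise and optional phylogenetically correlated deviations.
#'
#' Default intercepts place the mesothoracic (S) opening at 4x the area of
#' the metathoracic (T) and first three abdominal spiracles, with A4-A6 at
#' half the anterior abdominal size, and give a 1 g animal a total
#' diffusive conductance of ~18 nmol s^-1 kPa^-1 (so the largest animals
#' need a resting spiracular PO2 gradient of roughly half a kPa). Default
#' noise is smaller on anterior than posterior spiracle areas; depth noise
#' is independent of area noise.
#'
#' @param n_species number of species (>= 2).
#' @param specimens_per_species integer vector of length `n_species`
#'   (default: 7 species with 2 specimens, 3 with 1, totalling 17).
#' @param mass_range body-mass range, g (log-uniform sampling).
#' @param area_exponent,depth_exponent true mass-scaling exponents.
#' @param base_area_cm2 metathoracic opening area of a 1 g animal, cm^2.
#' @param area_multipliers named per-spiracle multipliers on `base_area_cm2`.
#' @param base_depth_cm spiracle depth of a 1 g animal, cm (all spiracles).
#' @param area_noise_sd named per-spiracle lognormal (log10) noise sd on area.
#' @param depth_noise_sd log10 noise sd on depth (recycled over spiracles).
#' @param eccentricity ratio d_transverse / d_sagittal of the slit-like
#'   opening.
#' @param lambda_signal strength of phylogenetically correlated deviations
#'   in `[0, 1]` (Pagel-lambda scaling of the Brownian covariance; 0 = none).
#' @param phylo_sd log10 sd of the Brownian species effect at the tips (the
#'   Brownian covariance is normalized to unit mean tip depth, so this is
#'   directly comparable to the noise sds).
#' @param seed RNG seed.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_species = 10,
                             specimens_per_species = NULL,
                             mass_range = c(0.097, 18),
                             area_exponent = 0.67,
                             depth_exponent = 0.33,
                             base_area_cm2 = 1.317e-3,
                             area_multipliers = c(S = 4, T = 1, A1 = 1, A2 = 1,
                                                  A3 = 1, A4 = 0.5, A5 = 0.5,
                                                  A6 = 0.5),
                             base_depth_cm = 0.1,
                             area_noise_sd = c(S = 0.05, T = 0.08, A1 = 0.10,
                                               A2 = 0.10, A3 = 0.10, A4 = 0.20,
                                               A5 = 0.22, A6 = 0.25),
                             depth_noise_sd = 0.08,
                             eccentricity = 2,
                             lambda_signal = 0,
                             phylo_sd = 0.1,
                             seed = 1) {
  # tolerate list-valued inputs (e.g. a re-read JSON manifest)
  for (nm in c("specimens_per_species", "mass_range", "area_multipliers",
               "area_noise_sd", "depth_noise_sd"))
    if (is.list(get(nm))) assign(nm, unlist(get(nm)))
  if (n_species < 2) stop("generator_config: need n_species >= 2")
  if (is.null(specimens_per_species)) {
    specimens_per_species <- rep(c(2L, 1L),
                                 c(min(7L, n_species),
                                   max(0L, n_species - 7L)))
  }
  if (length(specimens_per_species) != n_species)
    stop("generator_config: specimens_per_species must have length n_species")
  if (any(mass_range <= 0) || diff(mass_range) < 0)
    stop("generator_config: mass_range must be positive and ordered")
  labs <- spiracle_labels()
  area_multipliers <- area_multipliers[labs]
  area_noise_sd <- area_noise_sd[labs]
  depth_noise_sd <- rep_len(depth_noise_sd, 8L)
  names(depth_noise_sd) <- labs
  if (any(is.na(area_multipliers)) || any(is.na(area_noise_sd)))
    stop("generator_config: per-spiracle vectors must name all 8 spiracles")
  if (any(area_noise_sd < 0) || any(depth_noise_sd < 0) || phylo_sd < 0)
    stop("generator_config: noise sds must be >= 0")
  if (lambda_signal < 0 || lambda_signal > 1)
    stop("generator_config: lambda_signal must be in [0, 1]")
  structure(list(n_species = n_species,
                 specimens_per_species = as.integer(specimens_per_species),
                 mass_range = mass_range,
                 area_exponent = area_exponent,
                 depth_exponent = depth_exponent,
                 base_area_cm2 = base_area_cm2,
                 area_multipliers = area_multipliers,
                 base_depth_cm = base_depth_cm,
                 area_noise_sd = area_noise_sd,
                 depth_noise_sd = depth_noise_sd,
                 eccentricity = eccentricity,
                 lambda_signal = lambda_signal,
                 phylo_sd = phylo_sd,
                 seed = seed),
            class = "generator_config")
}

#' Generate a random species tree with unit branch lengths
#'
#' Random rooted topology (uniform sequential joins) with every branch set
#' to length 1, matching the unit-branch-length convention used when true
#' divergence times are unknown. Tip labels are `sp01 ... spNN`.
#'
#' @param config a [generator_config()].
#' @return A `phylo` object with `config$n_species` tips.
#' @export
generate_tree <- function(config = generator_config()) {
  set.seed(config$seed)
  tree <- ape::rtree(config$n_species, rooted = TRUE, br = NULL)
  tree$edge.length <- rep(1, nrow(tree$edge))
  tree$tip.label <- sprintf("sp%02d", seq_len(config$n_species))
  tree
}

#' Generate a synthetic spiracle measurement table
#'
#' Draws specimen masses log-uniformly over the configured range and, for
#' each spiracle, sets
#' `log10(dimension) = log10(intercept) + exponent * log10(mass) + phylo + noise`,
#' where `phylo` is a species-level Brownian deviation on the tree (its
#' covariance Pagel-scaled by `lambda_signal`) and `noise` is independent
#' Normal(0, sd) on the log10 scale. The two opening diameters are produced
#' with the configured eccentricity so that [elliptical_area()] recovers the
#' target area exactly.
#'
#' @param config a [generator_config()].
#' @param tree optional `phylo` from [generate_tree()]; generated from the
#'   config if omitted (required only when `lambda_signal > 0`).
#' @return A validated long-form measurement table (see
#'   [read_measurement_table()]).
#' @export
generate_specimens <- function(config = generator_config(), tree = NULL) {
  if (is.null(tree)) tree <- generate_tree(config)
  set.seed(config$seed + 1L)
  labs <- spiracle_labels()
  n_sp <- config$n_species
  species <- sprintf("sp%02d", seq_len(n_sp))
  spec_species <- rep(species, config$specimens_per_species)
  n <- length(spec_species)
  specimen_id <- sprintf("%s_%d", spec_species,
                         unlist(lapply(config$specimens_per_species, seq_len)))
  lr <- log10(config$mass_range)
  mass <- 10^stats::runif(n, lr[1], lr[2])
  sex <- sample(c("M", "F"), n, replace = TRUE)

  # species-level Brownian deviations, one independent draw per trait
  phylo_dev <- function() {
    if (config$lambda_signal == 0 || config$phylo_sd == 0)
      return(stats::setNames(numeric(n_sp), species))
    V <- phylo_covariance(tree, species, lambda = config$lambda_signal)
    Vn <- unclass(V) / mean(attr(V, "tip_depths"))
    L <- chol(Vn * config$phylo_sd^2)
    stats::setNames(drop(crossprod(L, stats::rnorm(n_sp))), species)
  }

  rows <- vector("list", 8L)
  for (k in seq_along(labs)) {
    lab <- labs[k]
    dev_area <- phylo_dev()
    dev_depth <- phylo_dev()
    log_area <- log10(config$base_area_cm2 * config$area_multipliers[lab]) +
      config$area_exponent * log10(mass) + dev_area[spec_species] +
      stats::rnorm(n, 0, config$area_noise_sd[lab])
    log_depth <- log10(config$base_depth_cm) +
      config$depth_exponent * log10(mass) + dev_depth[spec_species] +
      stats::rnorm(n, 0, config$depth_noise_sd[lab])
    area_mm2 <- 10^log_area * 100
    d_sag <- sqrt(4 * area_mm2 / (pi * config$eccentricity))
    rows[[k]] <- data.frame(specimen_id = specimen_id,
                            species = spec_species,
                            sex = sex,
                            mass_g = mass,
                            spiracle = lab,
                            d_transverse_mm = config$eccentricity * d_sag,
                            d_sagittal_mm = d_sag,
                            depth_mm = 10^log_depth * 10,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$specimen_id, match(out$spiracle, labs)), ]
  rownames(out) <- NULL
  validate_measurements(out)
  out
}

#' Write a complete synthetic dataset (measurements, tree, manifest)
#'
#' Emits the measurement CSV, the newick tree, and a JSON manifest recording
#' the full configuration and seed so the dataset can be regenerated exactly.
#'
#' @param config a [generator_config()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
simulate_dataset <- function(config = generator_config(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tree <- generate_tree(config)
  tab <- generate_specimens(config, tree)
  paths <- c(measurements = file.path(dir, "measurements.csv"),
             tree = file.path(dir, "tree.nwk"),
             manifest = file.path(dir, "manifest.json"))
  write_measurement_table(tab, paths["measurements"])
  ape::write.tree(tree, paths["tree"])
  cfg_out <- unclass(config)
  for (nm in c("area_multipliers", "area_noise_sd", "depth_noise_sd"))
    cfg_out[[nm]] <- as.list(cfg_out[[nm]])  # keep spiracle names in JSON
  jsonlite::write_json(cfg_out, paths["manifest"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
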