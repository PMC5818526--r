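#' Configuration for the synthetic community generator
#'
#' Defines a simulated landscape mirroring the sampling design the analysis
#' expects: 25 sites in four habitat classes (10 native-forest sites, 5 per
#' plantation class), a regional pool of 80 species, 6 sampling points per
#' site giving occurrence counts 0-6, individual-level trait measurements
#' with intraspecific variation, and habitat filtering in trait space.
#'
#' Filtering model: each species has a position in an 8-dimensional
#' standardized trait space; its occupancy probability at a site of habitat
#' `h` is `base_occupancy[h] * exp(-d^2 / (2 * omega[h]^2))` with `d` the
#' distance to the habitat's trait optimum. Under the default
#' `"homogenization"` scenario the plantation classes share one optimum with
#' narrow filters (trait-space narrowing plus compositional homogenization)
#' while the forest filter is broad and sits on the opposite side of the
#' regional centroid; base occupancies are calibrated so the expected
#' per-class species richness is field-realistic (about 21 / 15 / 11.5 /
#' 10.5 species for forest, unmanaged, young and old plantations). The
#' `"null"` scenario removes all filtering differences, for type-I-error
#' calibration.
#'
#' @param seed Integer seed; regeneration from the same config is
#'   bit-identical.
#' @param scenario `"homogenization"` (default) or `"null"`.
#' @param n_sites Named sites-per-habitat vector.
#' @param pool_size Species-pool size (default 80).
#' @param sampling_points Sampling points per site (default 6).
#' @param detection Per-sampling-point detection probability given occupancy.
#' @param base_occupancy Named per-habitat occupancy at the trait optimum.
#' @param omega Named per-habitat filter widths (standardized trait units).
#' @param optimum_offset Displacement of the shared plantation optimum from
#'   the regional centroid (standardized units; applied to the
#'   eye-to-mandible axis, shortening it, as disturbance filters out
#'   predators).
#' @param trait_mean_sdlog SD of species-level log trait deviations.
#' @param size_sdlog SD of the species log body-size factor.
#' @param cv_meanlog,cv_sdlog Log-normal parameters of the intraspecific
#'   coefficient of variation (per species and trait).
#' @param rare_fraction Fraction of pool species whose total measured
#'   individuals are capped below 6, exercising the SD-imputation rule.
#' @param spatial_clustering If TRUE, sites of a habitat cluster around a
#'   habitat center; default FALSE so spatial-autocorrelation nulls are
#'   clean.
#' @param landscape_size Landscape extent in m (default 5000).
#' @return Validated object of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              scenario = c("homogenization", "null"),
                              n_sites = c(forest = 10L,
                                          eucalyptus_unmanaged = 5L,
                                          eucalyptus_7y = 5L,
                                          eucalyptus_28y = 5L),
                              pool_size = 80L,
                              sampling_points = 6L,
                              detection = 0.45,
                              base_occupancy = NULL,
                              omega = NULL,
                              optimum_offset = 1.6,
                              trait_mean_sdlog = 0.35,
                              size_sdlog = 0.25,
                              cv_meanlog = log(0.08),
                              cv_sdlog = 0.3,
                              rare_fraction = 0.4,
                              spatial_clustering = FALSE,
                              landscape_size = 5000) {
  scenario <- match.arg(scenario)
  habitats <- names(n_sites)
  if (is.null(habitats)) stop("n_sites must be a named vector")
  if (scenario == "homogenization") {
    if (is.null(base_occupancy)) {
      base_occupancy <- stats::setNames(c(0.68, 1.0, 1.0, 1.0), habitats)
    }
    if (is.null(omega)) {
      omega <- stats::setNames(c(2.3, 1.65, 1.48, 1.43), habitats)
    }
  } else {
    if (is.null(base_occupancy)) {
      base_occupancy <- stats::setNames(rep(0.30, length(habitats)), habitats)
    }
    if (is.null(omega)) {
      omega <- stats::setNames(rep(1e6, length(habitats)), habitats)
    }
    optimum_offset <- 0
  }
  cfg <- list(seed = as.integer(seed), scenario = scenario,
              n_sites = n_sites, pool_size = as.integer(pool_size),
              sampling_points = as.integer(sampling_points),
              detection = detection, base_occupancy = base_occupancy,
              omega = omega, optimum_offset = optimum_offset,
              trait_mean_sdlog = trait_mean_sdlog, size_sdlog = size_sdlog,
              cv_meanlog = cv_meanlog, cv_sdlog = cv_sdlog,
              rare_fraction = rare_fraction,
              spatial_clustering = spatial_clustering,
              landscape_size = landscape_size)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$pool_size >= 10L, cfg$sampling_points >= 1L)
  probs <- c(cfg$detection, cfg$base_occupancy, cfg$rare_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(cfg$omega <= 0)) stop("filter widths omega must be positive")
  if (!identical(names(cfg$base_occupancy), names(cfg$n_sites)) ||
      !identical(names(cfg$omega), names(cfg$n_sites))) {
    stop("base_occupancy and omega must be named like n_sites")
  }
  class(cfg) <- "sim_config"
  cfg
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + k * 1000003) %% 2147483647)
}

# regional baseline trait geometry (mm, log scale)
base_log_traits <- function() {
  log(c(head_width = 0.80, scape_length = 0.65, eye_mandible_distance = 0.20,
        eye_length = 0.15, interocular_distance = 0.55, webers_length = 1.20,
        leg_length = 1.50, petiole_length = 0.25))
}

#' Generate the regional species pool
#'
#' Draws per-species true mean trait vectors around a regional centroid with
#' a shared log body-size factor (so Weber's length is allometrically
#' correlated with the other traits and ratio standardization is meaningful)
#' plus independent per-trait deviations, and per-species-per-trait
#' intraspecific SDs from a log-normal coefficient of variation. Also records
#' each species' position in the standardized trait space used by habitat
#' filtering.
#'
#' @param config A `sim_config`.
#' @return List with `species_id`, `means` (pool x 8, mm), `sds` (pool x 8,
#'   mm), `niche` (pool x 8 standardized positions), `rare` (logical flag per
#'   species marking measurement-capped species).
#' @export
generate_species_pool <- function(config) {
  set.seed(derive_seed(config$seed, 0L))
  s <- config$pool_size
  base <- base_log_traits()
  size <- stats::rnorm(s, 0, config$size_sdlog)
  dev_sd <- rep(config$trait_mean_sdlog, 8L)
  dev_sd[match("webers_length", trait_names())] <- 0.08
  dev <- matrix(stats::rnorm(s * 8L, 0, rep(dev_sd, each = s)), s, 8L)
  logm <- sweep(dev, 2L, base, "+") + size
  means <- exp(logm)
  dimnames(means) <- list(sprintf("sp%03d", seq_len(s)), trait_names())

  cv <- matrix(stats::rlnorm(s * 8L, config$cv_meanlog, config$cv_sdlog),
               s, 8L)
  sds <- means * cv
  dimnames(sds) <- dimnames(means)

  # standardized (z across the pool) log-ratio positions for filtering
  lr <- log_ratio_transform(means)
  niche <- scale(lr)
  attr(niche, "scaled:center") <- NULL
  attr(niche, "scaled:scale") <- NULL

  rare <- rep(FALSE, s)
  rare[sample.int(s, round(config$rare_fraction * s))] <- TRUE

  list(species_id = sprintf("sp%03d", seq_len(s)), means = means, sds = sds,
       niche = niche, rare = rare)
}

# Forest and plantation optima sit on opposite sides of the regional
# centroid along the eye-to-mandible axis (predator-associated trait, longer
# in forest); all plantation classes share one optimum, which is what drives
# their compositional homogenization.
habitat_optima <- function(config) {
  habitats <- names(config$n_sites)
  opt <- matrix(0, length(habitats), 8L,
                dimnames = list(habitats, trait_names()))
  plant <- habitats != "forest"
  opt[plant, "eye_mandible_distance"] <- -config$optimum_offset
  opt[!plant, "eye_mandible_distance"] <- config$optimum_offset
  opt
}

#' Sample site communities under habitat filtering
#'
#' For each site, each pool species is occupied with probability
#' `base_occupancy[h] * exp(-d^2 / (2 omega[h]^2))` (d = distance from the
#' species' standardized trait position to the habitat optimum); conditional
#' on occupancy the occurrence count is Binomial(sampling_points, detection).
#' Site coordinates are uniform over the landscape (or habitat-clustered when
#' configured).
#'
#' @param pool Output of [generate_species_pool()].
#' @param config The `sim_config`.
#' @return List with `occurrences` (site x species count matrix) and `sites`
#'   (data.frame: site_id, habitat, x, y).
#' @export
sample_communities <- function(pool, config) {
  set.seed(derive_seed(config$seed, 1L))
  habitats <- rep(names(config$n_sites), config$n_sites)
  n_site <- length(habitats)
  site_id <- sprintf("site%02d", seq_len(n_site))
  if (config$spatial_clustering) {
    centers <- matrix(stats::runif(2L * length(config$n_sites), 0,
                                   config$landscape_size),
                      length(config$n_sites), 2L,
                      dimnames = list(names(config$n_sites), NULL))
    xy <- centers[habitats, ] +
      matrix(stats::rnorm(2L * n_site, 0, config$landscape_size / 15),
             n_site, 2L)
  } else {
    xy <- matrix(stats::runif(2L * n_site, 0, config$landscape_size),
                 n_site, 2L)
  }
  opt <- habitat_optima(config)
  s <- config$pool_size
  occ <- matrix(0L, n_site, s, dimnames = list(site_id, pool$species_id))
  for (i in seq_len(n_site)) {
    h <- habitats[i]
    d2 <- rowSums(sweep(pool$niche, 2L, opt[h, ])^2)
    p_occ <- config$base_occupancy[[h]] * exp(-d2 / (2 * config$omega[[h]]^2))
    for (attempt in 1:2) {
      occupied <- stats::runif(s) < p_occ
      counts <- integer(s)
      counts[occupied] <- stats::rbinom(sum(occupied),
                                        config$sampling_points,
                                        config$detection)
      if (sum(counts) > 0L) break
      if (attempt == 2L) {
        stop("site ", site_id[i], " empty after resampling; increase ",
             "base_occupancy or detection")
      }
    }
    occ[i, ] <- counts
  }
  list(occurrences = occ,
       sites = data.frame(site_id = site_id, habitat = habitats,
                          x = xy[, 1L], y = xy[, 2L],
                          stringsAsFactors = FALSE))
}

#' Measure individuals of the sampled communities
#'
#' Emulates collecting up to six individuals per species per site: for every
#' occupied site-species pair the number measured is an occurrence-scaled
#' Poisson draw floored at 1 and capped at 6; individual trait values are
#' Normal(species mean, species SD), redrawn while non-positive. Species
#' flagged rare in the pool have their total measured individuals capped
#' below six (a random 1-5 subset is retained), exercising the
#' SD-imputation rule downstream.
#'
#' @param pool Output of [generate_species_pool()].
#' @param communities Output of [sample_communities()].
#' @param config The `sim_config`.
#' @return A validated `trait_table` data.frame.
#' @export
measure_individuals <- function(pool, communities, config) {
  set.seed(derive_seed(config$seed, 2L))
  occ <- communities$occurrences
  if (sum(occ) == 0L) stop("no occupied site-species pairs to measure")
  recs <- list()
  for (sp in seq_len(ncol(occ))) {
    sites_present <- which(occ[, sp] > 0L)
    if (length(sites_present) == 0L) next
    n_meas <- pmin(pmax(1L, stats::rpois(length(sites_present),
                                         occ[sites_present, sp])), 6L)
    total <- sum(n_meas)
    site_of <- rep(rownames(occ)[sites_present], n_meas)
    if (pool$rare[sp] && total >= 6L) {
      keep_n <- sample.int(5L, 1L)
      site_of <- site_of[sort(sample.int(total, keep_n))]
      total <- keep_n
    }
    tv <- matrix(0, total, 8L)
    for (j in seq_len(8L)) {
      v <- stats::rnorm(total, pool$means[sp, j], pool$sds[sp, j])
      tries <- 0L
      while (any(v <= 0)) {
        bad <- v <= 0
        v[bad] <- stats::rnorm(sum(bad), pool$means[sp, j], pool$sds[sp, j])
        tries <- tries + 1L
        if (tries > 100L) stop("persistent non-positive trait draws for ",
                               pool$species_id[sp])
      }
      tv[, j] <- v
    }
    colnames(tv) <- trait_names()
    recs[[length(recs) + 1L]] <- data.frame(
      species_id = pool$species_id[sp], site_id = site_of,
      as.data.frame(tv), stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, recs)
  df <- cbind(individual_id = sprintf("ind%05d", seq_len(nrow(df))), df)
  validate_trait_table(df)
}

#' Generate a complete synthetic dataset
#'
#' Runs [generate_species_pool()], [sample_communities()] and
#' [measure_individuals()] under one config and bundles the result with its
#' ground truth (true species means/SDs, habitat filter parameters, and the
#' qualitative ordering the filters induce).
#'
#' @param config A `sim_config` (default: the homogenization scenario,
#'   seed 1).
#' @return Object of class `synthetic_dataset`: `traits`, `occurrences`,
#'   `sites`, `ground_truth`, `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  pool <- generate_species_pool(config)
  comm <- sample_communities(pool, config)
  traits <- measure_individuals(pool, comm, config)
  gt <- list(
    species_means = pool$means, species_sds = pool$sds,
    rare_species = pool$species_id[pool$rare],
    habitat_optima = habitat_optima(config),
    omega = config$omega, base_occupancy = config$base_occupancy,
    expected_ordering = if (config$scenario == "homogenization") {
      paste("forest FRic above every plantation class;",
            "plantation-plantation beta below forest-plantation beta")
    } else "no habitat differences (null scenario)"
  )
  structure(list(traits = traits, occurrences = comm$occurrences,
                 sites = comm$sites, ground_truth = gt, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic dataset (", x$config$scenario, " scenario, seed ",
      x$config$seed, "): ", nrow(x$occurrences), " sites x ",
      ncol(x$occurrences), " pool species; ", nrow(x$traits),
      " measured individuals\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to CSV/YAML files
#'
#' Writes `traits.csv`, `occurrences.csv`, `sites.csv`, a config echo
#' (`config.yaml`) and the ground-truth descriptor (`ground_truth.yaml` plus
#' `ground_truth_species.csv`).
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(dataset$traits, file.path(dir, "traits.csv"),
                   row.names = FALSE)
  occ <- data.frame(site_id = rownames(dataset$occurrences),
                    dataset$occurrences, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.csv(occ, file.path(dir, "occurrences.csv"), row.names = FALSE)
  utils::write.csv(dataset$sites, file.path(dir, "sites.csv"),
                   row.names = FALSE)
  cfg <- unclass(dataset$config)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  gt <- dataset$ground_truth
  yaml::write_yaml(list(rare_species = gt$rare_species,
                        omega = as.list(gt$omega),
                        base_occupancy = as.list(gt$base_occupancy),
                        expected_ordering = gt$expected_ordering),
                   file.path(dir, "ground_truth.yaml"))
  sp <- data.frame(species_id = rownames(gt$species_means) %||%
                     sprintf("sp%03d", seq_len(nrow(gt$species_means))),
                   stats::setNames(as.data.frame(gt$species_means),
                                   paste0("mean_", colnames(gt$species_means))),
                   stats::setNames(as.data.frame(gt$species_sds),
                                   paste0("sd_", colnames(gt$species_sds))),
                   stringsAsFactors = FALSE)
  utils::write.csv(sp, file.path(dir, "ground_truth_species.csv"),
                   row.names = FALSE)
  invisible(dir)
}
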