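#' Analysis configuration
#'
#' Collects every tunable of the end-to-end analysis so a run is fully
#' described by (inputs, config): ordination axes retained, trait-grid
#' resolution, high-density-region trimming, the functional beta mode, the
#' permutation budget and seed.
#'
#' @param retained_axes PCA axes kept for the trait space (default 4).
#' @param cells_per_dim Grid cells per axis (default 15).
#' @param buffer_fraction Grid bound expansion per side (default 0.05).
#' @param trim_mass Species-TPD high-density-region mass (default 0.99).
#' @param beta_mode Functional beta partition mode, `"volume"` or
#'   `"overlap"` (see [functional_beta()]).
#' @param n_perm Permutations for PERMANOVA / Moran / Mantel (default 9999).
#' @param seed Integer seed for every permutation engine.
#' @param alpha Significance level for pairwise letters (default 0.05).
#' @param min_individuals SD-imputation threshold (default 6).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(retained_axes = 4L, cells_per_dim = 15L,
                            buffer_fraction = 0.05, trim_mass = 0.99,
                            beta_mode = c("volume", "overlap"),
                            n_perm = 9999L, seed = 1L, alpha = 0.05,
                            min_individuals = 6L) {
  structure(list(retained_axes = as.integer(retained_axes),
                 cells_per_dim = as.integer(cells_per_dim),
                 buffer_fraction = buffer_fraction, trim_mass = trim_mass,
                 beta_mode = match.arg(beta_mode),
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 alpha = alpha, min_individuals = as.integer(min_individuals),
                 fred_formula = "mean_overlap_depth_minus_one"),
            class = "pipeline_config")
}

#' Read and cross-validate the three input tables
#'
#' @param traits_csv Individual-level trait CSV (see [read_trait_table()]).
#' @param occurrences_csv Site x species occurrence-count CSV: a `site_id`
#'   column plus one integer column per species.
#' @param sites_csv Site metadata CSV: `site_id`, `habitat`, `x`, `y`
#'   (projected coordinates in m).
#' @return List `traits` (trait_table), `occurrences` (site x species
#'   matrix), `sites` (data.frame), all cross-referenced.
#' @export
read_inputs <- function(traits_csv, occurrences_csv, sites_csv) {
  traits <- read_trait_table(traits_csv)
  occ_df <- utils::read.csv(occurrences_csv, check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (!"site_id" %in% names(occ_df)) {
    stop("occurrences CSV needs a site_id column")
  }
  if (anyDuplicated(occ_df$site_id)) stop("duplicated site_id in occurrences")
  occ <- as.matrix(occ_df[, setdiff(names(occ_df), "site_id"), drop = FALSE])
  storage.mode(occ) <- "double"
  rownames(occ) <- occ_df$site_id
  if (anyNA(occ) || any(occ < 0)) {
    stop("occurrence counts must be non-negative and complete")
  }
  sites <- utils::read.csv(sites_csv, stringsAsFactors = FALSE)
  miss <- setdiff(c("site_id", "habitat", "x", "y"), names(sites))
  if (length(miss) > 0L) {
    stop("sites CSV is missing columns: ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(sites$site_id)) stop("duplicated site_id in sites")
  cross_reference(traits, occ, sites)
  message("read inputs: ", nrow(occ), " sites x ", ncol(occ), " species, ",
          nrow(traits), " measured individuals")
  list(traits = traits, occurrences = occ, sites = sites)
}

cross_reference <- function(traits, occ, sites) {
  if (!setequal(rownames(occ), sites$site_id)) {
    stop("site ids of occurrences and site metadata do not match")
  }
  occurring <- colnames(occ)[colSums(occ) > 0]
  orphans <- setdiff(occurring, unique(traits$species_id))
  if (length(orphans) > 0L) {
    stop("species present in occurrences but absent from the trait table: ",
         paste(orphans, collapse = ", "))
  }
  invisible(TRUE)
}

#' Run the full trait-diversity analysis in memory
#'
#' The computational core of [run_pipeline()]: standardization, ordination,
#' species summaries with SD imputation, species and community trait
#' probability distributions, alpha indices, taxonomic/functional beta
#' partitions, Bray-Curtis, habitat group comparisons, PERMANOVA, Moran's I
#' and the Mantel test.
#'
#' @param traits A `trait_table` (or data.frame with its columns).
#' @param occurrences Site x species occurrence-count matrix.
#' @param sites Site metadata data.frame (`site_id`, `habitat`, `x`, `y`).
#' @param config A [pipeline_config()].
#' @return List of results: `standardization`, `pca`, `coords`,
#'   `species_summary`, `grid`, `alpha` (per-site data.frame),
#'   `beta_taxonomic`, `beta_functional`, `bray_curtis`, `group_tests`,
#'   `permanova`, `spatial`, `config`.
#' @export
analyze_dataset <- function(traits, occurrences, sites,
                            config = pipeline_config()) {
  occ <- as.matrix(occurrences)
  sites <- as.data.frame(sites)
  sites <- sites[match(rownames(occ), sites$site_id), ]
  cross_reference(traits, occ, sites)

  std <- standardize_traits(traits)
  pca <- fit_trait_pca(std, retained_axes = config$retained_axes)
  coords <- project_individuals(pca, std)
  summ <- summarize_species(coords, min_individuals = config$min_individuals)
  axis_cols <- grep("^axis", names(coords), value = TRUE)
  grid <- build_grid(as.matrix(coords[, axis_cols]),
                     cells_per_dim = config$cells_per_dim,
                     buffer_fraction = config$buffer_fraction)

  tpds <- lapply(seq_len(nrow(summ)), function(i) {
    species_tpd(summ[i, ], grid, trim_mass = config$trim_mass)
  })
  names(tpds) <- summ$species_id

  occurring <- colnames(occ)[colSums(occ) > 0]
  dissim <- tpd_dissimilarity(tpds[occurring])

  n_site <- nrow(occ)
  tpdcs <- vector("list", n_site)
  alpha <- vector("list", n_site)
  for (i in seq_len(n_site)) {
    present <- colnames(occ)[occ[i, ] > 0]
    w <- occ[i, present] / sum(occ[i, present])
    tpdcs[[i]] <- community_tpd(tpds[present], w, site_id = rownames(occ)[i])
    cwm <- community_weighted_mean(std$species_means_raw, w, species = present)
    alpha[[i]] <- data.frame(
      site_id = rownames(occ)[i], habitat = sites$habitat[i],
      richness = species_richness(occ[i, ]),
      stats::setNames(as.data.frame(t(cwm)), paste0("cwm_", names(cwm))),
      fric = functional_richness(tpdcs[[i]], grid),
      fred = functional_redundancy(tpdcs[[i]], tpds[present]),
      rao_q = rao_q(weights = w,
                    dissim = dissim[present, present, drop = FALSE]),
      stringsAsFactors = FALSE)
  }
  alpha <- do.call(rbind, alpha)

  beta_tax <- taxonomic_beta(occ)
  beta_fun <- functional_beta(tpdcs, mode = config$beta_mode)
  bc <- bray_curtis(occ)

  indices <- c("richness", "fric", "fred", "rao_q",
               grep("^cwm_", names(alpha), value = TRUE))
  group_tests <- lapply(stats::setNames(indices, indices), function(v) {
    compare_groups(alpha[[v]], alpha$habitat, alpha = config$alpha)
  })

  perm_list <- list()
  k <- 0L
  for (flavor in c("taxonomic", "functional")) {
    bm <- if (flavor == "taxonomic") beta_tax else beta_fun
    for (comp in c("total", "turnover", "nested")) {
      k <- k + 1L
      pr <- permanova(bm[[comp]], sites$habitat, n_perm = config$n_perm,
                      seed = derive_seed(config$seed, 10L + k))
      perm_list[[paste(flavor, comp, sep = "_")]] <-
        data.frame(flavor = flavor, component = comp, F = pr$observed,
                   R2 = pr$r_squared, p = pr$p_value,
                   stringsAsFactors = FALSE)
    }
  }
  permanova_table <- do.call(rbind, perm_list)
  rownames(permanova_table) <- NULL

  xy <- as.matrix(sites[, c("x", "y")])
  spatial <- list(
    mantel = mantel_test(bc, as.matrix(stats::dist(xy)),
                         n_perm = config$n_perm,
                         seed = derive_seed(config$seed, 20L))
  )
  for (v in c("richness", "fric", "fred", "rao_q")) {
    spatial[[paste0("moran_", v)]] <-
      morans_i(alpha[[v]], xy, n_perm = config$n_perm,
               seed = derive_seed(config$seed, 21L))
  }

  list(standardization = std, pca = pca, coords = coords,
       species_summary = summ, grid = grid, tpds = tpds, tpdcs = tpdcs,
       alpha = alpha, beta_taxonomic = beta_tax, beta_functional = beta_fun,
       bray_curtis = bc, group_tests = group_tests,
       permanova = permanova_table, spatial = spatial, config = config)
}

#' Run the pipeline end-to-end from CSV inputs to an output directory
#'
#' Reads and validates the inputs, runs [analyze_dataset()], and writes all
#' declared outputs: standardized traits, the ordination model, species
#' summaries, the per-site alpha table, six beta matrices (two flavors x
#' three components), the Bray-Curtis matrix, the group-test and PERMANOVA
#' tables, the spatial-autocorrelation table, and a deterministic run
#' manifest. Two runs with identical inputs and config produce byte-identical
#' output trees; timings are logged to stderr only.
#'
#' @param traits_csv,occurrences_csv,sites_csv Input CSV paths (see
#'   [read_inputs()]).
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @return The [analyze_dataset()] result list, invisibly.
#' @export
run_pipeline <- function(traits_csv, occurrences_csv, sites_csv, out_dir,
                         config = pipeline_config()) {
  t0 <- proc.time()[["elapsed"]]
  inputs <- read_inputs(traits_csv, occurrences_csv, sites_csv)
  res <- analyze_dataset(inputs$traits, inputs$occurrences, inputs$sites,
                         config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, name, rn = FALSE) {
    utils::write.csv(x, file.path(out_dir, name), row.names = rn)
  }

  wcsv(res$standardization$individuals, "standardized_traits.csv")
  write_ordination_model(res$pca, file.path(out_dir, "ordination_model.txt"))
  wcsv(res$species_summary, "species_summary.csv")
  wcsv(res$alpha, "alpha.csv")

  for (flavor in c("taxonomic", "functional")) {
    bm <- if (flavor == "taxonomic") res$beta_taxonomic else res$beta_functional
    for (comp in c("total", "turnover", "nested")) {
      wcsv(bm[[comp]], paste0(flavor, "_", comp, ".csv"), rn = TRUE)
    }
  }
  wcsv(res$bray_curtis, "bray_curtis.csv", rn = TRUE)
  wcsv(beta_pairs_long(res$beta_taxonomic, res$beta_functional,
                       res$alpha$habitat), "beta_pairs.csv")

  tests <- do.call(rbind, lapply(names(res$group_tests), function(v) {
    g <- res$group_tests[[v]]
    data.frame(index = v, method = g$method, statistic = g$statistic,
               p_value = g$p_value, shapiro_p = g$shapiro_p,
               letters = paste(names(g$letters), g$letters, sep = "=",
                               collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  wcsv(tests, "tests.csv")
  wcsv(res$permanova, "permanova.csv")

  spat <- do.call(rbind, lapply(names(res$spatial), function(nm) {
    s <- res$spatial[[nm]]
    data.frame(test = nm, statistic = s$statistic, observed = s$observed,
               p_value = s$p_value, n_permutations = s$n_permutations,
               stringsAsFactors = FALSE)
  }))
  wcsv(spat, "spatial.csv")

  manifest <- list(
    package = "traitpd",
    version = as.character(utils::packageVersion("traitpd")),
    config = unclass(config),
    grid = list(dims = res$grid$dims, cells_per_dim = res$grid$cells_per_dim,
                lower = as.numeric(res$grid$lower),
                upper = as.numeric(res$grid$upper),
                cell_volume = res$grid$cell_volume),
    n_sites = nrow(res$alpha),
    n_species_pool = ncol(inputs$occurrences),
    n_individuals = nrow(inputs$traits),
    explained_fraction = as.numeric(res$pca$explained_fraction),
    outputs = sort(list.files(out_dir))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  message(sprintf("pipeline finished in %.1f s; outputs in %s",
                  proc.time()[["elapsed"]] - t0, out_dir))
  invisible(res)
}

write_ordination_model <- function(pca, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("retained_axes:", pca$retained_axes),
    paste("explained_fraction:",
          paste(format(pca$explained_fraction, digits = 15L), collapse = " ")),
    paste("center:", paste(format(pca$center, digits = 17L), collapse = " ")),
    paste("scale:", paste(format(pca$scale, digits = 17L), collapse = " ")),
    "loadings:"), con)
  utils::write.table(format(pca$loadings, digits = 17L), con, quote = FALSE,
                     col.names = FALSE)
}

beta_pairs_long <- function(beta_tax, beta_fun, habitats) {
  n <- length(beta_tax$sites)
  idx <- which(upper.tri(beta_tax$total), arr.ind = TRUE)
  out <- data.frame(
    site1 = beta_tax$sites[idx[, 1L]], site2 = beta_tax$sites[idx[, 2L]],
    habitat1 = habitats[idx[, 1L]], habitat2 = habitats[idx[, 2L]],
    stringsAsFactors = FALSE)
  for (flavor in c("taxonomic", "functional")) {
    bm <- if (flavor == "taxonomic") beta_tax else beta_fun
    for (comp in c("total", "turnover", "nested")) {
      out[[paste(flavor, comp, sep = "_")]] <- bm[[comp]][idx]
    }
  }
  out
}
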