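#' Canonical morphological trait names
#'
#' The eight ant morphological traits the package operates on, in canonical
#' column order. All lengths are in mm. Weber's length (mesosoma length) is
#' the allometric denominator used by [standardize_traits()].
#'
#' @return Character vector of length 8.
#' @export
trait_names <- function() {
  c("head_width", "scape_length", "eye_mandible_distance", "eye_length",
    "interocular_distance", "webers_length", "leg_length", "petiole_length")
}

id_cols <- function() c("individual_id", "species_id", "site_id")

#' Read and validate an individual-level trait table
#'
#' Reads a CSV with one row per measured individual: `individual_id`,
#' `species_id`, `site_id`, and the eight trait columns of [trait_names()]
#' (mm). Records with any missing trait value or any non-positive trait value
#' are rejected with the offending row identified.
#'
#' @param path Path to the CSV file.
#' @return A validated data.frame (class `trait_table`).
#' @export
read_trait_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trait_table(df)
}

#' Validate an in-memory trait table
#'
#' @param df data.frame with the columns documented in [read_trait_table()].
#' @return `df` with class `trait_table` prepended.
#' @export
validate_trait_table <- function(df) {
  needed <- c(id_cols(), trait_names())
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    stop("trait table is missing columns: ", paste(missing, collapse = ", "))
  }
  tv <- as.matrix(df[, trait_names()])
  storage.mode(tv) <- "double"
  if (anyNA(tv)) {
    bad <- df$individual_id[rowSums(is.na(tv)) > 0L]
    stop("trait table has missing trait values for individuals: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (any(tv <= 0)) {
    bad <- df$individual_id[rowSums(tv <= 0) > 0L]
    stop("non-positive trait values for individuals: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (anyDuplicated(df$individual_id)) {
    stop("duplicated individual_id in trait table")
  }
  df <- df[, needed]
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Allometric log-ratio standardization of traits
#'
#' Each trait except Weber's length is divided by Weber's length (removing
#' the dominant body-size axis), log-transformed, and z-scored; Weber's length
#' itself is log-transformed and z-scored, retaining body size as its own
#' dimension. The z-scoring constants (center and scale) are computed from the
#' matrix of per-species means of the log-ratio values -- the matrix the PCA
#' consumes -- and those same constants are applied to the individuals, so
#' species scores and individual projections live in one space.
#'
#' @param table A `trait_table` (see [read_trait_table()]).
#' @return An object of class `trait_standardization` with elements:
#'   \describe{
#'     \item{individuals}{data.frame of ids plus standardized trait columns.}
#'     \item{species_means}{species x 8 matrix of standardized species means.}
#'     \item{species_means_raw}{species x 8 matrix of raw-scale (mm) species
#'       mean traits, used for community weighted means.}
#'     \item{center, scale}{the 8-vectors of z-scoring constants.}
#'     \item{fingerprint}{string identifying the scaling constants, used to
#'       guard [project_individuals()] against mismatched models.}
#'   }
#' @export
standardize_traits <- function(table) {
  table <- validate_trait_table(as.data.frame(table))
  tv <- as.matrix(table[, trait_names()])
  lr <- log_ratio_transform(tv)

  sp <- factor(table$species_id, levels = unique(table$species_id))
  sp_means_lr <- rowsum(lr, sp) / as.vector(table(sp))
  sp_means_raw <- rowsum(tv, sp) / as.vector(table(sp))

  center <- colMeans(sp_means_lr)
  scale <- apply(sp_means_lr, 2L, stats::sd)
  if (any(scale == 0)) {
    stop("zero variance across species means for trait(s): ",
         paste(trait_names()[scale == 0], collapse = ", "))
  }

  z <- function(m) sweep(sweep(m, 2L, center), 2L, scale, "/")
  ind_std <- z(lr)
  out <- cbind(table[, id_cols()], as.data.frame(ind_std))

  structure(list(
    individuals = out,
    species_means = z(sp_means_lr),
    species_means_raw = sp_means_raw,
    center = center,
    scale = scale,
    fingerprint = scaling_fingerprint(center, scale)
  ), class = "trait_standardization")
}

log_ratio_transform <- function(tv) {
  wl <- tv[, "webers_length"]
  lr <- log(sweep(tv, 1L, wl, "/"))
  lr[, "webers_length"] <- log(wl)
  lr
}

scaling_fingerprint <- function(center, scale) {
  paste(format(c(center, scale), digits = 17L), collapse = "|")
}

#' Principal component ordination of species mean traits
#'
#' Fits a PCA on standardized per-species mean traits (never on individuals,
#' so heavily measured species do not dominate the axes). Axis signs are fixed
#' so the largest-magnitude loading of each component is positive, making the
#' ordination reproducible bit-for-bit. Individuals are projected onto the
#' fitted axes afterwards with [project_individuals()].
#'
#' @param x A `trait_standardization` object, or a numeric species x traits
#'   matrix (in which case it is centered internally and no fingerprint guard
#'   is available).
#' @param retained_axes Number of leading axes kept downstream (default 4).
#' @param var_target If non-NULL, overrides `retained_axes`: the smallest
#'   number of axes whose cumulative explained fraction reaches this value
#'   is retained.
#' @return Object of class `trait_pca`: `loadings` (orthonormal columns),
#'   `explained_fraction`, `retained_axes`, `center`, `scale`, `scores`
#'   (species scores on all axes), `fingerprint`.
#' @export
fit_trait_pca <- function(x, retained_axes = 4L, var_target = NULL) {
  if (inherits(x, "trait_standardization")) {
    m <- x$species_means
    fingerprint <- x$fingerprint
    pc_center <- rep(0, ncol(m))  # already centered over species
  } else {
    m <- as.matrix(x)
    fingerprint <- NA_character_
    pc_center <- colMeans(m)
  }
  if (nrow(m) < 2L) stop("PCA needs at least 2 species")
  centered <- sweep(m, 2L, pc_center)
  if (all(abs(centered) < 1e-12)) stop("zero-variance input matrix: PCA undefined")
  if (sum(apply(centered, 2L, stats::sd) > 0) < 2L) {
    stop("PCA needs at least 2 traits with nonzero variance")
  }

  pc <- stats::prcomp(centered, center = FALSE, scale. = FALSE)
  rot <- pc$rotation
  # sign convention: largest |loading| in each column positive
  for (j in seq_len(ncol(rot))) {
    k <- which.max(abs(rot[, j]))
    if (rot[k, j] < 0) rot[, j] <- -rot[, j]
  }
  ev <- pc$sdev^2
  explained <- ev / sum(ev)
  n_axes <- ncol(rot)
  if (!is.null(var_target)) {
    retained_axes <- which(cumsum(explained) >= var_target)[1L]
  }
  retained_axes <- min(as.integer(retained_axes), n_axes)

  structure(list(
    loadings = rot,
    explained_fraction = explained,
    retained_axes = retained_axes,
    center = pc_center,
    scale = rep(1, ncol(m)),
    scores = centered %*% rot,
    fingerprint = fingerprint
  ), class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, ...) {
  cat("Trait-space PCA:", ncol(x$loadings), "axes,",
      x$retained_axes, "retained\n")
  cat("Cumulative explained fraction:",
      paste(sprintf("%.3f", cumsum(x$explained_fraction)), collapse = " "), "\n")
  invisible(x)
}

#' Project standardized individuals into the retained trait space
#'
#' Applies the ordination fitted on species means to the individual-level
#' standardized traits, truncated to the retained axes. The standardization
#' fingerprint must match the one the model was fitted with.
#'
#' @param model A `trait_pca` from [fit_trait_pca()].
#' @param standardized A `trait_standardization`, or a numeric matrix of
#'   already-standardized trait rows.
#' @return If given a standardization object, a data.frame of ids plus
#'   `axis1..axisK` columns; if a matrix, the projected coordinate matrix.
#' @export
project_individuals <- function(model, standardized) {
  stopifnot(inherits(model, "trait_pca"))
  k <- model$retained_axes
  if (inherits(standardized, "trait_standardization")) {
    if (!is.na(model$fingerprint) &&
        !identical(model$fingerprint, standardized$fingerprint)) {
      stop("scaling-constant fingerprint mismatch: model was fitted on a ",
           "different standardization")
    }
    m <- as.matrix(standardized$individuals[, trait_names()])
    coords <- sweep(m, 2L, model$center) %*% model$loadings[, seq_len(k), drop = FALSE]
    colnames(coords) <- paste0("axis", seq_len(k))
    cbind(standardized$individuals[, id_cols()], as.data.frame(coords))
  } else {
    m <- as.matrix(standardized)
    coords <- sweep(m, 2L, model$center) %*% model$loadings[, seq_len(k), drop = FALSE]
    colnames(coords) <- paste0("axis", seq_len(k))
    coords
  }
}

#' Per-species trait-space summaries with the six-individual SD rule
#'
#' Summarizes projected individual coordinates per species: per-axis mean and
#' standard deviation. Species measured on fewer than `min_individuals`
#' individuals (default 6) cannot support their own SD estimate; they receive,
#' per axis, the arithmetic mean of the SDs of all adequately measured species
#' (the donor pool), and are flagged `sd_imputed`.
#'
#' @param coords data.frame from [project_individuals()] (needs `species_id`
#'   and `axis*` columns), or a numeric matrix plus a `species` vector.
#' @param species Species ids, required when `coords` is a bare matrix.
#' @param min_individuals Threshold below which SDs are imputed (default 6).
#' @return data.frame of class `species_trait_summary`: `species_id`,
#'   `n_individuals`, `mean_axis*`, `sd_axis*`, `sd_imputed`.
#' @export
summarize_species <- function(coords, species = NULL, min_individuals = 6L) {
  if (is.data.frame(coords) && "species_id" %in% names(coords)) {
    species <- coords$species_id
    m <- as.matrix(coords[, grep("^axis", names(coords)), drop = FALSE])
  } else {
    if (is.null(species)) stop("species ids required for a bare coordinate matrix")
    m <- as.matrix(coords)
    if (is.null(colnames(m))) colnames(m) <- paste0("axis", seq_len(ncol(m)))
  }
  sp <- factor(species, levels = unique(species))
  n <- as.vector(table(sp))
  means <- rowsum(m, sp) / n
  sds <- vapply(seq_len(ncol(m)), function(j) {
    tapply(m[, j], sp, stats::sd)
  }, numeric(nlevels(sp)))
  if (nlevels(sp) == 1L) sds <- matrix(sds, nrow = 1L)

  donor <- n >= min_individuals
  if (!any(donor)) {
    stop("SD imputation impossible: no species has >= ", min_individuals,
         " measured individuals (the donor pool for the SD rule is empty)")
  }
  donor_sd <- colMeans(sds[donor, , drop = FALSE])
  imputed <- !donor
  if (any(imputed)) {
    sds[imputed, ] <- matrix(donor_sd, sum(imputed), ncol(m), byrow = TRUE)
  }

  out <- data.frame(species_id = levels(sp), n_individuals = n,
                    stringsAsFactors = FALSE)
  mcols <- as.data.frame(means)
  names(mcols) <- paste0("mean_", colnames(m))
  scols <- as.data.frame(sds)
  names(scols) <- paste0("sd_", colnames(m))
  out <- cbind(out, mcols, scols)
  out$sd_imputed <- imputed
  rownames(out) <- NULL
  class(out) <- c("species_trait_summary", "data.frame")
  out
}
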