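#' Build a uniform trait-space grid
#'
#' Discretizes the retained trait space into a uniform rectangular grid.
#' Per-axis bounds are the observed coordinate range expanded by
#' `buffer_fraction` of the range on each side, so Gaussian tails have room.
#'
#' @param coords Numeric matrix (individuals x axes) of projected coordinates,
#'   or anything coercible to one.
#' @param cells_per_dim Number of cells per axis (default 15; with 4 axes that
#'   is 50,625 cells).
#' @param buffer_fraction Fractional range expansion per side (default 0.05).
#' @return Object of class `trait_grid`: `dims`, `lower`, `upper`, `step`,
#'   `cells_per_dim`, `n_cells`, `cell_volume`, `centers` (list of per-axis
#'   cell-center vectors), `id` (fingerprint used to detect grid mismatches).
#' @export
build_grid <- function(coords, cells_per_dim = 15L, buffer_fraction = 0.05) {
  m <- as.matrix(coords)
  if (nrow(m) == 0L) stop("no coordinates supplied")
  if (cells_per_dim < 4L) stop("cells_per_dim must be >= 4")
  lo <- apply(m, 2L, min)
  hi <- apply(m, 2L, max)
  rng <- hi - lo
  if (any(rng == 0)) {
    stop("axis ", paste(which(rng == 0), collapse = ", "),
         " has zero range; supply a minimum-width override by jittering or ",
         "dropping the axis")
  }
  lower <- lo - buffer_fraction * rng
  upper <- hi + buffer_fraction * rng
  step <- (upper - lower) / cells_per_dim
  centers <- lapply(seq_along(lower), function(j) {
    lower[j] + (seq_len(cells_per_dim) - 0.5) * step[j]
  })
  g <- list(dims = ncol(m), lower = lower, upper = upper, step = step,
            cells_per_dim = as.integer(cells_per_dim),
            n_cells = as.integer(cells_per_dim)^ncol(m),
            cell_volume = prod(step), centers = centers)
  g$id <- paste(format(c(lower, upper, cells_per_dim), digits = 15L),
                collapse = "|")
  class(g) <- "trait_grid"
  g
}

#' @export
print.trait_grid <- function(x, ...) {
  cat("Trait grid:", x$dims, "axes x", x$cells_per_dim, "cells =",
      x$n_cells, "cells; cell volume", signif(x$cell_volume, 4L), "\n")
  invisible(x)
}

# density of an axis-aligned Gaussian at all cell centers, as a dense vector
# over the grid; axis 1 varies fastest
gaussian_cell_density <- function(grid, mean, sd) {
  dens <- 1
  for (j in seq_len(grid$dims)) {
    dens <- as.vector(outer(dens, stats::dnorm(grid$centers[[j]], mean[j], sd[j])))
  }
  dens
}

#' Species-level trait probability distribution
#'
#' Evaluates an axis-aligned multivariate Gaussian (mean and per-axis SD from
#' a [summarize_species()] row) at the grid cell centers, normalizes it to a
#' probability distribution, and trims it to its highest-density region: cells
#' are ranked by probability (ties broken by cell index) and the smallest set
#' holding at least `trim_mass` of the mass is kept, then renormalized.
#'
#' @param summary One row of a `species_trait_summary`, or a list/vector pair:
#'   alternatively supply `mean` and `sd` directly.
#' @param grid A `trait_grid`.
#' @param trim_mass Mass of the retained high-density region, in (0.5, 1]
#'   (default 0.99). `trim_mass = 1` keeps every nonzero-density cell.
#' @param mean,sd Optional explicit per-axis mean and SD vectors (used instead
#'   of `summary`).
#' @return Object of class `species_tpd`: `species_id`, `prob` (dense vector
#'   over the grid summing to 1), `grid_id`.
#' @export
species_tpd <- function(summary = NULL, grid, trim_mass = 0.99,
                        mean = NULL, sd = NULL) {
  if (is.null(mean)) {
    row <- as.data.frame(summary)
    mean <- as.numeric(row[1L, grep("^mean_", names(row))])
    sd_cols <- setdiff(grep("^sd_", names(row), value = TRUE), "sd_imputed")
    sd <- as.numeric(row[1L, sd_cols])
    species_id <- as.character(row$species_id[1L])
  } else {
    species_id <- NA_character_
  }
  if (length(mean) != grid$dims || length(sd) != grid$dims) {
    stop("mean/sd dimension does not match grid")
  }
  if (any(sd <= 0)) stop("axis SDs must be positive")
  if (trim_mass <= 0.5 || trim_mass > 1) stop("trim_mass must be in (0.5, 1]")

  dens <- gaussian_cell_density(grid, mean, sd)
  total <- sum(dens)
  if (total * grid$cell_volume < 1e-6) {
    stop("virtually all probability mass falls outside the grid; ",
         "enlarge the bounds (buffer_fraction) or check the coordinates")
  }
  p <- dens / total
  p <- trim_to_hdr(p, trim_mass)
  structure(list(species_id = species_id, prob = p, grid_id = grid$id),
            class = "species_tpd")
}

# keep the highest-probability cells until >= trim_mass is covered; ties by
# cell index; renormalize
trim_to_hdr <- function(p, trim_mass) {
  if (trim_mass >= 1) return(p / sum(p))
  ord <- order(-p, seq_along(p))
  cum <- cumsum(p[ord])
  k <- which(cum >= trim_mass)[1L]
  keep <- ord[seq_len(k)]
  out <- numeric(length(p))
  out[keep] <- p[keep]
  out / sum(out)
}

#' Community-level trait probability distribution
#'
#' The weighted mixture of the species-level distributions of a community,
#' with weights renormalized to sum to one (weights are typically relative
#' occurrence frequencies) and the result renormalized to absorb trimming
#' round-off.
#'
#' @param tpds List of `species_tpd` objects sharing one grid.
#' @param weights Non-negative weights, at least one positive.
#' @param site_id Optional label.
#' @return Object of class `community_tpd`: `site_id`, `prob`, `species_ids`,
#'   `weights` (renormalized), `grid_id`.
#' @export
community_tpd <- function(tpds, weights, site_id = NA_character_) {
  if (length(tpds) == 0L) stop("no species distributions supplied")
  if (length(weights) != length(tpds)) stop("one weight per species required")
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be non-negative with at least one positive")
  }
  gid <- tpds[[1L]]$grid_id
  ok <- vapply(tpds, function(t) identical(t$grid_id, gid), logical(1L))
  if (!all(ok)) stop("species distributions are not on the same grid")
  w <- weights / sum(weights)
  p <- numeric(length(tpds[[1L]]$prob))
  for (i in seq_along(tpds)) p <- p + w[i] * tpds[[i]]$prob
  p <- p / sum(p)
  structure(list(
    site_id = site_id, prob = p,
    species_ids = vapply(tpds, function(t) t$species_id, character(1L)),
    weights = w, grid_id = gid
  ), class = "community_tpd")
}

tpd_prob <- function(x) {
  if (inherits(x, "species_tpd") || inherits(x, "community_tpd")) x$prob
  else as.numeric(x)
}

tpd_grid_id <- function(x) {
  if (inherits(x, "species_tpd") || inherits(x, "community_tpd")) x$grid_id
  else NA_character_
}

#' Overlap between two trait probability distributions
#'
#' The shared probability mass `sum(min(p, q))` over the common grid: 1 for
#' identical distributions, 0 for disjoint supports. `1 - overlap` is the
#' functional dissimilarity used by [rao_q()] and the overlap mode of
#' [functional_beta()].
#'
#' @param p,q `species_tpd`/`community_tpd` objects or bare probability
#'   vectors on the same grid.
#' @return Overlap in `[0, 1]`.
#' @export
tpd_overlap <- function(p, q) {
  gp <- tpd_grid_id(p); gq <- tpd_grid_id(q)
  if (!is.na(gp) && !is.na(gq) && !identical(gp, gq)) {
    stop("distributions are not on the same grid")
  }
  pv <- tpd_prob(p); qv <- tpd_prob(q)
  if (length(pv) != length(qv)) stop("distributions are not on the same grid")
  sum(pmin(pv, qv))
}

#' Pairwise functional dissimilarity matrix between species distributions
#'
#' @param tpds List of `species_tpd` objects on one grid.
#' @return Symmetric matrix of `1 - overlap`, zero diagonal, labelled by
#'   species id.
#' @export
tpd_dissimilarity <- function(tpds) {
  n <- length(tpds)
  m <- matrix(0, n, n)
  ids <- vapply(tpds, function(t) t$species_id, character(1L))
  if (n > 1L) {
    probs <- lapply(tpds, tpd_prob)
    gid <- tpds[[1L]]$grid_id
    for (i in seq_len(n - 1L)) {
      if (!identical(tpds[[i + 1L]]$grid_id, gid)) {
        stop("distributions are not on the same grid")
      }
      for (j in seq.int(i + 1L, n)) {
        d <- 1 - sum(pmin(probs[[i]], probs[[j]]))
        m[i, j] <- d
        m[j, i] <- d
      }
    }
  }
  dimnames(m) <- list(ids, ids)
  m
}
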