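#' Species richness of one community
#'
#' @param counts Non-negative occurrence counts (one per species).
#' @return Number of species with a positive count.
#' @export
species_richness <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("negative occurrence counts")
  sum(counts > 0)
}

#' Community weighted mean traits
#'
#' Abundance-weighted mean trait vector of a community, on the raw trait
#' scale (mm). Weights are relative occurrence frequencies and are
#' renormalized internally, so the CWM is invariant to a uniform rescaling
#' of counts.
#'
#' @param species_trait_means Species x traits matrix of raw-scale per-species
#'   mean traits, with species ids as rownames.
#' @param weights Named or positionally matched non-negative weights (e.g.
#'   occurrence counts) for the species present.
#' @param species Optional species ids selecting/ordering rows of
#'   `species_trait_means`.
#' @return Named trait-mean vector.
#' @export
community_weighted_mean <- function(species_trait_means, weights,
                                    species = NULL) {
  m <- as.matrix(species_trait_means)
  if (!is.null(species)) {
    miss <- setdiff(species, rownames(m))
    if (length(miss) > 0L) {
      stop("species present in the community but absent from the trait ",
           "table: ", paste(miss, collapse = ", "))
    }
    m <- m[species, , drop = FALSE]
  }
  if (length(weights) != nrow(m)) stop("one weight per species required")
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be non-negative with at least one positive")
  }
  w <- weights / sum(weights)
  colSums(m * w)
}

#' Functional richness (FRic)
#'
#' The volume of trait space occupied by a community: the number of cells in
#' the support of its trait probability distribution times the cell volume.
#' Species-level distributions are already trimmed to their high-density
#' region when built (see [species_tpd()]), so the community support is the
#' union of the species' high-density regions.
#'
#' @param tpdc A `community_tpd` (or `species_tpd` for a single species).
#' @param grid The `trait_grid` the distribution lives on.
#' @return Occupied volume (product of standardized-axis units).
#' @export
functional_richness <- function(tpdc, grid) {
  p <- tpd_prob(tpdc)
  gid <- tpd_grid_id(tpdc)
  if (!is.na(gid) && !identical(gid, grid$id)) stop("grid mismatch")
  n_support <- sum(p > 0)
  if (n_support == 0L) stop("empty support: distribution has no mass on the grid")
  n_support * grid$cell_volume
}

#' Functional redundancy (FRed)
#'
#' Mean species-overlap depth of the community minus one: with `M(cell)` the
#' number of contributing species whose trimmed distribution is positive in a
#' cell, `FRed = sum(TPDc * M) - 1`. A single-species community scores 0; `k`
#' species with identical distributions score `k - 1`; species with disjoint
#' trait regions score 0. Bounded by `richness - 1`.
#'
#' @param tpdc The `community_tpd`.
#' @param tpds List of the contributing `species_tpd` objects.
#' @return Non-negative redundancy value.
#' @export
functional_redundancy <- function(tpdc, tpds) {
  gid <- tpd_grid_id(tpdc)
  p <- tpd_prob(tpdc)
  m <- numeric(length(p))
  for (t in tpds) {
    if (!identical(t$grid_id, gid)) stop("grid mismatch")
    m <- m + (t$prob > 0)
  }
  sum(p * m) - 1
}

#' Rao's quadratic entropy
#'
#' Expected functional dissimilarity between two randomly drawn members of
#' the community: `Q = sum_ij w_i w_j d_ij` with `d_ij = 1 - overlap` of the
#' species' trait probability distributions and `w` relative occurrence
#' frequencies. Bounded above by `1 - sum(w^2)`.
#'
#' @param tpds List of contributing `species_tpd` objects (ignored when
#'   `dissim` is supplied).
#' @param weights Non-negative weights, renormalized internally.
#' @param dissim Optional precomputed dissimilarity matrix for the same
#'   species (see [tpd_dissimilarity()]); avoids recomputing overlaps when
#'   many communities share a species pool.
#' @return Rao's Q in `[0, 1)`.
#' @export
rao_q <- function(tpds = NULL, weights, dissim = NULL) {
  if (is.null(dissim)) {
    if (is.null(tpds)) stop("supply tpds or a dissimilarity matrix")
    dissim <- tpd_dissimilarity(tpds)
  }
  if (length(weights) != nrow(dissim)) stop("one weight per species required")
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be non-negative with at least one positive")
  }
  w <- weights / sum(weights)
  as.numeric(t(w) %*% dissim %*% w)
}
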