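#' Sorensen/Simpson pairwise dissimilarity partition
#'
#' Baselga's partition of pairwise dissimilarity for one site pair described
#' by incidence counts: `a` shared, `b` unique to the first site, `c` unique
#' to the second. Total dissimilarity is Sorensen
#' `beta_sor = (b + c) / (2a + b + c)`; the turnover component is Simpson
#' `beta_sim = min(b, c) / (a + min(b, c))` (0 when the denominator is 0);
#' the nestedness-resultant component is their difference. The same partition
#' is applied to grid cells by the volume mode of [functional_beta()].
#'
#' @param a,b,c Non-negative incidence counts; not all zero.
#' @return Named vector `c(total, turnover, nested)`, each in `[0, 1]`, with
#'   `total = turnover + nested`.
#' @export
baselga_pair <- function(a, b, c) {
  a <- unname(a); b <- unname(b); c <- unname(c)
  if (a < 0 || b < 0 || c < 0) stop("incidence counts must be non-negative")
  if (a + b + c == 0) stop("empty pair: a + b + c must be positive")
  total <- (b + c) / (2 * a + b + c)
  mn <- min(b, c)
  turnover <- if (a + mn == 0) 0 else mn / (a + mn)
  c(total = total, turnover = turnover, nested = total - turnover)
}

beta_matrices <- function(total, turnover, nested, flavor, sites) {
  dimnames(total) <- dimnames(turnover) <- dimnames(nested) <-
    list(sites, sites)
  structure(list(total = total, turnover = turnover, nested = nested,
                 flavor = flavor, sites = sites),
            class = "beta_matrices")
}

#' @export
print.beta_matrices <- function(x, ...) {
  cat(x$flavor, "beta diversity over", length(x$sites), "sites;",
      "mean total", sprintf("%.3f", mean(x$total[upper.tri(x$total)])), "\n")
  invisible(x)
}

#' Taxonomic beta diversity between all site pairs
#'
#' Presence/absence Sorensen dissimilarity with its Simpson turnover and
#' nestedness-resultant components, for every site pair of an occurrence
#' matrix.
#'
#' @param comm Site x species matrix of occurrence counts (rownames = sites).
#' @return A `beta_matrices` object (flavor "taxonomic") holding three
#'   symmetric zero-diagonal matrices: `total`, `turnover`, `nested`.
#' @export
taxonomic_beta <- function(comm) {
  m <- as.matrix(comm)
  if (nrow(m) < 2L) stop("need at least 2 sites")
  if (any(m < 0)) stop("negative occurrence counts")
  pa <- (m > 0) * 1
  empty <- rowSums(pa) == 0
  if (any(empty)) {
    stop("site(s) with zero species: ",
         paste(rownames(m)[empty], collapse = ", "))
  }
  shared <- pa %*% t(pa)                   # a for every pair
  rich <- rowSums(pa)
  n <- nrow(m)
  total <- turnover <- nested <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      comp <- baselga_pair(shared[i, j], rich[i] - shared[i, j],
                           rich[j] - shared[i, j])
      total[i, j] <- total[j, i] <- comp["total"]
      turnover[i, j] <- turnover[j, i] <- comp["turnover"]
      nested[i, j] <- nested[j, i] <- comp["nested"]
    }
  }
  beta_matrices(total, turnover, nested, "taxonomic",
                rownames(m) %||% as.character(seq_len(n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Functional beta diversity between all site pairs
#'
#' Pairwise functional dissimilarity between community trait probability
#' distributions, partitioned into turnover and nestedness components.
#'
#' Two modes are provided and labelled, because the partition of functional
#' dissimilarity is not unique:
#' \describe{
#'   \item{volume (default)}{Occupied grid cells play the role of species:
#'     per pair, `a` = cells in both supports, `b`/`c` = cells unique to each,
#'     fed to [baselga_pair()]. This mirrors the volume-based functional beta
#'     family.}
#'   \item{overlap}{`total = 1 - sum(min(p, q))`;
#'     `nested = total * |P_A - P_B| / (P_A + P_B)` where `P_X` is X's mass on
#'     cells outside the other's support (nested = 0 when both are 0);
#'     `turnover = total - nested`.}
#' }
#'
#' @param tpdcs List of `community_tpd` objects on one grid.
#' @param mode `"volume"` or `"overlap"`.
#' @return A `beta_matrices` object (flavor "functional").
#' @export
functional_beta <- function(tpdcs, mode = c("volume", "overlap")) {
  mode <- match.arg(mode)
  n <- length(tpdcs)
  if (n < 2L) stop("need at least 2 communities")
  gid <- tpdcs[[1L]]$grid_id
  if (!all(vapply(tpdcs, function(t) identical(t$grid_id, gid), logical(1L)))) {
    stop("communities are not on the same grid")
  }
  sites <- vapply(tpdcs, function(t) as.character(t$site_id), character(1L))
  probs <- lapply(tpdcs, tpd_prob)
  total <- turnover <- nested <- matrix(0, n, n)

  if (mode == "volume") {
    supp <- do.call(rbind, lapply(probs, function(p) p > 0)) * 1
    shared <- supp %*% t(supp)
    vol <- rowSums(supp)
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        comp <- baselga_pair(shared[i, j], vol[i] - shared[i, j],
                             vol[j] - shared[i, j])
        total[i, j] <- total[j, i] <- comp["total"]
        turnover[i, j] <- turnover[j, i] <- comp["turnover"]
        nested[i, j] <- nested[j, i] <- comp["nested"]
      }
    }
  } else {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        p <- probs[[i]]; q <- probs[[j]]
        tot <- 1 - sum(pmin(p, q))
        pa <- sum(p[q == 0])   # A's mass outside B's support
        pb <- sum(q[p == 0])
        nes <- if (pa + pb == 0) 0 else tot * abs(pa - pb) / (pa + pb)
        total[i, j] <- total[j, i] <- tot
        nested[i, j] <- nested[j, i] <- nes
        turnover[i, j] <- turnover[j, i] <- tot - nes
      }
    }
  }
  beta_matrices(total, turnover, nested, "functional", sites)
}

#' Bray-Curtis distances between sites
#'
#' Abundance-based compositional distance,
#' `BC(x, y) = 1 - 2 sum(min(x, y)) / (sum(x) + sum(y))`, computed with
#' `vegan::vegdist`. Used for the spatial-autocorrelation (Mantel) check.
#'
#' @param comm Site x species occurrence-count matrix.
#' @return Symmetric distance matrix with site labels.
#' @export
bray_curtis <- function(comm) {
  m <- as.matrix(comm)
  if (any(m < 0)) stop("negative occurrence counts")
  if (sum(rowSums(m) == 0) >= 2L) {
    stop("two or more all-zero sites: Bray-Curtis undefined for such pairs")
  }
  as.matrix(vegan::vegdist(m, method = "bray"))
}
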