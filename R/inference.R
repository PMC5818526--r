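#' Compare an index between habitat classes
#'
#' One-way comparison of a per-site index across habitat groups, with the
#' test chosen by a normality gate: Shapiro-Wilk on the ANOVA residuals. When
#' the residuals pass (p >= `gate_alpha`), one-way ANOVA with Tukey HSD
#' pairwise contrasts is used; otherwise Kruskal-Wallis with Dunn's rank-based
#' pairwise z tests, Holm-adjusted. Pairwise results are summarized as a
#' compact letter display (groups sharing a letter do not differ at `alpha`).
#'
#' @param values Numeric per-site index.
#' @param groups Habitat labels (coerced to factor).
#' @param alpha Pairwise significance level for the letters (default 0.05).
#' @param gate_alpha Shapiro-Wilk gate level (default 0.05).
#' @return Object of class `group_comparison`: `method`
#'   ("anova+tukey" or "kruskal+dunn"), `statistic`, `p_value`,
#'   `shapiro_p`, `pairwise` (data.frame with group pair and adjusted p),
#'   `letters` (named per-group), `group_means`.
#' @export
compare_groups <- function(values, groups, alpha = 0.05, gate_alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) {
    stop("every group needs at least 2 observations")
  }
  fit <- stats::aov(values ~ groups)
  sw <- stats::shapiro.test(stats::residuals(fit))

  if (sw$p.value >= gate_alpha) {
    tab <- summary(fit)[[1L]]
    statistic <- tab[1L, "F value"]
    p_value <- tab[1L, "Pr(>F)"]
    tk <- stats::TukeyHSD(fit)$groups
    pairs <- rownames(tk)
    pw <- data.frame(
      group1 = sub("-.*$", "", pairs),
      group2 = sub("^[^-]*-", "", pairs),
      p_adj = tk[, "p adj"],
      stringsAsFactors = FALSE
    )
    method <- "anova+tukey"
  } else {
    kw <- stats::kruskal.test(values, groups)
    statistic <- unname(kw$statistic)
    p_value <- kw$p.value
    pw <- dunn_pairwise(values, groups)
    method <- "kruskal+dunn"
  }
  rownames(pw) <- NULL
  letters <- cld_letters(levels(groups), pw, alpha)

  structure(list(
    method = method, statistic = statistic, p_value = p_value,
    shapiro_p = sw$p.value, pairwise = pw, letters = letters,
    group_means = tapply(values, groups, mean)
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison (", x$method, "): statistic = ",
      sprintf("%.4g", x$statistic), ", p = ", sprintf("%.4g", x$p_value),
      " (Shapiro-Wilk gate p = ", sprintf("%.3g", x$shapiro_p), ")\n",
      sep = "")
  cat("Letters:", paste(names(x$letters), x$letters, sep = "=",
                        collapse = "  "), "\n")
  invisible(x)
}

# Dunn's post-hoc z tests on ranks with tie correction, Holm-adjusted
dunn_pairwise <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  rbar <- tapply(r, groups, mean)
  ng <- table(groups)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2L)
  p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ng[[i]] + 1 / ng[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z))
  }
  data.frame(group1 = pairs[2L, ], group2 = pairs[1L, ],
             p_adj = stats::p.adjust(p, "holm"), stringsAsFactors = FALSE)
}

# compact letter display by insert-and-absorb on a pairwise significance set
cld_letters <- function(lev, pairwise, alpha) {
  sig <- pairwise[pairwise$p_adj < alpha, , drop = FALSE]
  cols <- list(lev)  # start: one letter covering everything
  for (k in seq_len(nrow(sig))) {
    g1 <- sig$group1[k]; g2 <- sig$group2[k]
    new_cols <- list()
    for (col in cols) {
      if (g1 %in% col && g2 %in% col) {
        new_cols <- c(new_cols, list(setdiff(col, g1)), list(setdiff(col, g2)))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    # absorb columns that are subsets of another
    keep <- rep(TRUE, length(new_cols))
    for (i in seq_along(new_cols)) {
      for (j in seq_along(new_cols)) {
        if (i != j && keep[j] &&
            all(new_cols[[i]] %in% new_cols[[j]]) &&
            (length(new_cols[[i]]) < length(new_cols[[j]]) || i > j)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    cols <- new_cols[keep]
  }
  out <- stats::setNames(rep("", length(lev)), lev)
  for (i in seq_along(cols)) {
    out[cols[[i]]] <- paste0(out[cols[[i]]], letters[i])
  }
  out
}

check_dist_matrix <- function(d, what = "distance matrix") {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-10) {
    stop(what, " must be symmetric")
  }
  if (any(diag(m) != 0)) stop(what, " must have a zero diagonal")
  if (any(m < 0)) stop(what, " must be non-negative")
  m
}

permutation_result <- function(name, observed, p, n_perm, seed,
                               extra = list()) {
  structure(c(list(statistic = name, observed = observed, p_value = p,
                   n_permutations = n_perm, seed = seed), extra),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(x$statistic, "=", sprintf("%.4f", x$observed))
  if (!is.null(x$r_squared)) cat(", R2 =", sprintf("%.3f", x$r_squared))
  cat(", p =", format(x$p_value), "(", x$n_permutations, "permutations )\n")
  invisible(x)
}

#' One-factor PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix with
#' a single grouping factor. Sums of squares follow the distance-based
#' identity `SS_total = sum_{i<j} d_ij^2 / N` and
#' `SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g`; the pseudo-F statistic is
#' `(SS_among / (g - 1)) / (SS_within / (N - g))`, and significance comes
#' from permuting the group labels with the add-one rule, so p is never 0.
#'
#' @param d Distance matrix (`dist` or symmetric matrix, zero diagonal).
#' @param groups Group labels, each group of size >= 2.
#' @param n_perm Number of label permutations (default 9999).
#' @param seed Integer seed making the permutation stream reproducible.
#' @return A `permutation_test` with `observed` (pseudo-F), `r_squared`,
#'   `p_value`, `n_permutations`, `seed`.
#' @export
permanova <- function(d, groups, n_perm = 9999L, seed = 1L) {
  m <- check_dist_matrix(d)
  groups <- factor(groups)
  n <- nrow(m)
  if (length(groups) != n) stop("one group label per site required")
  if (any(table(groups) < 2L)) stop("every group needs at least 2 sites")
  g <- nlevels(groups)
  d2 <- m^2
  ss_total <- sum(d2[upper.tri(d2)]) / n

  codes <- as.integer(groups)
  ss_within_of <- function(lab_matrix) {
    # lab_matrix: n_rows x n of integer codes; returns SS_within per row
    ssw <- numeric(nrow(lab_matrix))
    for (k in seq_len(g)) {
      ind <- (lab_matrix == k) * 1
      nk <- sum(codes == k)
      ssw <- ssw + rowSums((ind %*% d2) * ind) / (2 * nk)
    }
    ssw
  }
  f_of <- function(ssw) ((ss_total - ssw) / (g - 1)) / (ssw / (n - g))

  f_obs <- f_of(ss_within_of(matrix(codes, 1L)))
  set.seed(seed)
  perms <- matrix(0L, n_perm, n)
  for (i in seq_len(n_perm)) perms[i, ] <- codes[sample.int(n)]
  f_perm <- f_of(ss_within_of(perms))
  p <- (sum(f_perm >= f_obs) + 1) / (n_perm + 1)

  permutation_result(
    "pseudo-F", f_obs, p, n_perm, seed,
    extra = list(r_squared = (ss_total - ss_within_of(matrix(codes, 1L))) /
                   ss_total)
  )
}

#' Moran's I with Monte-Carlo inference
#'
#' Classical Moran's I of a per-site variable under inverse-distance spatial
#' weights (`w_ij = 1 / d_ij`, zero diagonal). Significance is two-sided
#' Monte Carlo: values are permuted over sites, the smaller tail probability
#' (add-one rule) is doubled and capped at 1. The expected value under the
#' null is `-1 / (n - 1)`.
#'
#' @param values Per-site variable (non-constant).
#' @param coords Site coordinate matrix (n x 2, projected units).
#' @param n_perm Number of permutations (default 9999).
#' @param seed Integer seed.
#' @param weights Optional explicit spatial weight matrix (zero diagonal)
#'   overriding the inverse-distance default, e.g. a row-standardized one.
#' @return A `permutation_test` with `observed` (I), `p_value`,
#'   `perm_mean` (mean permuted I), `expected` (`-1/(n-1)`).
#' @export
morans_i <- function(values, coords, n_perm = 9999L, seed = 1L,
                     weights = NULL) {
  x <- as.numeric(values)
  xy <- as.matrix(coords)
  n <- length(x)
  if (n < 4L) stop("need at least 4 sites")
  if (stats::sd(x) == 0) stop("variable is constant: Moran's I undefined")
  if (is.null(weights)) {
    dm <- as.matrix(stats::dist(xy))
    if (any(dm[upper.tri(dm)] == 0)) {
      stop("duplicate coordinates: inverse-distance weights undefined")
    }
    w <- 1 / dm
    diag(w) <- 0
  } else {
    w <- as.matrix(weights)
  }
  s0 <- sum(w)
  z <- x - mean(x)
  denom <- sum(z^2)
  i_of_rows <- function(zm) (n / s0) * rowSums((zm %*% w) * zm) / denom
  i_obs <- i_of_rows(matrix(z, 1L))

  set.seed(seed)
  perms <- matrix(0, n_perm, n)
  for (i in seq_len(n_perm)) perms[i, ] <- z[sample.int(n)]
  i_perm <- i_of_rows(perms)
  p_up <- (sum(i_perm >= i_obs) + 1) / (n_perm + 1)
  p_lo <- (sum(i_perm <= i_obs) + 1) / (n_perm + 1)
  p <- min(1, 2 * min(p_up, p_lo))

  permutation_result("Moran I", i_obs, p, n_perm, seed,
                     extra = list(perm_mean = mean(i_perm),
                                  expected = -1 / (n - 1)))
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation between the lower triangles of two distance matrices
#' over the same sites; one-sided (greater) significance by permuting the
#' site order of the second matrix, with the add-one rule.
#'
#' @param dist_a,dist_b Symmetric matrices (or `dist`) over the same sites in
#'   the same order.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Integer seed.
#' @return A `permutation_test` with `observed` (Mantel r) and `p_value`.
#' @export
mantel_test <- function(dist_a, dist_b, n_perm = 9999L, seed = 1L) {
  a <- check_dist_matrix(dist_a, "dist_a")
  b <- check_dist_matrix(dist_b, "dist_b")
  if (nrow(a) != nrow(b)) stop("matrices must cover the same sites")
  n <- nrow(a)
  lt <- lower.tri(a)
  av <- a[lt]
  if (stats::sd(av) == 0 || stats::sd(b[lt]) == 0) {
    stop("constant lower triangle: Mantel r undefined")
  }
  r_obs <- stats::cor(av, b[lt])
  set.seed(seed)
  r_perm <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    idx <- sample.int(n)
    r_perm[i] <- stats::cor(av, b[idx, idx][lt])
  }
  p <- (sum(r_perm >= r_obs) + 1) / (n_perm + 1)
  permutation_result("Mantel r", r_obs, p, n_perm, seed)
}
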