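# Shared fixtures, built in code.

# tiny deterministic trait table: n_per species, means spread apart
make_trait_table <- function(n_species = 5, n_per = 8, seed = 101,
                             sites = c("siteA", "siteB")) {
  set.seed(seed)
  recs <- lapply(seq_len(n_species), function(s) {
    base <- exp(rnorm(8, mean = log(c(0.8, 0.65, 0.2, 0.15, 0.55, 1.2, 1.5,
                                      0.25)), sd = 0.3))
    tv <- matrix(abs(rnorm(n_per * 8, rep(base, each = n_per),
                           rep(base * 0.08, each = n_per))) + 1e-6,
                 n_per, 8)
    colnames(tv) <- trait_names()
    data.frame(species_id = sprintf("sp%02d", s),
               site_id = rep_len(sites, n_per), as.data.frame(tv),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, recs)
  df <- cbind(individual_id = sprintf("i%04d", seq_len(nrow(df))), df)
  validate_trait_table(df)
}

# 1-D grid over [lo, hi] for analytic Gaussian checks
grid_1d <- function(lo = -6, hi = 6, cells = 400) {
  build_grid(matrix(c(lo, hi), ncol = 1), cells_per_dim = cells,
             buffer_fraction = 0)
}

# small simulated dataset for pipeline-level tests (cheap grid downstream)
small_config <- function(seed = 11, ...) {
  simulation_config(
    seed = seed,
    n_sites = c(forest = 4L, eucalyptus_unmanaged = 3L,
                eucalyptus_7y = 3L, eucalyptus_28y = 3L),
    pool_size = 30L, ...)
}

small_pipeline_config <- function(n_perm = 199L, cells_per_dim = 25L, ...) {
  pipeline_config(retained_axes = 2L, cells_per_dim = cells_per_dim,
                  n_perm = n_perm, ...)
}
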