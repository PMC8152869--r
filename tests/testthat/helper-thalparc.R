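# Shared fixtures, built once per test run. The coarse (level-2, 320
# direction) basis is enough for most module tests; the default level-3
# basis is used where quadrature accuracy is itself under test.

basis2 <- sh_basis(6, tessellation_level = 2)
basis3 <- sh_basis(6, tessellation_level = 3)

# small default-geometry phantom on the coarse basis
small_phantom <- function(seed = 1, snr = NULL, grid = c(16, 20, 12)) {
  cfg <- if (is.null(snr))
    phantom_config(grid_shape = grid, tessellation_level = 2, seed = seed)
  else
    phantom_config(grid_shape = grid, tessellation_level = 2, seed = seed,
                   snr = snr)
  make_phantom(cfg, basis = basis2)
}

# tiny cohort used by pipeline/io tests
tiny_cohort <- function(seed = 7, n_targets = 5)
  make_cohort(n_hc = 4, n_mcs = 3, n_vs = 3,
              phantom = phantom_config(grid_shape = c(16, 20, 12),
                                       tessellation_level = 2, seed = seed),
              effects = effect_config(), seed = seed, n_targets = n_targets)

# random unit vectors
runit <- function(n) {
  m <- matrix(stats::rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}
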