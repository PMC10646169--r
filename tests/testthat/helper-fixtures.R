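# Shared fixtures, built in code. Heavier objects are created once per test
# run and memoised in this environment.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# 20 x 20 checkerboard raster with 100-m cells
checkerboard_raster <- function(n = 20, cs = 100) {
  v <- outer(seq_len(n), seq_len(n), function(i, j) (i + j) %% 2)
  covariate_raster(v, cs, 0, 0, name = "checker", year = 2020L)
}

# brute-force buffer mean: exhaustive loop over all cells (the oracle)
brute_buffer_mean <- function(raster, ex, ny, radius) {
  cc <- cell_centers(raster)
  tot <- 0; n <- 0
  for (i in seq_len(nrow(raster$values))) {
    for (j in seq_len(ncol(raster$values))) {
      if ((cc$x[j] - ex)^2 + (cc$y[i] - ny)^2 <= radius^2) {
        v <- raster$values[i, j]
        if (!is.na(v)) { tot <- tot + v; n <- n + 1 }
      }
    }
  }
  if (n == 0) NA_real_ else tot / n
}

# a tiny synthetic study reused by several files
tiny_study <- function() {
  fixture("tiny_study", function() {
    cfg <- sim_config(n_grids = 25, n_years = 3, n_bcrs = 2,
                      cell_size = 500, seed = 42)
    simulate_study(cfg)
  })
}

tiny_model_data <- function() {
  fixture("tiny_model_data", function() {
    st <- tiny_study()
    cfg <- model_config_from_sim(st, K = 8)
    suppressMessages(
      prepare_model_data(st$surveys, st$detections, st$stack_std, cfg))
  })
}

# a short fit on the tiny study (smoke-scale draws)
tiny_fit <- function() {
  fixture("tiny_fit", function() {
    run_mcmc(tiny_model_data(), iter = 150, warmup = 250, chains = 2,
             thin = 1, seed = 7)
  })
}

# build a buffer_stack directly from an array of values (unit helper)
stack_from_values <- function(values, radii, covariates,
                              grid_ids = NULL, years = 2020L) {
  ng <- dim(values)[1]
  if (is.null(grid_ids)) grid_ids <- paste0("g", seq_len(ng))
  buffer_stack(values, grid_ids, years, covariates, radii)
}
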