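# Small fixtures shared across tests. Everything is generated in code.

# a fast phantom: 32x32 high-res grid, short run
tiny_spec <- function(...) {
  args <- list(grid_hr = 32L, scale = 2L, n_volumes = 160L, tr = 0.5,
               region_a = list(semi_x = 4, semi_y = 5, center_y_offset = 0),
               region_b = list(semi_x = 4, semi_y = 5, center_y_offset = 0),
               n_slices_structural = 3L, seed = 42L)
  override <- list(...)
  args[names(override)] <- override
  do.call(phantom_spec, args)
}

tiny_design <- function(n_volumes = 160L, tr = 0.5)
  default_design(n_volumes, tr, block_s = 10, rest_s = 10)

# random functional series with given geometry
random_series <- function(nx = 6, ny = 6, ns = 1, nt = 30, tr = 0.5,
                          seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed(functional_series(array(rnorm(nx * ny * ns * nt, 100, 5),
                                     dim = c(nx, ny, ns, nt)), tr = tr))
}

# random binary mask as an (x, y, 1) array
random_mask <- function(nx = 8, ny = 8, p = 0.4) {
  array(runif(nx * ny) < p, dim = c(nx, ny, 1L))
}

# a cc_map built directly from a matrix of values (helper to test
# extraction without running the whole pipeline)
cc_map_from_values <- function(values, mask = NULL) {
  if (is.matrix(values)) dim(values) <- c(dim(values), 1L)
  if (is.null(mask)) mask <- array(TRUE, dim = dim(values))
  vals <- array(NA_real_, dim = dim(values))
  vals[mask] <- values[mask]
  structure(list(values = vals, mask = mask, task_label = "synthetic",
                 n_zero_variance = 0L), class = "cc_map")
}

# exact 2x nearest-neighbour upsample of a mask
upsample2_nn <- function(mask) {
  mask[rep(seq_len(nrow(mask)), each = 2), rep(seq_len(ncol(mask)), each = 2)]
}
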