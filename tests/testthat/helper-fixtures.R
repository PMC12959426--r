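# Shared fixtures: built in code, small enough for fast unit tests.

# a coarse phantom for tests that only need structure, not resolution
tiny_spec <- function(lesions = list()) {
  phantom_spec(grid_dim = c(32L, 32L, 16L), voxel_size = c(4.5, 4.5, 9),
               lesions = lesions)
}

# constant-value volume on a simple grid
const_volume <- function(value = 0, dim = c(8L, 8L, 8L),
                         voxel_size = c(1, 1, 1)) {
  volume(array(value, dim = dim), voxel_size = voxel_size)
}

# binary sphere on the grid of `template`, radius in mm about world center
centered_sphere <- function(template, radius) {
  w <- world_grid(template)
  with_data(template,
            array(as.numeric(w$x^2 + w$y^2 + w$z^2 <= radius^2),
                  dim = dim(template$data)))
}

# exhaustive two-sided signed-rank p-value over all 2^n sign assignments
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  ws <- as.matrix(signs) %*% r
  lower <- mean(ws <= w_obs + 1e-9)
  upper <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}
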