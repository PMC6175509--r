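# Small, fast phantom used throughout the unit tests (the acceptance tests
# use the package's full-size default geometry).
test_spec <- function(..., scar = list(scar_blob(center_deg = 100,
                                                 extent_deg = 80,
                                                 transmurality = 0.6))) {
  phantom_spec(lv_endo_radii = c(12, 12, 20), lv_epi_radii = c(19, 19, 28),
               margin_mm = 3, scar = scar, seed = 42, ...)
}

# cache expensive shared fixtures across test files (helpers are sourced
# once per test run)
.fixture_cache <- new.env(parent = emptyenv())
fixture <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

test_phantom <- function() {
  fixture("phantom", generate_phantom(test_spec(), truth_resolution_mm = 0.4))
}

test_model <- function() {
  fixture("model", {
    ph <- test_phantom()
    scar_pipeline(ph$volume, ph$contours)
  })
}

# evenly distributed points on a sphere (Fibonacci lattice)
fibonacci_sphere <- function(n, radius = 1, center = c(0, 0, 0)) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  sweep(radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta),
                       cos(phi)), 2, center, "+")
}

rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
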