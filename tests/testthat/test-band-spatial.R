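test_that("band power integrates exactly on simple shapes", {
  g <- 1:45
  n <- 3
  flat <- regional_spectra(matrix(1, n, length(g)), g)
  expect_equal(unname(band_power(flat, alpha_band())), rep(4, n))
  expect_equal(unname(band_power(flat, beta_band())), rep(12, n))
  # support entirely outside the band
  v <- matrix(0, 1, length(g))
  v[1, g >= 30] <- 5
  outside <- regional_spectra(v, g)
  expect_equal(unname(band_power(outside, alpha_band())), 0)
  # piecewise-linear toy: values (0,2,2,6,0) at 8..12 Hz; trapezoids by hand:
  # 1*(0+2)/2 + 1*(2+2)/2 + 1*(2+6)/2 + 1*(6+0)/2 = 1 + 2 + 4 + 3 = 10
  v2 <- matrix(0, 1, length(g))
  v2[1, match(8:12, g)] <- c(0, 2, 2, 6, 0)
  toy <- regional_spectra(v2, g)
  expect_equal(unname(band_power(toy, alpha_band())), 10)
  expect_error(band_power(flat, band_definition("hf", 40, 60)), "outside")
})

test_that("band edges between grid points are handled by interpolation", {
  g <- seq(1, 45, by = 2)                  # 8 and 12 Hz not on the grid
  flat <- regional_spectra(matrix(3, 2, length(g)), g)
  expect_equal(unname(band_power(flat, alpha_band())), rep(12, 2))
})

test_that("band presets match their conventions", {
  expect_equal(c(alpha_band()$lo, alpha_band()$hi), c(8, 12))
  expect_equal(c(beta_band()$lo, beta_band()$hi), c(13, 25))
  expect_equal(c(beta_band(wide = TRUE)$lo, beta_band(wide = TRUE)$hi),
               c(15, 30))
})

test_that("spatial correlation is Pearson across masked regions", {
  a <- c(3, 1, 4, 1, 5)
  expect_equal(spatial_correlation(a, a), 1.0)
  expect_equal(spatial_correlation(a, 2 * a + 3), 1.0)   # affine invariance
  b <- c(2, 7, 1, 8, 2)
  expect_equal(spatial_correlation(a, b), pearson_by_hand(a, b),
               tolerance = 1e-12)
  mask <- c(TRUE, TRUE, TRUE, TRUE, FALSE)
  expect_equal(spatial_correlation(a, b, mask),
               pearson_by_hand(a[1:4], b[1:4]), tolerance = 1e-12)
  expect_error(spatial_correlation(a, rep(1, 5)), "variance")
  expect_error(spatial_correlation(a[1:2], b[1:2]), "3 masked")
})

test_that("the zero-eigenvalue mode of a uniform connectome is flat", {
  conn <- generate_connectome("uniform", n = 10)
  p <- sgm_params(alpha = 1)   # lambda_1 = 0, uniform eigenvector
  pat <- eigenmode_band_pattern(conn, p, 1, alpha_band())
  expect_lt(diff(range(pat)) / mean(pat), 1e-8)
})

test_that("eigenmode band patterns are permutation-equivariant", {
  conn <- random_conn(n = 8, seed = 9)
  p <- optimized_params()
  perm <- c(4, 8, 1, 6, 2, 7, 5, 3)
  pconn <- connectome(conn$weights[perm, perm], conn$distances[perm, perm],
                      labels = conn$labels[perm])
  a <- eigenmode_band_pattern(conn, p, 3, alpha_band())
  b <- eigenmode_band_pattern(pconn, p, 3, alpha_band())
  expect_equal(unname(b), unname(a[perm]), tolerance = 1e-8)
})

test_that("complex mode responses add up to the full spectrum", {
  # magnitude of the cumulative complex sum over all modes must reproduce
  # the direct-inverse band pattern when the expansion is exact (Hermitian)
  conn <- random_conn(n = 10, sparsity = 0.2, seed = 12)
  p <- optimized_params()
  full <- direct_inverse_spectrum(conn, p, freq_grid(),
                                  normalization = "symmetric")
  ebp <- band_power(full, alpha_band())
  sel <- sorted_cumulative_selection(conn, p, ebp, alpha_band(),
                                     normalization = "symmetric")
  n <- n_regions(conn)
  expect_equal(sel$correlation_curve[n], 1.0, tolerance = 1e-8)
})

test_that("self-matched selection returns the matching mode first", {
  conn <- distance_conn(n = 30, sparsity = 0.4, seed = 11)
  p <- optimized_params()
  pat5 <- eigenmode_band_pattern(conn, p, 5, alpha_band())
  sel <- sorted_cumulative_selection(conn, p, pat5, alpha_band())
  expect_equal(sel$ordering[1], 5)
  expect_equal(sel$correlation_curve[1], 1.0, tolerance = 1e-10)
  expect_equal(sel$best_k, 1L)
  expect_equal(sel$best_r, 1.0, tolerance = 1e-10)
  # best_r can never fall below the first cumulative point
  expect_gte(sel$best_r, sel$correlation_curve[1])
})

test_that("unrelated permuted maps score well below a self-match", {
  conn <- distance_conn(n = 30, sparsity = 0.4, seed = 11)
  p <- optimized_params()
  pat5 <- eigenmode_band_pattern(conn, p, 5, alpha_band())
  null_r <- vapply(1:20, function(s) {
    perm <- with_seed(s, sample(n_regions(conn)))
    sorted_cumulative_selection(conn, p, pat5[perm], alpha_band())$best_r
  }, numeric(1))
  expect_lt(mean(null_r), 0.7)
})

test_that("selection curve peaks at a small interior subset and declines", {
  # empirical map built from a few modes plus regional noise: the sorted
  # cumulative curve should rise to an interior optimum, then degrade as
  # the remaining modes are added
  conn <- distance_conn(n = 30, sparsity = 0.4, seed = 11)
  p <- optimized_params()
  resp <- spectralgm:::mode_responses(conn, p, freq_grid(), "all",
                                      "degree", "tau_G")
  base <- band_power(regional_spectra(
    Mod(resp[, , 2] + resp[, , 5] + resp[, , 9]),
    freq_grid(), conn$labels), alpha_band())
  target <- with_seed(17, base * exp(rnorm(length(base), 0, 0.1)))
  sel <- sorted_cumulative_selection(conn, p, target, alpha_band())
  n <- n_regions(conn)
  expect_gt(sel$best_k, 1)
  expect_lt(sel$best_k, n)
  expect_lt(sel$best_k, 10)                      # few modes suffice
  expect_gt(sel$best_r, sel$correlation_curve[1]) # rises after k = 1
  expect_gt(sel$best_r, sel$correlation_curve[n] + 0.2)  # then declines
})
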