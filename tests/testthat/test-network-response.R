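# Sort complex values the same way the package orders eigenvalues, for
# comparing against independent oracles.
sort_complex <- function(z) {
  z[order(round(Mod(z), 9), round(Re(z), 9), round(Im(z), 9))]
}

# Characteristic-polynomial oracle: Faddeev-LeVerrier recursion for the
# coefficients, then polyroot. Independent of LAPACK's eigensolver.
charpoly_eigs <- function(A) {
  n <- nrow(A)
  M <- diag(1 + 0i, n)
  cs <- complex(n)
  AM <- A
  for (k in seq_len(n)) {
    cs[k] <- -sum(diag(AM)) / k
    M <- AM + diag(cs[k], n)
    AM <- A %*% M
  }
  polyroot(c(cs[n:1], 1 + 0i))
}

test_that("complex connectivity reduces to real weights without delays", {
  conn <- distance_conn(n = 8, seed = 2)
  expect_equal(complex_connectivity(conn, 0, 5), conn$weights + 0i)
  # huge conduction speed: delays vanish
  cc <- complex_connectivity(conn, 2 * pi * 40, 1e9)
  expect_equal(cc, conn$weights + 0i, tolerance = 1e-6)
})

test_that("delay phase follows d/(1000 v) with distances in mm", {
  w <- matrix(c(0, 2, 2, 0), 2, 2)
  d <- matrix(c(0, 50, 50, 0), 2, 2)
  conn <- connectome(w, d)
  cc <- complex_connectivity(conn, 2 * pi * 10, 5)
  # tau = 0.05 m / 5 m/s = 0.01 s; phase = -2*pi*10*0.01 = -0.2*pi
  expect_equal(cc[1, 2], 2 * exp(-0.2i * pi), tolerance = 1e-12)
  expect_equal(Arg(cc[1, 2]), -0.2 * pi, tolerance = 1e-12)
})

test_that("complex Laplacian limits: alpha = 0 and uniform closed form", {
  conn <- random_conn(n = 6, seed = 5)
  L <- complex_laplacian(conn, 2 * pi * 10, sgm_params(alpha = 0))
  expect_equal(unname(L), diag(6) + 0i, tolerance = 1e-12)
  # all-ones connectome (diagonal included), zero delays, alpha = 1:
  # eigenvalues exactly {0, 1 x (N-1)}
  u <- generate_connectome("uniform", n = 12)
  em <- laplacian_eigs(complex_laplacian(u, 0, sgm_params(alpha = 1)))
  expect_equal(Mod(em$values[1]), 0, tolerance = 1e-12)
  expect_equal(Mod(em$values[-1]), rep(1, 11), tolerance = 1e-12)
  # the zero mode is the uniform pattern
  u1 <- em$vectors[, 1]
  expect_lt(max(Mod(u1 - mean(u1))), 1e-10)
  # closed form holds at any alpha: {1 - alpha, 1 x (N-1)}
  em2 <- laplacian_eigs(complex_laplacian(u, 0, sgm_params(alpha = 0.4)))
  expect_equal(sort(Mod(em2$values)), c(0.6, rep(1, 11)), tolerance = 1e-12)
})

test_that("Laplacian eigenvalues match a characteristic-polynomial oracle", {
  conn <- random_conn(n = 6, sparsity = 0.2, seed = 11)
  conn <- connectome(conn$weights,
                     generate_connectome("distance", 6, 0, 11)$distances)
  L <- complex_laplacian(conn, 2 * pi * 10, optimized_params())
  em <- laplacian_eigs(L)
  oracle <- charpoly_eigs(L)
  expect_equal(sort_complex(em$values), sort_complex(oracle),
               tolerance = 1e-6)
})

test_that("eigendecomposition is deterministic, unit-norm, residual-checked", {
  em <- laplacian_eigs(diag(5) + 0i)
  expect_equal(em$values, rep(1 + 0i, 5))
  set.seed(8)
  M <- matrix(complex(real = rnorm(25), imaginary = rnorm(25)), 5, 5)
  em <- laplacian_eigs(M)
  for (i in 1:5) {
    u <- em$vectors[, i]
    expect_equal(sum(Mod(u)^2), 1, tolerance = 1e-10)
    res <- sqrt(sum(Mod(M %*% u - em$values[i] * u)^2))
    expect_lt(res, 1e-8 * max(1, max(Mod(M))))
    k <- which.max(Mod(u))
    expect_equal(Im(u[k]), 0, tolerance = 1e-10)   # phase convention
    expect_gt(Re(u[k]), 0)
  }
  expect_true(all(diff(Mod(em$values)) >= -1e-12)) # ascending magnitude
  em2 <- laplacian_eigs(M)
  expect_identical(em$vectors, em2$vectors)
})

test_that("eigenmode response limits and direct evaluation", {
  p <- sgm_params(tau_G = 0.0061)
  w <- 2 * pi * 15
  expect_equal(eigenmode_response(0 + 0i, w, p), 1 / (1i * w),
               tolerance = 1e-12)
  # omega -> 0 with real lambda: h -> tau_G / lambda since F(0) = 1
  expect_equal(eigenmode_response(0.5 + 0i, 1e-9, p), 0.0061 / 0.5 + 0i,
               tolerance = 1e-6)
  Fv <- (1 / 0.0061^2) / (1i * w + 1 / 0.0061)^2
  expect_equal(eigenmode_response(1 + 0i, w, p),
               1 / (1i * w + Fv / 0.0061), tolerance = 1e-12)
})

test_that("uncoupled network produces region-identical spectra", {
  conn <- random_conn(n = 9, seed = 6)
  sp <- regional_spectrum(conn, sgm_params(alpha = 0), freq_grid(),
                          num_modes = "all")
  expect_lt(max(apply(sp$values, 2, function(col) diff(range(col)))),
            1e-10 * max(sp$values))
})

test_that("regional spectrum is equivariant under region permutation", {
  conn <- random_conn(n = 8, seed = 9)
  p <- optimized_params()
  perm <- c(3, 1, 7, 2, 8, 5, 4, 6)
  pconn <- connectome(conn$weights[perm, perm], conn$distances[perm, perm],
                      labels = conn$labels[perm])
  a <- regional_spectrum(conn, p, freq_grid(), "all")
  b <- regional_spectrum(pconn, p, freq_grid(), "all")
  expect_equal(unname(b$values), unname(a$values[perm, ]),
               tolerance = 1e-8)
})

test_that("eigenmode expansion equals the direct inverse when Hermitian", {
  conn <- random_conn(n = 10, sparsity = 0.2, seed = 12)
  p <- optimized_params()
  a <- regional_spectrum(conn, p, freq_grid(), "all",
                         normalization = "symmetric")
  b <- direct_inverse_spectrum(conn, p, freq_grid(),
                               normalization = "symmetric")
  expect_lt(max(abs(a$values - b$values) / b$values), 1e-6)
})

test_that("direct inverse closed forms: uncoupled network and single region", {
  p <- optimized_params()
  grid <- freq_grid()
  w <- 2 * pi * grid
  conn <- random_conn(n = 5, seed = 13)
  p0 <- sgm_params(alpha = 0)
  sp <- direct_inverse_spectrum(conn, p0, grid)
  FG <- gamma_spectrum(0.006, w)
  expected <- Mod(local_transfer(p0, w) / (1i * w + FG / 0.006))
  for (r in 1:5) expect_equal(unname(sp$values[r, ]), expected,
                              tolerance = 1e-10)
  # single self-connected region: L = 1 - alpha, scalar closed form
  one <- connectome(matrix(1, 1, 1))
  sp1 <- direct_inverse_spectrum(one, p, grid)
  FG <- gamma_spectrum(p$tau_G, w)
  lam <- 1 - p$alpha
  expected1 <- Mod(local_transfer(p, w) /
                     (1i * w + lam * FG / p$tau_G))
  expect_equal(unname(sp1$values[1, ]), expected1, tolerance = 1e-10)
})

test_that("two-thirds mode default truncates the expansion", {
  conn <- random_conn(n = 9, seed = 14)
  p <- optimized_params()
  full <- regional_spectrum(conn, p, freq_grid(), "all")
  tt <- regional_spectrum(conn, p, freq_grid())
  expect_false(isTRUE(all.equal(full$values, tt$values)))
  expect_equal(tt$values,
               regional_spectrum(conn, p, freq_grid(), 6)$values)
})

test_that("eigenvalue magnitudes are bounded and low modes vary most", {
  conn <- distance_conn(n = 24, sparsity = 0.2, seed = 21)
  p <- sgm_params()  # canonical defaults
  grid <- seq(0.5, 50, by = 2.5)
  mags <- sapply(grid, function(f) {
    Mod(laplacian_eigs(complex_laplacian(conn, 2 * pi * f, p))$values)
  })
  expect_true(all(mags >= 0))
  # row-normalization bounds |lambda| by 1 + alpha (Gershgorin)
  expect_true(all(mags <= 1 + p$alpha + 1e-8))
  # the nominal unit-interval range is a soft property of realistic
  # connectomes: log how much of it this synthetic fixture attains
  message(sprintf("eigenvalue magnitudes in [0,1]: %.1f%% (max %.3f)",
                  100 * mean(mags <= 1), max(mags)))
  # low-|lambda| modes shift more with frequency than high-|lambda| modes
  vr <- apply(mags, 1, var)
  n <- nrow(mags)
  low <- vr[seq_len(floor(n / 3))]
  high <- vr[seq(n - floor(n / 3) + 1, n)]
  expect_gt(mean(low), mean(high))
})
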