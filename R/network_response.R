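# Frequency-dependent complex connectivity, degree-normalized complex
# Laplacian, its eigendecomposition, and the closed-form steady-state
# regional frequency response.

#' Complex connectivity matrix at a given angular frequency
#'
#' Conduction delays become phase factors in the frequency domain: entry
#' (j,k) is `c_jk * exp(-1i * omega * d_jk / (1000 * v))`, with `d_jk` in
#' millimetres and `v` in metres/second (the 1000 converts mm to m). At
#' `omega = 0`, or as `v` grows large, this reduces to the real weight
#' matrix.
#'
#' @param conn a [connectome()].
#' @param omega angular frequency, rad/s (scalar).
#' @param v conduction speed, m/s.
#' @return N x N complex matrix.
#' @export
complex_connectivity <- function(conn, omega, v) {
  stopifnot(inherits(conn, "connectome"))
  if (v <= 0) stop_sgm("conduction speed v must be > 0")
  conn$weights * exp(-1i * omega * conn$distances / (1000 * v))
}

norm_factors <- function(conn, normalization) {
  deg <- degree_vector(conn)
  if (any(deg <= 0)) {
    stop_sgm("zero degree in region(s): %s",
             paste(conn$labels[deg <= 0], collapse = ", "))
  }
  switch(normalization,
         degree = list(left = 1 / deg, right = rep(1, length(deg))),
         symmetric = list(left = 1 / sqrt(deg), right = 1 / sqrt(deg)))
}

#' Complex Laplacian of the connectome at a given angular frequency
#'
#' `L(omega) = I - alpha * C(omega)` where `C(omega)` is the complex
#' connectivity matrix normalized by the real degree: row-normalized
#' `diag(1/deg) %*% Cstar` by default, or the symmetric variant
#' `diag(deg^-1/2) %*% Cstar %*% diag(deg^-1/2)`. The degree is always
#' computed from the real weights; only the connectivity entries carry
#' delay phases.
#'
#' @param conn a [connectome()].
#' @param omega angular frequency, rad/s (scalar).
#' @param params an [sgm_params()]; uses `alpha` and `v`.
#' @param normalization `"degree"` (default) or `"symmetric"`.
#' @return N x N complex matrix.
#' @examples
#' conn <- generate_connectome("uniform", n = 5)
#' complex_laplacian(conn, 0, sgm_params(alpha = 1))
#' @export
complex_laplacian <- function(conn, omega, params,
                              normalization = c("degree", "symmetric")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(params, "sgm_params"))
  nf <- norm_factors(conn, normalization)
  cstar <- complex_connectivity(conn, omega, params$v)
  n <- n_regions(conn)
  diag(n) - params$alpha * (nf$left * cstar) * rep(nf$right, each = n)
}

# Deterministic eigen post-processing: ascending |lambda| with ties broken
# by real then imaginary part; unit-norm columns; phase fixed so the
# largest-magnitude entry of each eigenvector is real-positive.
order_eigs <- function(values, vectors) {
  ord <- order(round(Mod(values), 12), round(Re(values), 12),
               round(Im(values), 12))
  values <- values[ord]
  vectors <- vectors[, ord, drop = FALSE]
  for (i in seq_along(values)) {
    u <- vectors[, i]
    u <- u / sqrt(sum(Mod(u)^2))
    k <- which.max(Mod(u))
    ph <- u[k] / Mod(u[k])
    vectors[, i] <- u / ph
  }
  list(values = values, vectors = vectors)
}

#' Eigendecomposition of a complex Laplacian
#'
#' Returns eigenvalues sorted by ascending magnitude (ties broken by real
#' part, then imaginary part) and unit-norm eigenvectors whose phase is
#' fixed so the largest-magnitude entry is real-positive, making the
#' decomposition deterministic. Residuals `||L u - lambda u||` are checked
#' against 1e-8.
#'
#' @param L square complex (or real) matrix.
#' @param frequency optional frequency in Hz recorded on the result.
#' @return an object of class `eigenmode_set` with fields `frequency`,
#'   `values` (complex vector) and `vectors` (complex matrix, column i is
#'   mode i).
#' @export
laplacian_eigs <- function(L, frequency = NA_real_) {
  if (!is.matrix(L) || nrow(L) != ncol(L)) stop_sgm("L must be square")
  if (any(!is.finite(Re(L))) || any(!is.finite(Im(L)))) {
    stop_sgm("L contains non-finite entries")
  }
  e <- tryCatch(eigen(L), error = function(err) {
    stop_sgm("eigensolver failed (rcond = %.3g): %s",
             tryCatch(rcond(L), error = function(e2) NA_real_),
             conditionMessage(err))
  })
  oe <- order_eigs(as.complex(e$values), matrix(as.complex(e$vectors),
                                                nrow(L), ncol(L)))
  res <- vapply(seq_along(oe$values), function(i) {
    sqrt(sum(Mod(L %*% oe$vectors[, i] - oe$values[i] * oe$vectors[, i])^2))
  }, numeric(1))
  tol <- 1e-8 * max(1, max(Mod(L)))
  if (any(res > tol)) {
    stop_sgm("eigenmode residual %.3g exceeds %.3g (rcond = %.3g)",
             max(res), tol, rcond(L))
  }
  structure(list(frequency = frequency, values = oe$values,
                 vectors = oe$vectors),
            class = "eigenmode_set")
}

#' @export
print.eigenmode_set <- function(x, ...) {
  cat(sprintf("eigenmode_set: %d modes%s; |lambda| in [%.4g, %.4g]\n",
              length(x$values),
              if (is.na(x$frequency)) "" else
                sprintf(" at %.3g Hz", x$frequency),
              min(Mod(x$values)), max(Mod(x$values))))
  invisible(x)
}

#' Frequency response of a single eigenmode
#'
#' `h_i(omega) = 1 / (j*omega + (lambda_i / tau_G) * F(omega))` where `F`
#' is the gamma-shaped spectrum evaluated with the graph time constant
#' `tau_G` (or with `tau_e` when `graph_tau = "tau_e"`; the long-range
#' projection neurons may or may not share the local excitatory time
#' constant, so both are supported). An exactly singular denominator is
#' capped at magnitude 1e12 with a warning.
#'
#' @param lambda complex eigenvalue(s) of the Laplacian.
#' @param omega angular frequency, rad/s (scalar).
#' @param params an [sgm_params()].
#' @param graph_tau which time constant drives the graph-level gamma
#'   response: `"tau_G"` (default) or `"tau_e"`.
#' @return complex vector of length `length(lambda)` (seconds).
#' @export
eigenmode_response <- function(lambda, omega, params,
                               graph_tau = c("tau_G", "tau_e")) {
  graph_tau <- match.arg(graph_tau)
  stopifnot(inherits(params, "sgm_params"))
  tau <- if (graph_tau == "tau_e") params$tau_e else params$tau_G
  den <- 1i * omega + (lambda / params$tau_G) * gamma_spectrum(tau, omega)
  h <- 1 / den
  bad <- !is.finite(Re(h)) | !is.finite(Im(h)) | Mod(h) > 1e12
  if (any(bad)) {
    warning("eigenmode response capped at magnitude 1e12", call. = FALSE)
    h[bad] <- 1e12 * exp(1i * Arg(ifelse(den[bad] == 0, 1, 1 / den[bad])))
  }
  h
}

# ---------------------------------------------------------------------------
# Spectrum engine. When all distances are zero the complex connectivity --
# and hence the normalized matrix A = D^-1 W -- is frequency-independent,
# so one eigendecomposition serves the whole grid (eigenvectors of
# L = I - alpha*A do not depend on alpha, and lambda = 1 - alpha*mu).
# Otherwise L(omega) is re-decomposed at every grid frequency.

make_engine <- function(conn, grid_hz, normalization) {
  nf <- norm_factors(conn, normalization)
  n <- n_regions(conn)
  A <- (nf$left * conn$weights) * rep(nf$right, each = n)
  zero_dist <- all(conn$distances == 0)
  list(n = n, grid = grid_hz, w = hz_to_omega(grid_hz),
       A = unname(A), distances = unname(conn$distances),
       zero_dist = zero_dist, labels = conn$labels)
}

# Eigens of L at one frequency index (or shared): returns list(values, vectors)
engine_eigs_at <- function(eng, params, fi) {
  if (eng$zero_dist) {
    # L = I - alpha*A is frequency-independent; decompose it directly so
    # degenerate cases (alpha = 0) keep an orthonormal eigenbasis
    L <- diag(eng$n) - params$alpha * eng$A
    e <- eigen(L)
    order_eigs(as.complex(e$values), matrix(as.complex(e$vectors),
                                            eng$n, eng$n))
  } else {
    ph <- exp(-1i * eng$w[fi] * eng$distances / (1000 * params$v))
    L <- diag(eng$n) - params$alpha * (eng$A * ph)
    e <- eigen(L)
    order_eigs(as.complex(e$values), matrix(as.complex(e$vectors),
                                            eng$n, eng$n))
  }
}

resolve_num_modes <- function(num_modes, n) {
  if (is.character(num_modes)) {
    num_modes <- match.arg(num_modes, c("two_thirds", "all"))
    if (num_modes == "all") n else ceiling(2 * n / 3)
  } else {
    k <- as.integer(num_modes)
    if (k < 1 || k > n) stop_sgm("num_modes must be in [1, %d]", n)
    k
  }
}

# Complex regional response summed over the first `k` modes (ascending
# |lambda|), N x F. Unit noise drive P(omega) = 1 at every region.
engine_spectrum <- function(eng, params, k, graph_tau) {
  Hl <- local_transfer(params, eng$w)
  nF <- length(eng$w)
  if (eng$zero_dist) {
    oe <- engine_eigs_at(eng, params, 1L)
    sel <- seq_len(k)
    U <- oe$vectors[, sel, drop = FALSE]
    w1 <- drop(Conj(t(U)) %*% rep(1, eng$n))
    # h: k x F response matrix
    tau <- if (graph_tau == "tau_e") params$tau_e else params$tau_G
    FG <- gamma_spectrum(tau, eng$w)
    den <- matrix(1i * eng$w, k, nF, byrow = TRUE) +
      outer(oe$values[sel] / params$tau_G, FG)
    h <- 1 / den
    coeff <- h * (w1 * matrix(Hl, k, nF, byrow = TRUE))
    U %*% coeff
  } else {
    X <- matrix(0i, eng$n, nF)
    for (fi in seq_len(nF)) {
      oe <- engine_eigs_at(eng, params, fi)
      sel <- seq_len(k)
      U <- oe$vectors[, sel, drop = FALSE]
      w1 <- drop(Conj(t(U)) %*% rep(1, eng$n))
      h <- eigenmode_response(oe$values[sel], eng$w[fi], params, graph_tau)
      X[, fi] <- U %*% (h * w1 * Hl[fi])
    }
    X
  }
}

#' Steady-state regional magnitude spectrum (eigenmode expansion)
#'
#' Closed-form whole-brain frequency response under unit white-noise drive
#' at every region: for each grid frequency,
#' `X(omega) = sum_i u_i u_i^H h_i(omega) H_local(omega) 1` over the first
#' `num_modes` eigenmodes of the complex Laplacian in ascending eigenvalue
#' magnitude. Returns the magnitude `|X|` per region per frequency.
#'
#' The rank-one expansion `u_i u_i^H` is exact when the eigenvectors are
#' orthonormal (symmetric normalization at zero delay); otherwise it is the
#' model's stated approximation, and [direct_inverse_spectrum()] provides
#' the exact linear-solve reference.
#'
#' @param conn a [connectome()].
#' @param params an [sgm_params()].
#' @param grid frequency grid in Hz (strictly increasing).
#' @param num_modes integer number of modes, `"two_thirds"` (default,
#'   `ceiling(2N/3)`), or `"all"`.
#' @param normalization `"degree"` or `"symmetric"` Laplacian normalization.
#' @param graph_tau `"tau_G"` or `"tau_e"` for the graph-level gamma
#'   response.
#' @return a [regional_spectra()] object (N x F nonnegative magnitudes).
#' @examples
#' conn <- generate_connectome("random", n = 12, sparsity = 0.3, seed = 1)
#' sp <- regional_spectrum(conn, sgm_params(), freq_grid())
#' @export
regional_spectrum <- function(conn, params, grid = freq_grid(),
                              num_modes = "two_thirds",
                              normalization = c("degree", "symmetric"),
                              graph_tau = c("tau_G", "tau_e")) {
  normalization <- match.arg(normalization)
  graph_tau <- match.arg(graph_tau)
  stopifnot(inherits(conn, "connectome"), inherits(params, "sgm_params"))
  eng <- make_engine(conn, grid, normalization)
  k <- resolve_num_modes(num_modes, eng$n)
  X <- engine_spectrum(eng, params, k, graph_tau)
  regional_spectra(Mod(X), grid, conn$labels)
}

#' Steady-state regional magnitude spectrum (direct linear solve)
#'
#' Exact reference implementation: solves
#' `(j*omega*I + (F(omega)/tau_G) * L(omega)) X = H_local(omega) * 1`
#' densely at every grid frequency, bypassing the eigenmode expansion.
#' Used as the correctness oracle for [regional_spectrum()].
#'
#' @inheritParams regional_spectrum
#' @return a [regional_spectra()] object.
#' @export
direct_inverse_spectrum <- function(conn, params, grid = freq_grid(),
                                    normalization = c("degree", "symmetric"),
                                    graph_tau = c("tau_G", "tau_e")) {
  normalization <- match.arg(normalization)
  graph_tau <- match.arg(graph_tau)
  stopifnot(inherits(conn, "connectome"), inherits(params, "sgm_params"))
  w <- hz_to_omega(grid)
  n <- n_regions(conn)
  tau <- if (graph_tau == "tau_e") params$tau_e else params$tau_G
  Hl <- local_transfer(params, w)
  FG <- gamma_spectrum(tau, w)
  vals <- matrix(0, n, length(grid))
  ones <- rep(1, n)
  for (fi in seq_along(grid)) {
    L <- complex_laplacian(conn, w[fi], params, normalization)
    M <- diag(1i * w[fi], n) + (FG[fi] / params$tau_G) * L
    x <- tryCatch(solve(M, Hl[fi] * ones), error = function(e) {
      stop_sgm("singular system at %.4g Hz: %s", grid[fi],
               conditionMessage(e))
    })
    vals[, fi] <- Mod(x)
  }
  regional_spectra(vals, grid, conn$labels)
}

#' Per-eigenmode magnitude responses over a frequency grid
#'
#' The magnitude of each mode's scalar contribution
#' `|h_i(omega) * (u_i^H 1) * H_local(omega)|`, a (modes x frequencies)
#' table useful for inspecting which modes carry which rhythms.
#'
#' @inheritParams regional_spectrum
#' @return numeric matrix (num_modes x length(grid)) with modes in
#'   ascending eigenvalue-magnitude order.
#' @export
eigenmode_spectra <- function(conn, params, grid = freq_grid(),
                              num_modes = "all",
                              normalization = c("degree", "symmetric"),
                              graph_tau = c("tau_G", "tau_e")) {
  normalization <- match.arg(normalization)
  graph_tau <- match.arg(graph_tau)
  eng <- make_engine(conn, grid, normalization)
  k <- resolve_num_modes(num_modes, eng$n)
  w <- eng$w
  Hl <- local_transfer(params, w)
  out <- matrix(0, k, length(w))
  for (fi in seq_along(w)) {
    oe <- engine_eigs_at(eng, params, fi)
    w1 <- drop(Conj(t(oe$vectors[, seq_len(k), drop = FALSE])) %*%
                 rep(1, eng$n))
    h <- eigenmode_response(oe$values[seq_len(k)], w[fi], params, graph_tau)
    out[, fi] <- Mod(h * w1 * Hl[fi])
  }
  dimnames(out) <- list(paste0("mode", seq_len(k)),
                        format(grid, trim = TRUE))
  out
}

# Complex single-mode regional responses: N x F x k array, mode i at each
# frequency being the i-th mode in ascending |lambda| order there.
mode_responses <- function(conn, params, grid, num_modes,
                           normalization, graph_tau) {
  eng <- make_engine(conn, grid, normalization)
  k <- resolve_num_modes(num_modes, eng$n)
  w <- eng$w
  Hl <- local_transfer(params, w)
  out <- array(0i, c(eng$n, length(w), k))
  if (eng$zero_dist) {
    oe <- engine_eigs_at(eng, params, 1L)
    w1 <- drop(Conj(t(oe$vectors)) %*% rep(1, eng$n))
    tau <- if (graph_tau == "tau_e") params$tau_e else params$tau_G
    FG <- gamma_spectrum(tau, w)
    for (i in seq_len(k)) {
      h <- 1 / (1i * w + (oe$values[i] / params$tau_G) * FG)
      out[, , i] <- outer(oe$vectors[, i], h * w1[i] * Hl)
    }
  } else {
    for (fi in seq_along(w)) {
      oe <- engine_eigs_at(eng, params, fi)
      w1 <- drop(Conj(t(oe$vectors)) %*% rep(1, eng$n))
      h <- eigenmode_response(oe$values, w[fi], params, graph_tau)
      for (i in seq_len(k)) {
        out[, fi, i] <- oe$vectors[, i] * (h[i] * w1[i] * Hl[fi])
      }
    }
  }
  out
}
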