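# Spectral goodness-of-fit and bounded simulated-annealing optimization of
# the seven global parameters.

# Row-standardize a matrix across columns; rows with zero variance -> NA.
row_standardize <- function(m) {
  mu <- rowMeans(m)
  ctr <- m - mu
  s <- sqrt(rowSums(ctr^2))
  ctr / ifelse(s > 0, s, NA_real_)
}

interp_rows <- function(values, from, to) {
  t(apply(values, 1, function(v) stats::approx(from, v, xout = to,
                                               rule = 2)$y))
}

#' Spectral correlation between model and empirical regional spectra
#'
#' Goodness of fit of a modeled spectrum: the Pearson correlation between
#' model and empirical spectra across frequencies, computed per region on
#' the dB scale (raw magnitudes are dominated by low-frequency power), then
#' averaged over regions. Regions with a constant spectrum are skipped with
#' a warning. If the empirical grid differs from the model grid, the
#' empirical spectra are linearly interpolated onto the model grid.
#'
#' @param model,empirical [regional_spectra()] objects over matching region
#'   sets (matched by label).
#' @param mask optional logical vector over the model's regions restricting
#'   the average (e.g. a cortical mask); default all regions.
#' @param scale `"db"` (default) or `"linear"` amplitude scale for the
#'   correlation.
#' @return mean Pearson r in `[-1, 1]`.
#' @examples
#' conn <- generate_connectome("random", n = 8, sparsity = 0.2, seed = 1)
#' sp <- regional_spectrum(conn, sgm_params(), freq_grid())
#' spectral_correlation(sp, sp)   # 1
#' @export
spectral_correlation <- function(model, empirical, mask = NULL,
                                 scale = c("db", "linear")) {
  scale <- match.arg(scale)
  stopifnot(inherits(model, "regional_spectra"),
            inherits(empirical, "regional_spectra"))
  if (!setequal(model$labels, empirical$labels)) {
    stop_sgm("model and empirical spectra cover different region sets")
  }
  ev <- empirical$values[match(model$labels, empirical$labels), ,
                         drop = FALSE]
  if (!isTRUE(all.equal(model$grid, empirical$grid))) {
    if (min(empirical$grid) > min(model$grid) ||
        max(empirical$grid) < max(model$grid)) {
      warning("empirical grid does not cover the model grid; edge values ",
              "extended", call. = FALSE)
    }
    ev <- interp_rows(ev, empirical$grid, model$grid)
  }
  if (is.null(mask)) mask <- rep(TRUE, nrow(model$values))
  tf <- if (scale == "db") spectra_db else identity
  zm <- row_standardize(tf(model$values[mask, , drop = FALSE]))
  ze <- row_standardize(tf(ev[mask, , drop = FALSE]))
  r <- rowSums(zm * ze)
  if (any(is.na(r))) {
    warning(sprintf("%d region(s) with constant spectrum skipped",
                    sum(is.na(r))), call. = FALSE)
  }
  mean(r, na.rm = TRUE)
}

#' Simulated-annealing acceptance probability
#'
#' A trial point that improves the cost (`delta <= 0`, minimization sense)
#' is always accepted; a worse point is accepted with logistic probability
#' `1 / (1 + exp(delta / temperature))`, allowing escapes from local
#' minima early in the schedule.
#'
#' @param delta cost difference, new minus old.
#' @param temperature current positive temperature.
#' @return acceptance probability in `(0, 1]`, vectorized over `delta`.
#' @examples
#' anneal_acceptance(-0.1, 0.5)   # 1
#' anneal_acceptance(0.5, 0.5)    # 1/(1+e)
#' @export
anneal_acceptance <- function(delta, temperature) {
  if (any(temperature <= 0)) stop_sgm("temperature must be > 0")
  ifelse(delta <= 0, 1, 1 / (1 + exp(delta / temperature)))
}

params_from_vector <- function(x) {
  do.call(sgm_params, as.list(stats::setNames(x, tunable_parameters())))
}

#' Fit the seven global parameters to empirical regional spectra
#'
#' Maximizes the region-averaged spectral correlation by bounded simulated
#' annealing in normalized `[0, 1]` coordinates: exponential cooling
#' `T_k = t0 * cooling^k`, Gaussian single-coordinate proposals scaled by
#' the current temperature and reflected at the bounds, logistic acceptance
#' of worse moves ([anneal_acceptance()]), and reannealing (temperature
#' reset and restart from the incumbent best) every `reanneal`
#' acceptances. The run
#' is deterministic given `seed` and leaves the caller's RNG state
#' untouched.
#'
#' @param empirical a [regional_spectra()] of observed spectra.
#' @param conn the [connectome()] the model is evaluated on; its
#'   `cortical_mask` restricts the fitted regions.
#' @param bounds named list of `c(lower, upper)` per tunable parameter;
#'   default [sgm_bounds()]. A parameter whose bounds coincide is held
#'   fixed.
#' @param seed integer seed for the proposal stream.
#' @param max_iter iteration cap; default `7 * 3000` (3000 per tunable
#'   parameter).
#' @param grid fitting frequency grid in Hz; default [freq_grid()]
#'   (2-45 Hz at 0.5 Hz).
#' @param init optional [sgm_params()] starting point; default the
#'   canonical parameter values clipped into the bounds.
#' @param num_modes,normalization,graph_tau forwarded to the forward model
#'   (see [regional_spectrum()]).
#' @param scale amplitude scale for the correlation cost, `"db"` default.
#' @param t0,cooling,reanneal annealing schedule: initial temperature,
#'   geometric cooling factor per iteration, acceptances between reanneals.
#' @param reanneal_decay factor applied to the temperature ceiling at each
#'   reanneal: successive cycles restart from the incumbent best at
#'   progressively lower temperature, so early cycles explore globally and
#'   late cycles refine locally. Set to 1 for classical full-temperature
#'   reannealing.
#' @return an object of class `sgm_fit`: `best_params` ([sgm_params()]),
#'   `cost_trace` (best correlation so far, per iteration),
#'   `final_correlation`, `iterations_used`, `seed`, `bounds`.
#' @export
fit_parameters <- function(empirical, conn, bounds = sgm_bounds(),
                           seed = 1, max_iter = 7 * 3000,
                           grid = freq_grid(), init = NULL,
                           num_modes = "two_thirds",
                           normalization = c("degree", "symmetric"),
                           graph_tau = c("tau_G", "tau_e"),
                           scale = c("db", "linear"),
                           t0 = 1, cooling = 0.95, reanneal = 100,
                           reanneal_decay = 1) {
  normalization <- match.arg(normalization)
  graph_tau <- match.arg(graph_tau)
  scale <- match.arg(scale)
  stopifnot(inherits(empirical, "regional_spectra"),
            inherits(conn, "connectome"))
  pnames <- tunable_parameters()
  if (!all(pnames %in% names(bounds))) {
    stop_sgm("bounds must name all of: %s", paste(pnames, collapse = ", "))
  }
  lb <- vapply(bounds[pnames], `[`, numeric(1), 1L)
  ub <- vapply(bounds[pnames], `[`, numeric(1), 2L)
  if (any(ub < lb)) stop_sgm("upper bound below lower bound")
  if (!setequal(conn$labels, empirical$labels)) {
    stop_sgm("empirical spectra and connectome cover different regions")
  }

  # Precompute: empirical dB on the fitting grid, standardized per region,
  # restricted to the cortical mask; and the spectrum engine.
  ev <- empirical$values[match(conn$labels, empirical$labels), ,
                         drop = FALSE]
  if (!isTRUE(all.equal(empirical$grid, grid))) {
    ev <- interp_rows(ev, empirical$grid, grid)
  }
  mask <- conn$cortical_mask
  tf <- if (scale == "db") spectra_db else identity
  ze <- row_standardize(tf(ev[mask, , drop = FALSE]))
  keep <- !is.na(ze[, 1])
  if (!all(keep)) {
    warning(sprintf("%d constant empirical region(s) skipped from the fit",
                    sum(!keep)), call. = FALSE)
  }
  eng <- make_engine(conn, grid, normalization)
  k <- resolve_num_modes(num_modes, eng$n)

  correlation_of <- function(x) {
    p <- params_from_vector(x)
    X <- engine_spectrum(eng, p, k, graph_tau)
    zm <- row_standardize(tf(Mod(X)[mask, , drop = FALSE]))
    mean(rowSums(zm * ze)[keep], na.rm = TRUE)
  }

  free <- which(ub > lb)
  denorm <- function(u) lb + u * (ub - lb)
  start <- if (is.null(init)) unlist(sgm_params()[pnames]) else
    unlist(init[pnames])
  start <- pmin(pmax(start, lb), ub)
  u <- ifelse(ub > lb, (start - lb) / (ub - lb), 0)

  cur_r <- correlation_of(denorm(u))
  if (!is.finite(cur_r)) stop_sgm("non-finite cost at the starting point")
  best_r <- cur_r
  best_u <- u
  if (length(free) == 0L) {
    return(structure(list(best_params = params_from_vector(denorm(u)),
                          cost_trace = best_r, final_correlation = best_r,
                          iterations_used = 1L, seed = as.integer(seed),
                          bounds = bounds),
                     class = "sgm_fit"))
  }

  trace <- numeric(max_iter)
  with_seed(seed, {
    kk <- 0L       # iterations since last reanneal
    acc <- 0L
    ceiling_t <- t0
    for (it in seq_len(max_iter)) {
      temp <- ceiling_t * cooling^kk
      # one randomly chosen free coordinate per proposal: axis moves walk
      # the ridges between covarying parameters far more efficiently than
      # simultaneous perturbation of all seven
      j <- if (length(free) == 1L) free else free[sample.int(length(free), 1L)]
      prop <- u
      prop[j] <- (u[j] + temp * stats::rnorm(1L)) %% 2
      if (prop[j] > 1) prop[j] <- 2 - prop[j]
      new_r <- correlation_of(denorm(prop))
      if (is.finite(new_r)) {
        delta <- (-new_r) - (-cur_r)   # minimization-sense difference
        if (stats::runif(1) < anneal_acceptance(delta, temp)) {
          u <- prop
          cur_r <- new_r
          acc <- acc + 1L
          if (new_r > best_r) {
            best_r <- new_r
            best_u <- prop
          }
          if (acc %% reanneal == 0L) {
            kk <- 0L          # reanneal: reset temperature to a decayed
            ceiling_t <- max(ceiling_t * reanneal_decay, 1e-6)
            u <- best_u       # ceiling, restart from the incumbent best
            cur_r <- best_r
          }
        }
      }
      kk <- kk + 1L
      trace[it] <- best_r
    }
  })
  structure(list(best_params = params_from_vector(denorm(best_u)),
                 cost_trace = trace, final_correlation = best_r,
                 iterations_used = max_iter, seed = as.integer(seed),
                 bounds = bounds),
            class = "sgm_fit")
}

#' @export
print.sgm_fit <- function(x, ...) {
  cat(sprintf("sgm_fit: final spectral correlation %.4f after %d iterations (seed %d)\n",
              x$final_correlation, x$iterations_used, x$seed))
  print(x$best_params)
  invisible(x)
}

#' Serialize a fit result to JSON
#'
#' Parameters in SI units, the per-iteration best-correlation trace, the
#' seed and the bounds.
#'
#' @param fit an `sgm_fit`.
#' @param path output path.
#' @param trace_every keep every k-th trace entry (the full trace at
#'   1; thinning keeps files small for long runs).
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path, trace_every = 1L) {
  stopifnot(inherits(fit, "sgm_fit"))
  idx <- seq(1L, length(fit$cost_trace), by = as.integer(trace_every))
  obj <- list(
    best_params = fit$best_params[tunable_parameters()],
    final_correlation = fit$final_correlation,
    iterations_used = fit$iterations_used,
    seed = fit$seed,
    bounds = fit$bounds,
    cost_trace = fit$cost_trace[idx]
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
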