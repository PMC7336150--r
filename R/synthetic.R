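# Pseudo-empirical regional spectra with known ground truth, standing in
# for source-localized resting-state recordings so that fitting and
# eigenmode selection can be exercised and tested without real data.

#' Generate pseudo-empirical regional spectra
#'
#' Evaluates the forward model at known parameters and perturbs it with
#' independent Gaussian noise applied on the dB scale (multiplicative in
#' linear magnitude), emulating the log-scale character of spectral
#' estimation noise. With `noise_sd_db = 0` the spectra equal the forward
#' model exactly. Reproducible bit-exactly from the same arguments; the
#' caller's RNG state is untouched.
#'
#' @param conn a [connectome()].
#' @param params the generating ("true") [sgm_params()].
#' @param noise_sd_db noise standard deviation in dB, `>= 0` (1 dB is a
#'   realistic default for averaged resting-state spectra).
#' @param seed integer seed.
#' @param grid frequency grid in Hz.
#' @param num_modes,normalization,graph_tau forwarded to
#'   [regional_spectrum()].
#' @return an object of class `sgm_synthetic`: `connectome`, `true_params`,
#'   `spectra` (noisy [regional_spectra()]), `noiseless` (the clean
#'   forward spectra), `noise_sd_db`, `seed`.
#' @examples
#' conn <- generate_connectome("random", n = 10, sparsity = 0.3, seed = 1)
#' ds <- generate_pseudo_spectra(conn, sgm_params(), noise_sd_db = 1, seed = 7)
#' @export
generate_pseudo_spectra <- function(conn, params, noise_sd_db = 1, seed = 1,
                                    grid = freq_grid(),
                                    num_modes = "two_thirds",
                                    normalization = c("degree", "symmetric"),
                                    graph_tau = c("tau_G", "tau_e")) {
  normalization <- match.arg(normalization)
  graph_tau <- match.arg(graph_tau)
  if (noise_sd_db < 0) stop_sgm("noise_sd_db must be >= 0")
  clean <- regional_spectrum(conn, params, grid, num_modes, normalization,
                             graph_tau)
  vals <- clean$values
  if (noise_sd_db > 0) {
    eps <- with_seed(seed, matrix(stats::rnorm(length(vals), 0, noise_sd_db),
                                  nrow(vals), ncol(vals)))
    vals <- vals * 10^(eps / 20)
  }
  structure(list(connectome = conn, true_params = params,
                 spectra = regional_spectra(vals, grid, conn$labels),
                 noiseless = clean,
                 noise_sd_db = noise_sd_db, seed = as.integer(seed)),
            class = "sgm_synthetic")
}

#' @export
print.sgm_synthetic <- function(x, ...) {
  cat(sprintf("sgm_synthetic: %d regions, noise %.3g dB, seed %d\n",
              length(x$spectra$labels), x$noise_sd_db, x$seed))
  invisible(x)
}

#' Write a synthetic dataset: spectra plus a JSON ground-truth sidecar
#'
#' @param dataset an `sgm_synthetic`.
#' @param spectra_path output path for the spectra table.
#' @param sidecar_path output path for the JSON sidecar recording the true
#'   parameters, noise level and seed; default `<spectra_path>.json`.
#' @return `dataset`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, spectra_path,
                                    sidecar_path = NULL) {
  stopifnot(inherits(dataset, "sgm_synthetic"))
  write_regional_spectra(dataset$spectra, spectra_path)
  sidecar_path <- sidecar_path %||% paste0(spectra_path, ".json")
  jsonlite::write_json(
    list(true_params = dataset$true_params[tunable_parameters()],
         noise_sd_db = dataset$noise_sd_db, seed = dataset$seed),
    sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(dataset)
}
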