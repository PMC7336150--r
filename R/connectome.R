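# Connectome container, validation, text I/O, degree computation, and
# synthetic connectome generators (uniform / random / distance-based).

#' Construct and validate a connectome
#'
#' A connectome couples a symmetric nonnegative inter-regional connection
#' weight matrix with a matrix of fiber distances in millimetres and a
#' cortical mask selecting the regions used when comparing against empirical
#' spectra. Asymmetric weight input is symmetrized by averaging the two
#' directions, with a warning.
#'
#' @param weights N x N nonnegative numeric matrix of connection strengths
#'   (arbitrary units).
#' @param distances N x N nonnegative numeric matrix of fiber distances in
#'   millimetres; zero diagonal. Defaults to all-zero (no conduction delays).
#' @param labels character vector of N region identifiers. Defaults to
#'   dimnames of `weights`, else `"R1"..."RN"`.
#' @param cortical_mask logical vector of length N marking regions used for
#'   spectra comparison; defaults to all `TRUE`.
#' @param repair_isolated if `TRUE`, regions with zero total connection
#'   strength are epsilon-repaired (degree padded by 1e-12) rather than
#'   rejected.
#' @return an object of class `connectome` with fields `labels`, `weights`,
#'   `distances`, `cortical_mask`.
#' @examples
#' conn <- connectome(matrix(1, 4, 4))
#' degree_vector(conn)
#' @export
connectome <- function(weights, distances = NULL, labels = NULL,
                       cortical_mask = NULL, repair_isolated = FALSE) {
  assert_finite_matrix(weights, "weights")
  n <- nrow(weights)
  if (ncol(weights) != n) stop_sgm("weights must be square")
  if (n < 1) stop_sgm("need at least one region")
  if (any(weights < 0)) stop_sgm("weights contain negative entries")
  if (is.null(labels)) {
    labels <- rownames(weights) %||% paste0("R", seq_len(n))
  }
  if (length(labels) != n) stop_sgm("labels length %d != %d regions",
                                    length(labels), n)
  asym <- max(abs(weights - t(weights)))
  if (asym > 1e-8 * max(1, max(abs(weights)))) {
    warning("asymmetric weights symmetrized by averaging (W + t(W))/2",
            call. = FALSE)
  }
  weights <- (weights + t(weights)) / 2

  if (is.null(distances)) distances <- matrix(0, n, n)
  assert_finite_matrix(distances, "distances")
  if (!all(dim(distances) == c(n, n))) {
    stop_sgm("distances are %dx%d but weights are %dx%d",
             nrow(distances), ncol(distances), n, n)
  }
  if (any(distances < 0)) stop_sgm("distances contain negative entries")
  if (max(abs(distances - t(distances))) > 1e-8 * max(1, max(distances))) {
    stop_sgm("distances must be symmetric")
  }
  distances <- (distances + t(distances)) / 2
  diag(distances) <- 0

  if (is.null(cortical_mask)) cortical_mask <- rep(TRUE, n)
  if (!is.logical(cortical_mask) || length(cortical_mask) != n) {
    stop_sgm("cortical_mask must be a logical vector of length %d", n)
  }

  deg <- colSums(weights)
  if (any(deg <= 0)) {
    bad <- labels[deg <= 0]
    if (!repair_isolated) {
      stop_sgm("isolated region(s) with zero degree: %s",
               paste(bad, collapse = ", "))
    }
  }

  dimnames(weights) <- dimnames(distances) <- list(labels, labels)
  structure(
    list(labels = as.character(labels), weights = weights,
         distances = distances, cortical_mask = cortical_mask,
         repair_isolated = isTRUE(repair_isolated)),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  n <- length(x$labels)
  nz <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("connectome: %d regions, %d nonzero undirected edges\n", n, nz))
  cat(sprintf("  delays: %s; cortical regions: %d/%d\n",
              if (all(x$distances == 0)) "none (zero distances)" else
                sprintf("distances up to %.1f mm", max(x$distances)),
              sum(x$cortical_mask), n))
  invisible(x)
}

#' Number of regions in a connectome
#' @param conn a `connectome`.
#' @return integer region count.
#' @export
n_regions <- function(conn) length(conn$labels)

#' Total connection strength per region
#'
#' The degree of region k is the sum of real connection weights into it,
#' `deg_k = sum_j c_jk`. Degree is always computed from the real weights;
#' the complex (delayed) connectivity matrix is normalized by this same
#' real-valued degree.
#'
#' @param conn a `connectome`.
#' @return nonnegative numeric vector of length N, named by region. When the
#'   connectome was built with `repair_isolated = TRUE`, zero degrees are
#'   padded by 1e-12 so downstream normalization never divides by zero.
#' @export
degree_vector <- function(conn) {
  stopifnot(inherits(conn, "connectome"))
  deg <- colSums(conn$weights)
  if (isTRUE(conn$repair_isolated)) deg <- deg + 1e-12
  deg
}

# ---------------------------------------------------------------------------
# Text I/O: comma- or tab-delimited matrix, first row = region labels.

read_label_matrix <- function(path) {
  if (!file.exists(path)) stop_sgm("file not found: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, comment.char = "#")
  m <- as.matrix(df)
  if (!is.numeric(m)) stop_sgm("non-numeric entries in %s", path)
  rownames(m) <- colnames(m)
  m
}

#' Load a connectome from delimited-text matrices
#'
#' Both files are square numeric matrices whose first row holds the region
#' labels (comma- or tab-delimited; lines starting with `#` are ignored).
#' Asymmetric weights are symmetrized by averaging with a warning; label
#' order is preserved as in the file.
#'
#' @param weights_path path to the weight-matrix file.
#' @param distances_path optional path to the distance-matrix file (mm);
#'   omitted means zero distances (no delays).
#' @param cortical_labels optional character vector naming the regions to
#'   mark cortical; all others get `cortical_mask = FALSE`.
#' @param ... passed on to [connectome()] (e.g. `repair_isolated`).
#' @return a validated `connectome`.
#' @export
load_connectome <- function(weights_path, distances_path = NULL,
                            cortical_labels = NULL, ...) {
  w <- read_label_matrix(weights_path)
  if (nrow(w) != ncol(w)) {
    stop_sgm("weight matrix in %s is %dx%d, not square",
             weights_path, nrow(w), ncol(w))
  }
  d <- NULL
  if (!is.null(distances_path)) {
    d <- read_label_matrix(distances_path)
    if (!all(dim(d) == dim(w))) {
      stop_sgm("dimension mismatch: weights %dx%d vs distances %dx%d",
               nrow(w), ncol(w), nrow(d), ncol(d))
    }
    if (!identical(colnames(w), colnames(d))) {
      stop_sgm("region labels differ between weight and distance files")
    }
  }
  mask <- NULL
  if (!is.null(cortical_labels)) {
    unknown <- setdiff(cortical_labels, colnames(w))
    if (length(unknown)) {
      stop_sgm("cortical labels not in connectome: %s",
               paste(unknown, collapse = ", "))
    }
    mask <- colnames(w) %in% cortical_labels
  }
  connectome(w, d, labels = colnames(w), cortical_mask = mask, ...)
}

#' Write a connectome to delimited-text matrices
#'
#' @param conn a `connectome`.
#' @param weights_path output path for the weight matrix.
#' @param distances_path optional output path for the distance matrix.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `conn`, invisibly.
#' @export
write_connectome <- function(conn, weights_path, distances_path = NULL,
                             sep = ",") {
  stopifnot(inherits(conn, "connectome"))
  wm <- function(m, path) {
    utils::write.table(m, path, sep = sep, row.names = FALSE,
                       col.names = TRUE, quote = FALSE)
  }
  wm(conn$weights, weights_path)
  if (!is.null(distances_path)) wm(conn$distances, distances_path)
  invisible(conn)
}

# ---------------------------------------------------------------------------
# Generators

# Seeded pseudo-brain geometry: points on an ellipsoidal shell with mild
# radial jitter, semi-axes on the scale of a human hemisphere pair (mm).
ellipsoid_shell_coords <- function(n, semi_axes = c(65, 85, 55),
                                   jitter = 0.08) {
  dirs <- matrix(stats::rnorm(3 * n), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  r <- 1 - jitter * stats::runif(n)
  sweep(dirs * r, 2, semi_axes, `*`)
}

#' Generate a synthetic connectome
#'
#' Three connectome variants used as controls and null models:
#' `"uniform"` is the all-ones matrix (diagonal included) whose normalized
#' Laplacian has the closed-form eigenvalue set `{1 - alpha, 1 x (N-1)}` at
#' zero delays; `"random"` draws symmetric uniform(0,1] off-diagonal weights
#' and zeroes a given fraction of off-diagonal pairs; `"distance"` places
#' regions on a seeded ellipsoidal shell (or uses supplied coordinates) and
#' sets weights `exp(-d/sigma)` with `sigma` the median pairwise distance,
#' thresholded to the requested sparsity.
#'
#' The generator is a pure function of its arguments: the same seed gives a
#' bit-identical connectome, and the caller's RNG state is left untouched.
#'
#' @param kind one of `"uniform"`, `"random"`, `"distance"`.
#' @param n number of regions (>= 2).
#' @param sparsity fraction in `[0, 1)` of off-diagonal pairs set to zero
#'   (ignored for `"uniform"`).
#' @param seed integer seed.
#' @param coords optional N x 3 positions in mm; required to give the
#'   uniform/random variants a nonzero distance matrix, generated internally
#'   for `"distance"` when omitted.
#' @return a validated `connectome`.
#' @examples
#' generate_connectome("random", n = 10, sparsity = 0.5, seed = 1)
#' @export
generate_connectome <- function(kind = c("uniform", "random", "distance"),
                                n, sparsity = 0, seed = 1, coords = NULL) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (n < 2) stop_sgm("need n >= 2 regions")
  if (sparsity < 0 || sparsity >= 1) stop_sgm("sparsity must be in [0, 1)")
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (!all(dim(coords) == c(n, 3))) stop_sgm("coords must be %d x 3", n)
  }
  with_seed(seed, {
    dist_mat <- function(p) {
      d <- as.matrix(stats::dist(p))
      dimnames(d) <- NULL
      d
    }
    distances <- if (!is.null(coords)) dist_mat(coords) else NULL

    if (kind == "uniform") {
      w <- matrix(1, n, n)
      return(connectome(w, distances))
    }

    npair <- n * (n - 1) / 2
    nzero <- round(sparsity * npair)
    for (attempt in seq_len(100L)) {
      if (kind == "random") {
        vals <- 1 - stats::runif(npair)    # uniform (0, 1]
        if (nzero > 0) vals[sample.int(npair, nzero)] <- 0
        w <- matrix(0, n, n)
        w[upper.tri(w)] <- vals
        w <- w + t(w)
        d <- distances
      } else {                             # distance-based
        p <- if (is.null(coords)) ellipsoid_shell_coords(n) else coords
        d <- dist_mat(p)
        sigma <- stats::median(d[upper.tri(d)])
        w <- exp(-d / sigma)
        diag(w) <- 0
        if (nzero > 0) {
          ut <- which(upper.tri(w))
          drop_idx <- ut[order(w[ut])][seq_len(nzero)]
          w[drop_idx] <- 0
          w <- pmin(w, t(w))               # keep symmetric zero pattern
        }
      }
      if (all(colSums(w) > 0)) {
        return(connectome(w, d))
      }
    }
    stop_sgm("sparsity %.2f produced isolated regions in 100 attempts",
             sparsity)
  })
}
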