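# Diffusion-encoding schemes and acquisition protocols.
#
# Unit convention: b-values are stored internally in ms/um^2 (so a stored
# 1.2 corresponds to 1200 s/mm^2) and diffusivities in um^2/ms; FSL-dialect
# files on disk always carry s/mm^2.

B0_THRESHOLD_S_MM2 <- 50

#' Convert b-values between s/mm^2 and the internal ms/um^2 convention
#'
#' @param b Numeric vector of b-values.
#' @return Converted numeric vector.
#' @export
b_to_internal <- function(b) b * 1e-3

#' @rdname b_to_internal
#' @export
b_to_s_mm2 <- function(b) b * 1e3

#' Construct a gradient scheme
#'
#' A gradient scheme records, per acquired volume, the diffusion-encoding
#' direction (a unit 3-vector, or the zero vector for unweighted volumes)
#' and the b-value in ms/um^2. Volumes with b below 50 s/mm^2 are treated
#' as b0 (unweighted) volumes.
#'
#' @param directions Numeric matrix with one row per volume and 3 columns.
#'   Rows for weighted volumes must have unit Euclidean norm (within 1e-9);
#'   rows for b0 volumes must be all-zero (they are zeroed on construction).
#' @param bvalues Numeric vector of b-values in ms/um^2, one per volume.
#' @return An object of class `gradient_scheme`.
#' @export
gradient_scheme <- function(directions, bvalues) {
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L)
    stopf("directions must have 3 columns, got %d", ncol(directions))
  bvalues <- as.numeric(bvalues)
  if (nrow(directions) != length(bvalues))
    stopf("length mismatch: %d directions vs %d b-values",
          nrow(directions), length(bvalues))
  if (any(!is.finite(bvalues)) || any(bvalues < 0))
    stopf("b-values must be finite and non-negative")
  is_b0 <- bvalues < b_to_internal(B0_THRESHOLD_S_MM2)
  directions[is_b0, ] <- 0
  if (any(!is_b0)) {
    nrm <- sqrt(rowSums(directions[!is_b0, , drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-9))
      stopf("weighted directions must be unit vectors (max |norm-1| = %.3g)",
            max(abs(nrm - 1)))
    if (!any(is_b0))
      stopf("scheme has weighted volumes but no b0 volume; the log-linear intercept is not estimable")
  }
  structure(list(directions = unname(directions), bvalues = bvalues),
            class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("<gradient_scheme> %d volumes (%d b0 + %d weighted), b in {%s} ms/um^2\n",
              scheme_length(x), scheme_n_b0(x),
              scheme_length(x) - scheme_n_b0(x),
              paste(sort(unique(round(x$bvalues[!scheme_is_b0(x)], 6))),
                    collapse = ", ")))
  invisible(x)
}

#' Scheme accessors
#'
#' `scheme_length()` is the total number of volumes, `scheme_is_b0()` a
#' logical vector flagging unweighted volumes, `scheme_n_b0()` their count.
#'
#' @param scheme A `gradient_scheme`.
#' @return See description.
#' @export
scheme_length <- function(scheme) length(scheme$bvalues)

#' @rdname scheme_length
#' @export
scheme_is_b0 <- function(scheme)
  scheme$bvalues < b_to_internal(B0_THRESHOLD_S_MM2)

#' @rdname scheme_length
#' @export
scheme_n_b0 <- function(scheme) sum(scheme_is_b0(scheme))

#' Generate an antipodally-symmetric set of diffusion directions
#'
#' Minimizes the electrostatic-repulsion energy
#' \eqn{\sum_{i<j} 1/\|g_i-g_j\| + 1/\|g_i+g_j\|}
#' over unit vectors by projected gradient descent from a seeded random
#' start (with backtracking step control and a small number of restarts).
#' Deterministic for fixed `(n, seed)`.
#'
#' @param n Number of directions (>= 2).
#' @param seed Integer seed for the random starts.
#' @param n_iter Maximum gradient-descent iterations per restart.
#' @param tol Relative energy-change convergence tolerance.
#' @return An `n x 3` matrix of unit row vectors.
#' @export
generate_directions <- function(n, seed = 1L, n_iter = 1000L, tol = 1e-8) {
  if (!is_scalar_number(n) || n < 2) stopf("n must be a single integer >= 2")
  n <- as.integer(n)
  n_restarts <- if (n <= 24L) 3L else 1L
  best <- NULL
  best_e <- Inf
  for (r in seq_len(n_restarts)) {
    g0 <- with_seed(derive_seed(seed, "dirs", n, r), {
      m <- matrix(stats::rnorm(3L * n), n, 3L)
      m / sqrt(rowSums(m^2))
    })
    res <- .descend_directions(g0, n_iter, tol)
    if (res$energy < best_e) {
      best_e <- res$energy
      best <- res$g
    }
  }
  # canonical hemisphere: flip so the largest-|component| entry is positive
  for (i in seq_len(n)) {
    k <- which.max(abs(best[i, ]))
    if (best[i, k] < 0) best[i, ] <- -best[i, ]
  }
  unname(best)
}

.pair_energy <- function(g) {
  C <- tcrossprod(g)
  n <- nrow(g)
  iu <- upper.tri(C)
  dm <- pmax(2 - 2 * C[iu], 1e-12)
  dp <- pmax(2 + 2 * C[iu], 1e-12)
  sum(1 / sqrt(dm) + 1 / sqrt(dp))
}

.descend_directions <- function(g, n_iter, tol) {
  e <- .pair_energy(g)
  step <- 0.05
  for (it in seq_len(n_iter)) {
    C <- tcrossprod(g)
    A <- pmax(2 - 2 * C, 1e-12)^(-1.5)
    B <- pmax(2 + 2 * C, 1e-12)^(-1.5)
    diag(A) <- 0
    diag(B) <- 0
    grad <- -((rowSums(A) + rowSums(B)) * g - A %*% g + B %*% g)
    # tangential component only: radial motion is removed by renormalization
    grad <- grad - rowSums(grad * g) * g
    improved <- FALSE
    while (step > 1e-14) {
      cand <- g - step * grad
      cand <- cand / sqrt(rowSums(cand^2))
      ec <- .pair_energy(cand)
      if (ec < e) {
        improved <- TRUE
        converged <- (e - ec) < tol * abs(e)
        g <- cand
        e <- ec
        step <- step * 1.2
        if (converged) return(list(g = g, energy = e))
        break
      }
      step <- step / 2
    }
    if (!improved) break
  }
  list(g = g, energy = e)
}

#' Minimum pairwise angular separation of an antipodal direction set
#'
#' Angles are computed modulo sign (antipodal symmetry), in degrees.
#'
#' @param g Matrix of unit row vectors.
#' @return Minimum pairwise angle in degrees.
#' @export
min_pairwise_angle <- function(g) {
  C <- abs(tcrossprod(as.matrix(g)))
  C[C > 1] <- 1
  min(acos(C[upper.tri(C)])) * 180 / pi
}

#' Built-in acquisition protocols
#'
#' Returns one of the three spinal-cord acquisition protocols compared by
#' the package:
#' \describe{
#'   \item{A}{126 directions, b = 700 s/mm^2, Nb0 = 10, NA = 6, NR = 1.}
#'   \item{B}{12 directions, b = 1200 s/mm^2, Nb0 = 5, NA = 4, NR = 15.}
#'   \item{C}{2 directions (slice = z and read = x) at b = 200, 400, 800,
#'     1200, 1500 s/mm^2, Nb0 = 5, NA = 4, NR = 20.}
#' }
#' Timing metadata (delta, Delta, TE, TR in ms) is carried along but the
#' mono-exponential signal model depends on it only through b.
#'
#' @param name Protocol label: "A", "B" or "C".
#' @return An object of class `acquisition_protocol` with fields `name`,
#'   `scheme`, `n_averages`, `n_repetitions`, `timing`.
#' @export
builtin_protocol <- function(name) {
  if (!is.character(name) || length(name) != 1L || !(name %in% c("A", "B", "C")))
    stopf("unknown protocol '%s'; valid labels are A, B, C",
          paste(name, collapse = ","))
  key <- paste0("protocol_", name)
  if (!is.null(.cordti_cache[[key]])) return(.cordti_cache[[key]])
  b0dir <- function(k) matrix(0, k, 3L)
  p <- switch(name,
    A = {
      dirs <- generate_directions(126L, seed = 20160825L)
      acquisition_protocol(
        name = "A",
        scheme = gradient_scheme(rbind(b0dir(10L), dirs),
                                 c(rep(0, 10L), rep(0.7, 126L))),
        n_averages = 6L, n_repetitions = 1L,
        timing = list(delta = 3, Delta = 11, TE = 22.3, TR = 2100))
    },
    B = {
      dirs <- generate_directions(12L, seed = 20160826L)
      acquisition_protocol(
        name = "B",
        scheme = gradient_scheme(rbind(b0dir(5L), dirs),
                                 c(rep(0, 5L), rep(1.2, 12L))),
        n_averages = 4L, n_repetitions = 15L,
        timing = list(delta = 4, Delta = 11, TE = 23.3, TR = 2100))
    },
    C = {
      # slice axis = phantom z, read axis = phantom x
      bset <- c(0.2, 0.4, 0.8, 1.2, 1.5)
      dirs <- rbind(matrix(rep(c(0, 0, 1), 5L), ncol = 3L, byrow = TRUE),
                    matrix(rep(c(1, 0, 0), 5L), ncol = 3L, byrow = TRUE))
      acquisition_protocol(
        name = "C",
        scheme = gradient_scheme(rbind(b0dir(5L), dirs),
                                 c(rep(0, 5L), bset, bset)),
        n_averages = 4L, n_repetitions = 20L,
        timing = list(delta = 4, Delta = 11, TE = 23.3, TR = 2100))
    })
  .cordti_cache[[key]] <- p
  p
}

#' Construct an acquisition protocol
#'
#' @param name Label, one of "A", "B", "C" or "custom".
#' @param scheme A `gradient_scheme`.
#' @param n_averages Number of complex-domain averages (NA), positive integer.
#' @param n_repetitions Number of magnitude-domain repetitions (NR).
#' @param timing Optional list with delta, Delta, TE, TR in ms.
#' @return An `acquisition_protocol` object.
#' @export
acquisition_protocol <- function(name, scheme, n_averages = 1L,
                                 n_repetitions = 1L, timing = list()) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  if (!is_scalar_number(n_averages) || n_averages < 1)
    stopf("n_averages must be a positive integer")
  if (!is_scalar_number(n_repetitions) || n_repetitions < 1)
    stopf("n_repetitions must be a positive integer")
  structure(list(name = as.character(name), scheme = scheme,
                 n_averages = as.integer(n_averages),
                 n_repetitions = as.integer(n_repetitions),
                 timing = timing),
            class = "acquisition_protocol")
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat(sprintf("<acquisition_protocol %s> NA=%d NR=%d\n",
              x$name, x$n_averages, x$n_repetitions))
  print(x$scheme)
  invisible(x)
}

#' Build a protocol from a config list
#'
#' The list mirrors the JSON config schema: fields `name`, `ndir`,
#' `bvalues_s_mm2`, `nb0`, `na`, `nr`, `seed` (seed is used to generate
#' the direction set). Each direction is acquired at every listed b-value.
#'
#' @param cfg Named list.
#' @return An `acquisition_protocol`.
#' @export
protocol_from_config <- function(cfg) {
  need <- c("name", "ndir", "bvalues_s_mm2", "nb0")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stopf("protocol config missing fields: %s",
                          paste(miss, collapse = ", "))
  ndir <- as.integer(cfg$ndir)
  bset <- b_to_internal(as.numeric(cfg$bvalues_s_mm2))
  dirs <- generate_directions(ndir, seed = cfg$seed %||% 1L)
  dmat <- dirs[rep(seq_len(ndir), each = length(bset)), , drop = FALSE]
  bvec <- rep(bset, times = ndir)
  nb0 <- as.integer(cfg$nb0)
  acquisition_protocol(
    name = cfg$name,
    scheme = gradient_scheme(rbind(matrix(0, nb0, 3L), dmat),
                             c(rep(0, nb0), bvec)),
    n_averages = cfg$na %||% 1L,
    n_repetitions = cfg$nr %||% 1L,
    timing = cfg$timing %||% list())
}

#' Log-linear DTI design matrix
#'
#' One row per volume:
#' \eqn{[-b g_x^2, -b g_y^2, -b g_z^2, -2b g_x g_y, -2b g_x g_z, -2b g_y g_z, 1]};
#' b0 rows are `[0,0,0,0,0,0,1]`. The pure `b * g g^T` b-matrix is used
#' (no imaging cross-terms).
#'
#' @param scheme A `gradient_scheme`.
#' @return Matrix of size `n_volumes x 7`.
#' @export
design_matrix <- function(scheme) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  g <- scheme$directions
  b <- scheme$bvalues
  cbind(-b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3], 1)
}

#' Rank of a scheme's design matrix
#'
#' A full tensor fit needs rank 7 (six tensor components plus intercept);
#' two-direction schemes such as protocol C are rank-deficient.
#'
#' @param scheme A `gradient_scheme`.
#' @return Integer rank.
#' @export
scheme_rank <- function(scheme) qr(design_matrix(scheme))$rank

#' Read and write FSL-dialect gradient tables
#'
#' `write_fsl_gradients()` writes a `bval` file (one space-separated row of
#' b-values in s/mm^2) and a `bvec` file (3 rows by N columns of direction
#' components, `%.6f` formatted). `read_fsl_gradients()` reads the pair
#' back into a `gradient_scheme` (b-values converted to ms/um^2, weighted
#' directions renormalized to unit length).
#'
#' @param scheme A `gradient_scheme`.
#' @param bval_path,bvec_path File paths.
#' @return `read_fsl_gradients()` returns a `gradient_scheme`;
#'   `write_fsl_gradients()` returns the two paths invisibly.
#' @export
write_fsl_gradients <- function(scheme, bval_path, bvec_path) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  writeLines(paste(sprintf("%.6f", b_to_s_mm2(scheme$bvalues)), collapse = " "),
             bval_path)
  rows <- apply(t(scheme$directions), 1L,
                function(r) paste(sprintf("%.6f", r), collapse = " "))
  writeLines(rows, bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' @rdname write_fsl_gradients
#' @export
read_fsl_gradients <- function(bval_path, bvec_path) {
  bv <- scan(bval_path, quiet = TRUE)
  gm <- as.matrix(utils::read.table(bvec_path))
  if (nrow(gm) != 3L)
    stopf("bvec file must have 3 rows, got %d", nrow(gm))
  if (ncol(gm) != length(bv))
    stopf("volume-count mismatch: %d b-values vs %d bvec columns",
          length(bv), ncol(gm))
  if (any(bv < 0)) stopf("negative b-value in %s", bval_path)
  g <- t(gm)
  nrm <- sqrt(rowSums(g^2))
  weighted <- bv >= B0_THRESHOLD_S_MM2
  bad <- weighted & (nrm < 0.99 | nrm > 1.01)
  if (any(bad))
    stopf("non-unit bvec column(s) at volume(s): %s",
          paste(which(bad), collapse = ", "))
  g[weighted, ] <- g[weighted, , drop = FALSE] / nrm[weighted]
  g[!weighted, ] <- 0
  gradient_scheme(g, b_to_internal(bv))
}
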