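# Tensor and two-direction estimators, derived metrics, angular deviation
# and frame-projected metrics.

# Default cord mask: voxels whose mean b0 signal is positive.
default_mask <- function(study) {
  b0 <- which(scheme_is_b0(study$scheme))
  dims <- dim(study$data)
  m <- matrix(study$data, prod(dims[1:3]), dims[4])
  mb0 <- rowMeans(m[, b0, drop = FALSE])
  array(mb0 > 0, dim = dims[1:3])
}

# Floor non-positive signals at eps * S0hat before taking logs; returns the
# log-signal matrix (volumes x voxels) and a per-voxel floored flag.
log_signals <- function(S) {
  s0hat <- pmax(apply(S, 2L, max), .Machine$double.xmin)
  floorv <- .Machine$double.eps * s0hat
  floored <- colSums(S < rep(floorv, each = nrow(S))) > 0
  Sf <- pmax(S, rep(floorv, each = nrow(S)))
  list(logS = log(Sf), floored = floored)
}

#' Fit the diffusion tensor field of a study
#'
#' Solves the log-linear system `log S = X beta` per voxel with the
#' scheme's [design_matrix()]. `method = "ols"` is ordinary least squares;
#' `method = "wls"` (the default) performs one re-weighting pass with
#' weights equal to the squared signals predicted by the OLS fit. Exact on
#' noiseless mono-exponential data. Non-positive signals are floored at
#' machine epsilon times the per-voxel signal maximum and flagged.
#'
#' @param study A [dwi_study()] whose scheme has design-matrix rank 7.
#' @param mask Logical 3D array selecting voxels to fit; default: voxels
#'   with positive mean b0 signal.
#' @param method "wls" or "ols".
#' @return An object of class `tensor_fit`: `tensor` (n x 6 matrix of
#'   Dxx, Dyy, Dzz, Dxy, Dxz, Dyz in um^2/ms), `s0` (fitted intercepts on
#'   the signal scale), `voxels` (linear indices into the grid), `dim`,
#'   `flag_floored`, `method`.
#' @export
fit_tensor <- function(study, mask = NULL, method = c("wls", "ols")) {
  stopifnot(inherits(study, "dwi_study"))
  method <- match.arg(method)
  X <- design_matrix(study$scheme)
  if (qr(X)$rank < 7L)
    stopf(paste("scheme is rank-deficient (rank %d < 7): the full tensor is not",
                "estimable; use fit_adc_per_direction() for two-direction schemes"),
          qr(X)$rank)
  dims <- dim(study$data)
  if (is.null(mask)) mask <- default_mask(study)
  stopifnot(identical(dim(mask), dims[1:3]))
  vox <- which(mask)
  if (length(vox) == 0L) stopf("mask selects no voxels")
  S <- matrix(study$data, prod(dims[1:3]), dims[4])[vox, , drop = FALSE]
  S <- t(S)                                   # volumes x voxels
  ls <- log_signals(S)
  qrX <- qr(X)
  beta <- qr.coef(qrX, ls$logS)               # 7 x voxels
  if (method == "wls") {
    for (j in seq_len(ncol(beta))) {
      w <- exp(2 * (X %*% beta[, j]))         # squared predicted signals
      w <- pmin(pmax(as.numeric(w), 1e-300), 1e300)
      Xw <- X * w
      # ill-conditioned weights (e.g. floored signals) fall back to OLS
      bj <- tryCatch(solve(crossprod(X, Xw), crossprod(Xw, ls$logS[, j])),
                     error = function(e) beta[, j])
      beta[, j] <- bj
    }
  }
  structure(list(tensor = t(beta[1:6, , drop = FALSE]),
                 s0 = exp(beta[7, ]),
                 voxels = vox, dim = dims[1:3],
                 flag_floored = ls$floored, method = method),
            class = "tensor_fit")
}

tensor_to_matrix <- function(d) {
  matrix(c(d[1], d[4], d[5],
           d[4], d[2], d[6],
           d[5], d[6], d[3]), 3L, 3L)
}

as_tensor_rows <- function(D) {
  if (inherits(D, "tensor_fit")) return(D$tensor)
  if (is.null(dim(D))) {
    stopifnot(length(D) == 6L)
    return(matrix(D, 1L, 6L))
  }
  stopifnot(ncol(D) == 6L)
  as.matrix(D)
}

fa_from_eigenvalues <- function(l) {
  md <- mean(l)
  den <- sum(l^2)
  if (den <= 0) return(0)
  fa <- sqrt(1.5 * sum((l - md)^2) / den)
  min(max(fa, 0), 1)
}

#' Eigen-metrics of diffusion tensors
#'
#' Eigen-decomposes each tensor (eigenvalues sorted descending) and derives
#' FA, MD = mean eigenvalue, AD = largest eigenvalue, RD = mean of the two
#' smaller eigenvalues. FA is computed on the raw (possibly negative)
#' eigenvalues and then clipped to `[0, 1]`. The principal eigenvector sign
#' is fixed so its slice-axis component is non-negative. Negative
#' eigenvalues and degenerate leading eigenvalues (`lambda1 == lambda2`
#' within tolerance) are flagged, not clamped.
#'
#' @param D A `tensor_fit`, an `n x 6` component matrix, or a length-6
#'   vector (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
#' @param slice_axis Unit 3-vector of the slice axis (for the v1 sign fix).
#' @return List of class `tensor_metrics`: `lambda` (n x 3), `v1` (n x 3),
#'   `FA`, `MD`, `AD`, `RD`, `flag_negative_eig`, `flag_degenerate`, plus
#'   `voxels`/`dim` when fitted from a study.
#' @export
tensor_metrics <- function(D, slice_axis = c(0, 0, 1)) {
  rows <- as_tensor_rows(D)
  n <- nrow(rows)
  lambda <- matrix(NA_real_, n, 3L)
  v1 <- matrix(NA_real_, n, 3L)
  FA <- MD <- AD <- RD <- numeric(n)
  neg <- degen <- logical(n)
  for (i in seq_len(n)) {
    e <- eigen(tensor_to_matrix(rows[i, ]), symmetric = TRUE)
    l <- e$values
    lambda[i, ] <- l
    vec <- e$vectors[, 1L]
    sc <- sum(vec * slice_axis)
    if (sc < 0) vec <- -vec
    v1[i, ] <- vec
    MD[i] <- mean(l)
    AD[i] <- l[1]
    RD[i] <- (l[2] + l[3]) / 2
    FA[i] <- fa_from_eigenvalues(l)
    neg[i] <- any(l < 0)
    degen[i] <- (l[1] - l[2]) <= 1e-10 * max(abs(l), 1e-30)
  }
  out <- list(lambda = lambda, v1 = v1, FA = FA, MD = MD, AD = AD, RD = RD,
              flag_negative_eig = neg, flag_degenerate = degen)
  if (inherits(D, "tensor_fit")) {
    out$voxels <- D$voxels
    out$dim <- D$dim
    out$flag_floored <- D$flag_floored
  }
  structure(out, class = "tensor_metrics")
}

#' Assemble metric maps from per-voxel metrics
#'
#' @param metrics A `tensor_metrics` carrying `voxels` and `dim` (i.e.
#'   computed from a `tensor_fit`), or a list of vectors plus explicit
#'   `voxels`/`dim`.
#' @param which Character vector of metric names to map.
#' @return Named list of 3D arrays (NA outside the fitted voxels).
#' @export
metric_maps <- function(metrics, which = DTI_METRICS) {
  stopifnot(!is.null(metrics$voxels), !is.null(metrics$dim))
  lapply(stats::setNames(which, which), function(nm) {
    a <- array(NA_real_, dim = metrics$dim)
    a[metrics$voxels] <- metrics[[nm]]
    a
  })
}

#' Per-direction ADC fit for two-direction schemes
#'
#' Per voxel, a joint log-linear fit of `log S` against b over the volumes
#' acquired along the requested axis plus all b0 volumes; the slope is
#' `-ADC`, the intercept is shared across b-values. Exact on noiseless
#' mono-exponential data.
#'
#' @param study A [dwi_study()] acquired with at least two distinct
#'   b-values (including b0) along the requested direction.
#' @param direction "slice" (phantom z axis) or "read" (x axis).
#' @param mask Logical 3D array; default as in [fit_tensor()].
#' @return List: `adc` (3D array, um^2/ms; NA outside mask), `voxels`,
#'   `dim`, `flag_floored`.
#' @export
fit_adc_per_direction <- function(study, direction = c("slice", "read"),
                                  mask = NULL) {
  stopifnot(inherits(study, "dwi_study"))
  direction <- match.arg(direction)
  axis <- if (direction == "slice") c(0, 0, 1) else c(1, 0, 0)
  g <- study$scheme$directions
  along <- !scheme_is_b0(study$scheme) & abs(as.numeric(g %*% axis)) > 0.999
  if (!any(along))
    stopf("no weighted volumes along the %s direction in this scheme", direction)
  sel <- which(along | scheme_is_b0(study$scheme))
  b <- study$scheme$bvalues[sel]
  if (length(unique(round(b, 9))) < 2L)
    stopf("need at least two distinct b-values (including b0) along %s", direction)
  dims <- dim(study$data)
  if (is.null(mask)) mask <- default_mask(study)
  vox <- which(mask)
  if (length(vox) == 0L) stopf("mask selects no voxels")
  S <- t(matrix(study$data, prod(dims[1:3]), dims[4])[vox, sel, drop = FALSE])
  ls <- log_signals(S)
  Xd <- cbind(-b, 1)
  beta <- qr.coef(qr(Xd), ls$logS)        # rows: ADC, log S0
  adc <- array(NA_real_, dim = dims[1:3])
  adc[vox] <- beta[1L, ]
  list(adc = adc, voxels = vox, dim = dims[1:3], flag_floored = ls$floored)
}

#' Two-direction (protocol C style) metrics
#'
#' From the apparent diffusivities along the slice (`adc_s`) and read
#' (`adc_r`) directions:
#' `AD_C = ADC_s`, `RD_C = ADC_r`, `MD_C = (ADC_s + 2 ADC_r) / 3`, and
#' `FA_C = sqrt(3/2) * sqrt((ADC_s - MD_C)^2 + 2 (ADC_r - MD_C)^2) /
#' sqrt(ADC_s^2 + 2 ADC_r^2)`.
#' `FA_C` is 0 exactly when `ADC_s == ADC_r`; the 0/0 case
#' (`ADC_s = ADC_r = 0`) is defined as 0 and flagged, and negative inputs
#' are flagged but computed as printed.
#'
#' @param adc_s,adc_r Numeric vectors or arrays (same shape).
#' @return List of class `twodir_metrics`: `AD`, `RD`, `MD`, `FA` (same
#'   shape as the inputs), `flag_negative`, `flag_zero`.
#' @export
two_direction_metrics <- function(adc_s, adc_r) {
  stopifnot(length(adc_s) == length(adc_r))
  dm <- dim(adc_s)
  s <- as.numeric(adc_s)
  r <- as.numeric(adc_r)
  md <- (s + 2 * r) / 3
  den <- s^2 + 2 * r^2
  num <- (s - md)^2 + 2 * (r - md)^2
  fa <- ifelse(den > 0, sqrt(1.5 * num / den), 0)
  flag_zero <- den == 0 & !is.na(den)
  flag_neg <- (s < 0 | r < 0) & !is.na(den)
  reshape <- function(x) { if (!is.null(dm)) dim(x) <- dm; x }
  structure(list(AD = reshape(s), RD = reshape(r), MD = reshape(md),
                 FA = reshape(fa),
                 flag_negative = reshape(flag_neg),
                 flag_zero = reshape(flag_zero)),
            class = "twodir_metrics")
}

#' Angular deviation from the slice axis
#'
#' `theta = arccos(|v1 . s|)` in degrees, in `[0, 90]`; the absolute value
#' reflects the sign ambiguity of fiber orientation.
#'
#' @param v1 Unit 3-vector, or an `n x 3` matrix of unit rows, or a
#'   `tensor_metrics` object (its `v1` is used; degenerate voxels yield NA).
#' @param slice_axis Unit 3-vector.
#' @return Numeric vector of angles in degrees.
#' @export
angular_deviation <- function(v1, slice_axis = c(0, 0, 1)) {
  degen <- NULL
  if (inherits(v1, "tensor_metrics")) {
    degen <- v1$flag_degenerate
    v1 <- v1$v1
  }
  if (is.null(dim(v1))) v1 <- matrix(v1, 1L, 3L)
  nrm <- sqrt(rowSums(v1^2))
  if (any(nrm < 1e-12, na.rm = TRUE)) stopf("zero eigenvector supplied")
  v1 <- v1 / nrm
  s <- slice_axis / sqrt(sum(slice_axis^2))
  ct <- pmin(abs(as.numeric(v1 %*% s)), 1)
  theta <- acos(ct) * 180 / pi
  if (!is.null(degen)) theta[degen] <- NA_real_
  theta
}

#' Frame-projected metrics
#'
#' Pseudo-eigenvalues are the diagonal tensor components in the imaging
#' frame (`axes` columns: read, phase, slice). `AD' = D_slice`,
#' `RD'` is the mean of the two in-plane diagonals (or the read diagonal
#' only with `rd_mode = "read_only"`, matching the two-direction geometry),
#' `MD'` is the mean of the three diagonals (exactly the eigenvalue MD, by
#' trace invariance), and `FA'` applies the standard FA formula to the
#' three diagonals.
#'
#' @param D A length-6 tensor, `n x 6` matrix or `tensor_fit`.
#' @param axes Orthonormal 3x3 matrix, columns = (read, phase, slice);
#'   default identity.
#' @param rd_mode "inplane_mean" (default) or "read_only".
#' @return List: `AD`, `RD`, `MD`, `FA` (frame-projected), `deviation`
#'   (list of relative deviations `(X' - X)/X` versus [tensor_metrics()]).
#' @export
frame_projected_metrics <- function(D, axes = diag(3),
                                    rd_mode = c("inplane_mean", "read_only")) {
  rd_mode <- match.arg(rd_mode)
  axes <- as.matrix(axes)
  if (max(abs(crossprod(axes) - diag(3))) > 1e-8)
    stopf("axes must be orthonormal")
  rows <- as_tensor_rows(D)
  n <- nrow(rows)
  dread <- dphase <- dslice <- numeric(n)
  for (i in seq_len(n)) {
    M <- crossprod(axes, tensor_to_matrix(rows[i, ])) %*% axes
    dread[i] <- M[1, 1]; dphase[i] <- M[2, 2]; dslice[i] <- M[3, 3]
  }
  ADp <- dslice
  RDp <- if (rd_mode == "inplane_mean") (dread + dphase) / 2 else dread
  MDp <- (dread + dphase + dslice) / 3
  FAp <- vapply(seq_len(n),
                function(i) fa_from_eigenvalues(c(dread[i], dphase[i], dslice[i])),
                numeric(1))
  tm <- tensor_metrics(rows, slice_axis = axes[, 3L])
  rel <- function(a, b) ifelse(b != 0, (a - b) / b, NA_real_)
  list(AD = ADp, RD = RDp, MD = MDp, FA = FAp,
       deviation = list(FA = rel(FAp, tm$FA), MD = rel(MDp, tm$MD),
                        AD = rel(ADp, tm$AD), RD = rel(RDp, tm$RD)))
}

#' Compute the four metric maps of a study under the appropriate estimator
#'
#' Tensor schemes (design rank 7) go through [fit_tensor()] +
#' [tensor_metrics()] and also yield the angular-deviation map `theta`;
#' rank-deficient two-direction schemes go through
#' [fit_adc_per_direction()] + [two_direction_metrics()] (`theta` is NA:
#' marked "2-dir only").
#'
#' @param study A [dwi_study()].
#' @param mask Optional logical 3D mask.
#' @param method Tensor fit method, "wls" or "ols".
#' @return List: `maps` (named list of 3D arrays FA/MD/AD/RD/theta),
#'   `estimator` ("tensor" or "2dir").
#' @export
compute_metric_maps <- function(study, mask = NULL, method = "wls") {
  if (scheme_rank(study$scheme) >= 7L) {
    fit <- fit_tensor(study, mask = mask, method = method)
    tm <- tensor_metrics(fit)
    maps <- metric_maps(tm, DTI_METRICS)
    theta <- array(NA_real_, dim = fit$dim)
    theta[fit$voxels] <- angular_deviation(tm)
    maps$theta <- theta
    list(maps = maps, estimator = "tensor")
  } else {
    fs <- fit_adc_per_direction(study, "slice", mask = mask)
    fr <- fit_adc_per_direction(study, "read", mask = mask)
    td <- two_direction_metrics(fs$adc, fr$adc)
    maps <- list(FA = td$FA, MD = td$MD, AD = td$AD, RD = td$RD,
                 theta = array(NA_real_, dim = fs$dim))
    list(maps = maps, estimator = "2dir")
  }
}

#' Write metric maps as NIfTI volumes with a JSON sidecar
#'
#' @param maps Named list of 3D arrays (e.g. from [compute_metric_maps()]).
#' @param out_dir Output directory.
#' @param voxel_mm Voxel dimensions in mm.
#' @param sidecar Extra fields recorded in the JSON sidecar (fit method,
#'   scheme hash, ...).
#' @return Invisible vector of written paths.
#' @export
write_metric_maps <- function(maps, out_dir, voxel_mm = c(1, 1, 1),
                              sidecar = list()) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stopf("cannot create output directory %s", out_dir)
  paths <- character(0)
  for (nm in names(maps)) {
    p <- file.path(out_dir, paste0(nm, ".nii"))
    x <- maps[[nm]]
    x[is.na(x)] <- 0
    nifti_write(x, p, voxel_mm = voxel_mm, datatype = "float32")
    paths <- c(paths, p)
  }
  sp <- file.path(out_dir, "maps.json")
  jsonlite::write_json(sidecar, sp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, sp))
}
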