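# Protocol-comparison statistics: SNR, CNR, inter-/intra-subject CV,
# effect size, exact/approximate Mann-Whitney, Spearman correlation.
# Sample (n-1) standard deviations throughout.

#' Signal-to-noise ratio of a volume
#'
#' `SNR = mean(tissue values) / SD(background values)` with the sample SD.
#'
#' @param volume Scalar 3D array.
#' @param rois A [roi_set()].
#' @param tissue_label Tissue ROI name (e.g. "wholeWM" or "wholeGM").
#' @param background_label Background ROI name (needs >= 100 voxels).
#' @return SNR scalar.
#' @export
snr <- function(volume, rois, tissue_label = "wholeWM",
                background_label = "background") {
  tv <- extract_roi(volume, rois, tissue_label)
  bg <- extract_roi(volume, rois, background_label)
  if (length(bg) < 100L)
    stopf("background ROI has %d voxels; need >= 100", length(bg))
  sdbg <- sample_sd(bg)
  if (sdbg == 0)
    stopf("background SD is zero (noiseless image); SNR undefined")
  mean(tv) / sdbg
}

#' Contrast-to-noise ratio between WM and GM on a parameter map
#'
#' `CNR = (M_WM - M_GM) / sqrt((SD_WM^2 + SD_GM^2) / 2)`, signed.
#'
#' @param metric_map Scalar 3D array (a DTI parameter map).
#' @param rois A [roi_set()].
#' @param wm_label,gm_label ROI names (>= 2 voxels each).
#' @return Signed CNR scalar.
#' @export
cnr <- function(metric_map, rois, wm_label = "wholeWM", gm_label = "wholeGM") {
  wm <- extract_roi(metric_map, rois, wm_label)
  gm <- extract_roi(metric_map, rois, gm_label)
  if (length(wm) < 2L || length(gm) < 2L)
    stopf("CNR needs >= 2 voxels in each ROI")
  sw <- sample_sd(wm); sg <- sample_sd(gm)
  if (sw == 0 && sg == 0) stopf("both ROI SDs are zero; CNR undefined")
  (mean(wm) - mean(gm)) / sqrt((sw^2 + sg^2) / 2)
}

#' Inter-subject coefficient of variation
#'
#' Sample SD of the per-subject ROI means divided by their mean.
#'
#' @param subject_means Numeric vector of per-subject ROI means (>= 2).
#' @return CV scalar (dimensionless).
#' @export
cv_inter <- function(subject_means) {
  if (length(subject_means) < 2L) stopf("cv_inter needs >= 2 subjects")
  m <- mean(subject_means)
  if (m == 0) stopf("mean of subject means is zero; CV undefined")
  sample_sd(subject_means) / m
}

#' Intra-subject coefficient of variation
#'
#' Per subject, within-ROI sample SD divided by within-ROI mean; the
#' summary value is the arithmetic mean of the per-subject CVs (per-subject
#' CVs are returned as well, for significance testing between protocols).
#'
#' @param voxel_values List of numeric vectors, one per subject (>= 2
#'   voxels each).
#' @return List: `cv` (mean of per-subject CVs), `per_subject`.
#' @export
cv_intra <- function(voxel_values) {
  stopifnot(is.list(voxel_values), length(voxel_values) >= 1L)
  nm <- names(voxel_values) %||% as.character(seq_along(voxel_values))
  per <- vapply(seq_along(voxel_values), function(i) {
    v <- voxel_values[[i]]
    if (length(v) < 2L) stopf("subject %s: intra-subject CV needs >= 2 voxels", nm[i])
    m <- mean(v)
    if (m == 0) stopf("subject %s: ROI mean is zero; CV undefined", nm[i])
    sample_sd(v) / m
  }, numeric(1))
  list(cv = mean(per), per_subject = stats::setNames(per, nm))
}

#' Effect size (control-referenced standardized difference)
#'
#' `ES = (mean(case) - mean(control)) / SD(control)`, signed: a lower
#' metric in the case group gives a negative ES.
#'
#' @param case_values,control_values Numeric vectors.
#' @return Signed ES scalar.
#' @export
effect_size <- function(case_values, control_values) {
  s <- sample_sd(control_values)
  if (is.na(s) || s == 0) stopf("control-group SD is zero; effect size undefined")
  (mean(case_values) - mean(control_values)) / s
}

# Exact null distribution of the Mann-Whitney U statistic by enumeration of
# all C(n+m, n) rank arrangements (cached per (n, m)).
u_null_values <- function(n, m) {
  key <- sprintf("unull_%d_%d", n, m)
  if (!is.null(.cordti_cache[[key]])) return(.cordti_cache[[key]])
  combos <- utils::combn(n + m, n)
  u <- colSums(combos) - n * (n + 1) / 2
  .cordti_cache[[key]] <- u
  u
}

#' Two-sided Mann-Whitney U test
#'
#' Exact permutation null (full enumeration of all `C(n+m, n)` rank
#' arrangements) when `n + m <= 16` and the pooled sample is tie-free;
#' otherwise the normal approximation with tie correction and continuity
#' correction. The exact two-sided p-value is the null probability of a U
#' at least as far from `nm/2` as observed.
#'
#' @param x,y Non-empty numeric vectors.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact branch;
#'   default `NULL` chooses automatically. Ties always force the
#'   approximation.
#' @return List: `U` (for the `x` sample), `p` in (0, 1], `method`.
#' @export
mann_whitney <- function(x, y, exact = NULL) {
  if (!length(x) || !length(y)) stopf("both samples must be non-empty")
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0L
  use_exact <- if (is.null(exact)) (n + m <= 16L && !has_ties) else exact
  if (use_exact && has_ties) use_exact <- FALSE
  if (use_exact) {
    u_all <- u_null_values(n, m)
    dev <- abs(u_all - n * m / 2)
    p <- mean(dev >= abs(U - n * m / 2) - 1e-9)
    method <- "exact"
  } else {
    N <- n + m
    ties <- table(pooled)
    tiecorr <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n * m / 12 * ((N + 1) - tiecorr)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - n * m / 2) - 0.5) / sqrt(sigma2)
      z <- max(z, 0)
      p <- min(1, 2 * stats::pnorm(-z))
    }
    method <- "normal_approx"
  }
  list(U = U, p = max(p, .Machine$double.xmin), method = method)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Spearman rank correlation with two-sided p-value
#'
#' `rho` is the Pearson correlation of mid-ranks (average ranks on ties).
#' The p-value uses exact enumeration of all `n!` permutations for
#' `n <= 8` (default) and the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` otherwise.
#'
#' @param x,y Equal-length numeric vectors, length >= 3, non-constant.
#' @param exact Force or forbid exact enumeration; default `NULL` chooses
#'   `n <= 8`.
#' @return List: `rho`, `p`, `method`.
#' @export
spearman_cor <- function(x, y, exact = NULL) {
  n <- length(x)
  if (n != length(y)) stopf("x and y must have equal length")
  if (n < 3L) stopf("spearman_cor needs length >= 3")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stopf("rank correlation undefined for a constant input vector")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  use_exact <- if (is.null(exact)) n <= 8L else exact
  if (use_exact) {
    xc <- rx - mean(rx)
    yc <- ry - mean(ry)
    perms <- all_permutations(n)
    denom <- sqrt(sum(xc^2) * sum(yc^2))
    rho_perm <- as.numeric((matrix(yc[perms], nrow(perms), n) %*% xc) / denom)
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    r2 <- min(rho^2, 1 - 1e-15)
    tstat <- rho * sqrt((n - 2) / (1 - r2))
    p <- min(1, 2 * stats::pt(-abs(tstat), df = n - 2))
    method <- "t_approx"
  }
  list(rho = rho, p = max(p, .Machine$double.xmin), method = method)
}

#' Benjamini-Hochberg adjustment (off by default in the pipeline)
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
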