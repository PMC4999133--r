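# Synthetic spinal-cord phantom: procedural cross-section, ground-truth
# axisymmetric tensors per tissue, diffusion-weighted signal synthesis and
# Rician magnitude noise with the scanner's averaging structure.

ROI_LABELS <- c(background = 0L, vWM = 1L, dWM = 2L, vlWM = 3L, dlWM = 4L,
                vGM = 5L, dGM = 6L)
ROI_NAMES <- c("vWM", "dWM", "vlWM", "dlWM", "vGM", "dGM")
WM_ROIS <- c("vWM", "dWM", "vlWM", "dlWM")
GM_ROIS <- c("vGM", "dGM")
DTI_METRICS <- c("FA", "MD", "AD", "RD")

#' Default tissue parameters for the spinal-cord phantom
#'
#' Axisymmetric tensors per tissue: axial diffusivity AD and radial
#' diffusivity RD in um^2/ms, unweighted signal S0 in arbitrary units, and
#' the principal axis (the cord runs along the slice axis z; the
#' dorso-lateral WM sector is tilted by `dlwm_tilt_deg` about y to give the
#' angular-deviation analysis something to measure). WM values AD = 1.5,
#' RD = 0.25 and GM values AD = 0.85, RD = 0.65 are typical rodent-cord
#' literature values; S0(WM) = 0.8 * S0(GM) creates b0 contrast.
#'
#' With `biexp = TRUE` each tissue also carries a fast/slow bi-exponential
#' split `(f, fast_scale, slow_scale)` with volume-weighted tangent
#' diffusivity equal to the mono-exponential tensor
#' (`f*fast + (1-f)*slow = 1`).
#'
#' @param biexp Add bi-exponential compartment parameters.
#' @param dlwm_tilt_deg Tilt (degrees) of the dlWM principal axis.
#' @return Named list of per-tissue parameter lists.
#' @export
default_tissue_params <- function(biexp = FALSE, dlwm_tilt_deg = 10) {
  zaxis <- c(0, 0, 1)
  tilt <- dlwm_tilt_deg * pi / 180
  taxis <- c(sin(tilt), 0, cos(tilt))
  wm <- function(axis) list(AD = 1.5, RD = 0.25, S0 = 800, axis = axis)
  gm <- function() list(AD = 0.85, RD = 0.65, S0 = 1000, axis = zaxis)
  tp <- list(vWM = wm(zaxis), dWM = wm(zaxis), vlWM = wm(zaxis),
             dlWM = wm(taxis), vGM = gm(), dGM = gm())
  if (biexp) {
    tp <- lapply(tp, function(t) {
      t$biexp <- list(f = 0.7, fast_scale = 1.3, slow_scale = 0.3)
      t
    })
  }
  tp
}

#' Default disease effects
#'
#' Fractional shifts of the ground-truth AD and RD applied to diseased
#' (G93A) subjects, per ROI and timepoint. Signs follow the week-17 pattern
#' reported for tensor protocols in ALS-model cord: FA, MD and AD decrease
#' in all ROIs; RD increases in WM and decreases in GM. Week-10 effects are
#' the same pattern at roughly one third the size (pre-symptomatic stage).
#' Magnitudes are a package choice (no ground-truth units are published).
#'
#' @return Nested list `timepoint -> roi -> list(AD=, RD=)` of fractional
#'   shifts.
#' @export
default_disease_effects <- function() {
  wm17 <- list(AD = -0.15, RD = 0.08)
  gm17 <- list(AD = -0.12, RD = -0.10)
  wm10 <- list(AD = -0.05, RD = 0.025)
  gm10 <- list(AD = -0.04, RD = -0.03)
  list(
    week10 = c(stats::setNames(rep(list(wm10), 4), WM_ROIS),
               stats::setNames(rep(list(gm10), 2), GM_ROIS)),
    week17 = c(stats::setNames(rep(list(wm17), 4), WM_ROIS),
               stats::setNames(rep(list(gm17), 2), GM_ROIS))
  )
}

#' Specify a synthetic spinal-cord phantom
#'
#' @param grid Integer 3-vector of voxel counts (nx, ny, nz). The default
#'   matches the acquisition geometry (in-plane matrix at 0.078 x 0.109 mm
#'   over a 1.4 x 1 cm^2 field of view, 8 slices of 0.8 mm).
#' @param voxel_mm Voxel size in mm.
#' @param tissue_params Per-tissue parameters, see [default_tissue_params()].
#' @param noise_sigma Per-channel Gaussian noise SD, in S0 units.
#' @param subject_cv Fractional inter-subject SD applied multiplicatively to
#'   AD and RD (one draw per tissue per subject).
#' @param disease_effects See [default_disease_effects()].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(128L, 180L, 8L),
                         voxel_mm = c(0.078, 0.109, 0.8),
                         tissue_params = default_tissue_params(),
                         noise_sigma = 130,
                         subject_cv = 0.05,
                         disease_effects = default_disease_effects()) {
  grid <- as.integer(grid)
  stopifnot(length(grid) == 3L, all(grid >= 1L),
            length(voxel_mm) == 3L, all(voxel_mm > 0))
  miss <- setdiff(ROI_NAMES, names(tissue_params))
  if (length(miss)) stopf("tissue_params missing: %s", paste(miss, collapse = ", "))
  for (nm in ROI_NAMES) {
    t <- tissue_params[[nm]]
    if (!(t$AD > 0 && t$RD > 0)) stopf("%s: diffusivities must be positive", nm)
    if (nm %in% WM_ROIS && t$AD < t$RD)
      stopf("%s: WM requires AD >= RD", nm)
    if (t$S0 <= 0) stopf("%s: S0 must be positive", nm)
    if (!is.null(t$biexp)) {
      f <- t$biexp$f
      if (!(f >= 0 && f <= 1)) stopf("%s: bi-exponential fraction f must be in [0,1]", nm)
    }
    ax <- t$axis
    if (abs(sqrt(sum(ax^2)) - 1) > 1e-9) stopf("%s: axis must be a unit vector", nm)
  }
  if (!is_scalar_number(noise_sigma) || noise_sigma < 0)
    stopf("noise_sigma must be a non-negative number")
  if (!is_scalar_number(subject_cv) || subject_cv < 0)
    stopf("subject_cv must be a non-negative number")
  for (tp in names(disease_effects)) {
    for (roi in names(disease_effects[[tp]])) {
      eff <- disease_effects[[tp]][[roi]]
      for (m in intersect(c("FA", "MD", "AD"), names(eff)))
        if (eff[[m]] > 0)
          stopf("disease effect on %s in %s must be <= 0 (disease lowers FA/MD/AD)", m, roi)
    }
  }
  structure(list(grid = grid, voxel_mm = voxel_mm,
                 tissue_params = tissue_params, noise_sigma = noise_sigma,
                 subject_cv = subject_cv, disease_effects = disease_effects),
            class = "phantom_spec")
}

#' Procedural cord cross-section label map
#'
#' An elliptical cord centered in the field of view: the inner region is
#' gray matter split into ventral/dorsal halves, the outer annulus is white
#' matter split into four sectors (ventral, dorsal, ventro-lateral,
#' dorso-lateral) by polar angle. All slices are identical (the lumbar cord
#' is approximately straight and the slices perpendicular to it).
#'
#' @param grid Integer 3-vector (nx, ny, nz).
#' @return Integer 3D array with the labels of `ROI_LABELS`.
#' @export
make_label_map <- function(grid) {
  grid <- as.integer(grid)
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  rx <- 0.42 * nx; ry <- 0.42 * ny
  u <- (seq_len(nx) - cx) / rx
  v <- (seq_len(ny) - cy) / ry
  U <- matrix(u, nx, ny)
  V <- matrix(v, nx, ny, byrow = TRUE)
  r2 <- U^2 + V^2
  phi <- atan2(V, U) * 180 / pi        # dorsal = +y
  sl <- matrix(ROI_LABELS[["background"]], nx, ny)
  in_cord <- r2 <= 1
  in_gm <- r2 <= 0.55^2
  sl[in_gm & V > 0] <- ROI_LABELS[["dGM"]]
  sl[in_gm & V <= 0] <- ROI_LABELS[["vGM"]]
  wm <- in_cord & !in_gm
  sl[wm & phi > 45 & phi < 135] <- ROI_LABELS[["dWM"]]
  sl[wm & phi < -45 & phi > -135] <- ROI_LABELS[["vWM"]]
  lateral <- wm & (abs(phi) <= 45 | abs(phi) >= 135)
  sl[lateral & V > 0] <- ROI_LABELS[["dlWM"]]
  sl[lateral & V <= 0] <- ROI_LABELS[["vlWM"]]
  present <- ROI_LABELS[ROI_NAMES] %in% sl
  if (!all(present))
    stopf("grid %s too small: missing ROI label(s) %s", paste(grid, collapse = "x"),
          paste(ROI_NAMES[!present], collapse = ", "))
  array(rep(sl, nz), dim = c(nx, ny, nz))
}

# Axisymmetric tensor with given axial/radial diffusivity and principal axis,
# returned as the 6-vector (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
axisym_tensor <- function(AD, RD, axis) {
  D <- RD * diag(3) + (AD - RD) * tcrossprod(axis)
  c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}

# Closed-form FA of an axisymmetric tensor (eigenvalues AD, RD, RD).
fa_axisym <- function(AD, RD) {
  md <- (AD + 2 * RD) / 3
  num <- (AD - md)^2 + 2 * (RD - md)^2
  den <- AD^2 + 2 * RD^2
  if (den <= 0) return(0)
  sqrt(1.5 * num / den)
}

# Solve for the RD giving a target FA at fixed AD (used when disease effects
# are specified on FA directly).
rd_for_fa <- function(AD, fa_target) {
  if (fa_target <= 0) return(AD)
  f <- function(rd) fa_axisym(AD, rd) - fa_target
  stats::uniroot(f, lower = 1e-9, upper = AD, tol = 1e-12)$root
}

#' Build one synthetic subject
#'
#' Per-subject tissue parameters are the spec values scaled by
#' `(1 + eps)` with `eps ~ Normal(0, subject_cv)`, one draw per tissue per
#' subject (applied jointly to AD and RD). Diseased ("G93A") subjects are
#' additionally scaled by the fractional disease effects for their
#' timepoint: AD and RD shifts are applied directly; an `FA` entry, if
#' present, adjusts RD (at fixed AD) so that FA reaches the shifted value.
#' Deterministic given `(subject_id, seed)` — the biological draw does not
#' depend on group or timepoint, so the same animal keeps its anatomy
#' across sessions.
#'
#' @param spec A `phantom_spec`.
#' @param subject_id Character or integer subject identifier.
#' @param group "WT" or "G93A".
#' @param timepoint Timepoint label, e.g. "week10" or "week17".
#' @param seed Integer base seed.
#' @return An object of class `subject_phantom` with the label map, the
#'   per-tissue realized parameters (`tissue`), per-tissue ground-truth
#'   metrics (`truth`), and metadata.
#' @export
make_subject <- function(spec, subject_id, group = c("WT", "G93A"),
                         timepoint = "week17", seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  group <- match.arg(group)
  label_map <- make_label_map(spec$grid)
  eps <- with_seed(derive_seed(seed, "subject", subject_id), {
    stats::setNames(stats::rnorm(length(ROI_NAMES), 0, spec$subject_cv),
                    ROI_NAMES)
  })
  tissue <- spec$tissue_params[ROI_NAMES]
  for (nm in ROI_NAMES) {
    sc <- 1 + eps[[nm]]
    tissue[[nm]]$AD <- tissue[[nm]]$AD * sc
    tissue[[nm]]$RD <- tissue[[nm]]$RD * sc
    if (group == "G93A") {
      eff <- spec$disease_effects[[timepoint]][[nm]]
      if (!is.null(eff)) {
        if (!is.null(eff$AD)) tissue[[nm]]$AD <- tissue[[nm]]$AD * (1 + eff$AD)
        if (!is.null(eff$RD)) tissue[[nm]]$RD <- tissue[[nm]]$RD * (1 + eff$RD)
        if (!is.null(eff$FA)) {
          fa0 <- fa_axisym(tissue[[nm]]$AD, tissue[[nm]]$RD)
          tissue[[nm]]$RD <- rd_for_fa(tissue[[nm]]$AD, (1 + eff$FA) * fa0)
        }
      }
    }
    tissue[[nm]]$tensor <- axisym_tensor(tissue[[nm]]$AD, tissue[[nm]]$RD,
                                         tissue[[nm]]$axis)
  }
  truth <- do.call(rbind, lapply(ROI_NAMES, function(nm) {
    t <- tissue[[nm]]
    data.frame(roi = nm,
               metric = DTI_METRICS,
               value = c(fa_axisym(t$AD, t$RD), (t$AD + 2 * t$RD) / 3,
                         t$AD, t$RD))
  }))
  structure(list(label_map = label_map, tissue = tissue, truth = truth,
                 subject_id = as.character(subject_id), group = group,
                 timepoint = timepoint, grid = spec$grid,
                 voxel_mm = spec$voxel_mm),
            class = "subject_phantom")
}

#' Ground-truth tensor field of a subject
#'
#' @param subject A `subject_phantom`.
#' @return Matrix `n_cord_voxels x 6` of tensor components
#'   (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) in raster order over in-cord voxels.
#' @export
subject_tensor_field <- function(subject) {
  idx <- which(subject$label_map > 0L)
  lab <- subject$label_map[idx]
  tens <- t(vapply(subject$tissue, function(t) t$tensor, numeric(6)))
  out <- tens[match(lab, ROI_LABELS[rownames(tens)]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate noiseless diffusion-weighted signals
#'
#' Mono-exponential: `S = S0 * exp(-b * g' D g)` per voxel and volume.
#' Bi-exponential (tissues carrying a `biexp` entry):
#' `S = S0 * (f * exp(-b g' Df g) + (1-f) * exp(-b g' Ds g))` with
#' `Df = fast_scale * D`, `Ds = slow_scale * D`. Background voxels are 0.
#'
#' @param subject A `subject_phantom`.
#' @param protocol An `acquisition_protocol` (or a bare `gradient_scheme`).
#' @return 4D array `(nx, ny, nz, n_volumes)` of non-negative signals.
#' @export
simulate_signal <- function(subject, protocol) {
  scheme <- if (inherits(protocol, "acquisition_protocol")) protocol$scheme
            else protocol
  stopifnot(inherits(scheme, "gradient_scheme"))
  g <- scheme$directions
  b <- scheme$bvalues
  nvol <- length(b)
  dims <- dim(subject$label_map)
  data <- array(0, dim = c(dims, nvol))
  nvox <- prod(dims)
  for (nm in ROI_NAMES) {
    t <- subject$tissue[[nm]]
    # g' D g for the axisymmetric tensor: RD + (AD-RD) (g.axis)^2
    proj2 <- as.numeric(g %*% t$axis)^2
    gDg <- t$RD + (t$AD - t$RD) * proj2
    s <- if (is.null(t$biexp)) {
      t$S0 * exp(-b * gDg)
    } else {
      be <- t$biexp
      t$S0 * (be$f * exp(-b * be$fast_scale * gDg) +
              (1 - be$f) * exp(-b * be$slow_scale * gDg))
    }
    vox <- which(subject$label_map == ROI_LABELS[[nm]])
    for (v in seq_len(nvol)) data[vox + (v - 1) * nvox] <- s[v]
  }
  data
}

#' Add Rician noise and apply the protocol's averaging structure
#'
#' The NA signal averages are combined in the complex domain (k-space
#' averaging as performed on the scanner), so each reconstructed magnitude
#' volume sees per-channel noise `sigma / sqrt(NA)`. The NR repetitions are
#' reconstructed independently and then averaged in the magnitude domain
#' (registration-then-averaging). `sigma = 0` returns the input unchanged.
#' Deterministic for fixed `seed`.
#'
#' @param noiseless 4D array of noiseless signals.
#' @param protocol An `acquisition_protocol` (provides NA, NR and, when
#'   `meta` is supplied, the scheme of the returned study).
#' @param sigma Per-channel Gaussian SD, in S0 units (>= 0).
#' @param seed Integer seed.
#' @param meta Optional metadata list; when supplied a [dwi_study()] is
#'   returned instead of a bare array.
#' @return 4D array of averaged magnitudes, or a `dwi_study` when `meta`
#'   is given.
#' @export
add_noise_and_average <- function(noiseless, protocol, sigma, seed = 1L,
                                  meta = NULL) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  if (!is_scalar_number(sigma) || sigma < 0)
    stopf("sigma must be a non-negative number")
  out <- if (sigma == 0) {
    noiseless
  } else {
    sig_eff <- sigma / sqrt(protocol$n_averages)
    nr <- protocol$n_repetitions
    n <- length(noiseless)
    acc <- with_seed(derive_seed(seed, "noise"), {
      a <- numeric(n)
      for (r in seq_len(nr)) {
        re <- noiseless + stats::rnorm(n, 0, sig_eff)
        im <- stats::rnorm(n, 0, sig_eff)
        a <- a + sqrt(re * re + im * im)
      }
      a / nr
    })
    array(acc, dim = dim(noiseless))
  }
  if (is.null(meta)) return(out)
  dwi_study(out, voxel_mm = meta$voxel_mm %||% c(1, 1, 1),
            scheme = protocol$scheme, meta = meta)
}

#' Simulate one study (signal synthesis + noise + averaging)
#'
#' @param subject A `subject_phantom`.
#' @param protocol An `acquisition_protocol`.
#' @param sigma Per-channel noise SD.
#' @param seed Integer seed.
#' @return A [dwi_study()].
#' @export
simulate_study <- function(subject, protocol, sigma, seed = 1L) {
  noiseless <- simulate_signal(subject, protocol)
  meta <- list(subject_id = subject$subject_id, group = subject$group,
               timepoint = subject$timepoint, protocol = protocol$name,
               voxel_mm = subject$voxel_mm)
  add_noise_and_average(noiseless, protocol, sigma,
                        seed = derive_seed(seed, subject$subject_id,
                                           subject$timepoint, protocol$name),
                        meta = meta)
}

#' Simulate a cohort under one or more protocols
#'
#' Every subject is simulated under all requested protocols from the same
#' underlying phantom (within-session consistency); the per-ROI ground-truth
#' metrics of every subject are recorded for recovery tests.
#'
#' @param spec A `phantom_spec`.
#' @param n_per_group Subjects per group (>= 2).
#' @param groups Character vector of groups ("WT", "G93A").
#' @param timepoints Character vector of timepoints.
#' @param protocols List of `acquisition_protocol` objects (or protocol
#'   labels understood by [builtin_protocol()]).
#' @param seed Integer base seed.
#' @return List with `studies` (list of `dwi_study`), `truth` (tidy
#'   data.frame: subject, group, timepoint, roi, metric, value),
#'   `label_map`, and `rois` (a [roi_set()]).
#' @export
make_cohort <- function(spec, n_per_group = 7L, groups = c("WT", "G93A"),
                        timepoints = c("week10", "week17"),
                        protocols = list("B"), seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_per_group < 2) stopf("n_per_group must be >= 2")
  protocols <- lapply(protocols, function(p) {
    if (inherits(p, "acquisition_protocol")) p else builtin_protocol(p)
  })
  studies <- list()
  truth <- list()
  label_map <- NULL
  for (grp in groups) {
    for (i in seq_len(n_per_group)) {
      sid <- sprintf("%s%02d", grp, i)
      for (tp in timepoints) {
        subject <- make_subject(spec, sid, grp, tp, seed = seed)
        if (is.null(label_map)) label_map <- subject$label_map
        tr <- subject$truth
        tr$subject <- sid; tr$group <- grp; tr$timepoint <- tp
        truth[[length(truth) + 1L]] <- tr
        for (p in protocols) {
          st <- simulate_study(subject, p, spec$noise_sigma, seed = seed)
          studies[[paste(sid, tp, p$name, sep = "_")]] <- st
        }
      }
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(studies = studies,
       truth = truth[, c("subject", "group", "timepoint", "roi", "metric", "value")],
       label_map = label_map,
       rois = roi_set(label_map))
}

#' Write a cohort's ground-truth registry as tidy TSV
#'
#' @param cohort Result of [make_cohort()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_truth_tsv <- function(cohort, path) {
  utils::write.table(cohort$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
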