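test_that("label map contains all six ROIs on every slice and rejects tiny grids", {
  lm <- make_label_map(c(24, 24, 3))
  for (z in 1:3)
    expect_setequal(setdiff(unique(as.vector(lm[, , z])), 0L), 1:6)
  # background occupies a substantial share of the FOV
  expect_gt(mean(lm == 0L), 0.3)
  expect_error(make_label_map(c(3, 3, 1)), "too small")
})

test_that("zero-variance WT subject reproduces the spec parameters exactly", {
  spec <- tiny_spec(subject_cv = 0)
  sub <- make_subject(spec, "s1", "WT", "week17", seed = 1)
  for (nm in c("vWM", "vGM")) {
    expect_identical(sub$tissue[[nm]]$AD, spec$tissue_params[[nm]]$AD)
    expect_identical(sub$tissue[[nm]]$RD, spec$tissue_params[[nm]]$RD)
  }
  # truth registry FA consistent with the registered AD/RD
  tr <- sub$truth
  for (roi in unique(tr$roi)) {
    v <- setNames(tr$value[tr$roi == roi], tr$metric[tr$roi == roi])
    expect_equal(v[["MD"]], (v[["AD"]] + 2 * v[["RD"]]) / 3, tolerance = 1e-12)
    expect_equal(v[["FA"]], cordti:::fa_axisym(v[["AD"]], v[["RD"]]),
                 tolerance = 1e-12)
  }
})

test_that("subject draws differ by subject_id but not by timepoint", {
  spec <- tiny_spec(subject_cv = 0.1)
  a <- make_subject(spec, "s1", "WT", "week10", seed = 9)
  b <- make_subject(spec, "s2", "WT", "week10", seed = 9)
  a2 <- make_subject(spec, "s1", "WT", "week17", seed = 9)
  expect_false(isTRUE(all.equal(a$tissue$vWM$AD, b$tissue$vWM$AD)))
  expect_identical(a$tissue$vWM$AD, a2$tissue$vWM$AD)  # same animal, same anatomy
})

test_that("an FA disease effect adjusts RD by root-finding at fixed AD", {
  eff <- list(week17 = list(vWM = list(FA = -0.1)))
  spec <- tiny_spec(subject_cv = 0, disease_effects = eff)
  wt <- make_subject(spec, "s1", "WT", "week17", seed = 1)
  dz <- make_subject(spec, "s1", "G93A", "week17", seed = 1)
  expect_identical(dz$tissue$vWM$AD, wt$tissue$vWM$AD)
  fa_wt <- cordti:::fa_axisym(wt$tissue$vWM$AD, wt$tissue$vWM$RD)
  fa_dz <- cordti:::fa_axisym(dz$tissue$vWM$AD, dz$tissue$vWM$RD)
  expect_equal(fa_dz, 0.9 * fa_wt, tolerance = 1e-9)
  expect_gt(dz$tissue$vWM$RD, wt$tissue$vWM$RD)
})

test_that("disease effects must not raise FA/MD/AD", {
  eff <- list(week17 = list(vWM = list(AD = +0.1)))
  expect_error(tiny_spec(disease_effects = eff), "must be <= 0")
})

test_that("simulated signals follow the mono- and bi-exponential models", {
  # scalar oracle: S0=1000, b=1.2 along the principal axis, AD=1.5
  spec <- tiny_spec(subject_cv = 0)
  spec$tissue_params$vGM$S0 <- 1000
  sub <- make_subject(spec, "s1", "WT", "week17", seed = 1)
  sch <- gradient_scheme(rbind(c(0, 0, 0), c(0, 0, 1)), c(0, 1.2))
  p <- acquisition_protocol("custom", sch)
  sig <- simulate_signal(sub, p)
  vox <- which(sub$label_map == 1L)[1]           # a vWM voxel (AD = 1.5)
  idx <- arrayInd(vox, dim(sub$label_map))
  expect_equal(sig[idx[1], idx[2], idx[3], 2],
               800 * exp(-1.2 * 1.5), tolerance = 1e-12)
  expect_equal(1000 * exp(-1.2 * 1.5), 165.2989, tolerance = 1e-4)
  # b0 volume equals S0 everywhere in cord, 0 outside
  expect_true(all(sig[, , , 1][sub$label_map > 0] %in% c(800, 1000)))
  expect_true(all(sig[, , , 1][sub$label_map == 0] == 0))

  # bi-exponential with f = 1 degenerates to mono with the fast compartment
  tp <- default_tissue_params(biexp = TRUE)
  for (nm in names(tp)) tp[[nm]]$biexp <- list(f = 1, fast_scale = 1,
                                               slow_scale = 0.3)
  spec_bi <- tiny_spec(tissue_params = tp, subject_cv = 0)
  sub_bi <- make_subject(spec_bi, "s1", "WT", "week17", seed = 1)
  expect_equal(simulate_signal(sub_bi, p), sig, tolerance = 1e-12)
})

test_that("noise model matches Rayleigh/Rician closed forms", {
  pB <- builtin_protocol("B")
  p1 <- acquisition_protocol("custom", pB$scheme, n_averages = 4,
                             n_repetitions = 1)
  # sigma = 0 is the exact identity
  x <- array(abs(rnorm(4 * 4 * 2 * 17)), dim = c(4, 4, 2, 17))
  expect_identical(add_noise_and_average(x, p1, 0, seed = 1), x)
  expect_error(add_noise_and_average(x, p1, -1), "non-negative")

  # background (S = 0): magnitude is Rayleigh(sigma_eff)
  sigma <- 40
  sig_eff <- sigma / sqrt(4)
  z <- array(0, dim = c(50, 50, 4, 1))
  zn <- add_noise_and_average(z, acquisition_protocol("x", gradient_scheme(
    matrix(0, 1, 3), 0), n_averages = 4, n_repetitions = 1), sigma, seed = 3)
  expect_lt(abs(mean(zn) / (sig_eff * sqrt(pi / 2)) - 1), 0.02)
  expect_lt(abs(sd(zn) / (sig_eff * sqrt(2 - pi / 2)) - 1), 0.02)

  # high SNR: Rician mean within 1% of S; oracle = Laguerre/Bessel closed form
  S <- 10 * sig_eff
  sn <- add_noise_and_average(array(S, dim = c(50, 50, 4, 1)),
                              acquisition_protocol("x", gradient_scheme(
                                matrix(0, 1, 3), 0), 4, 1), sigma, seed = 4)
  rician_mean <- function(nu, s) {
    # sigma*sqrt(pi/2)*L_{1/2}(-nu^2/2sigma^2); the e^{x/2} of the Laguerre
    # form cancels against the scaling of the exponentially-scaled Bessels
    x <- -nu^2 / (2 * s^2)
    s * sqrt(pi / 2) * ((1 - x) * besselI(-x / 2, 0, expon.scaled = TRUE) -
                          x * besselI(-x / 2, 1, expon.scaled = TRUE))
  }
  expect_lt(abs(mean(sn) - S) / S, 0.01)
  expect_equal(mean(sn), rician_mean(S, sig_eff), tolerance = 0.005)
})

test_that("make_cohort is deterministic and complete", {
  spec <- tiny_spec(grid = c(16, 16, 1))
  pB <- builtin_protocol("B")
  pC <- builtin_protocol("C")
  co <- make_cohort(spec, n_per_group = 2, groups = c("WT", "G93A"),
                    timepoints = c("week10", "week17"),
                    protocols = list(pB, pC), seed = 5)
  expect_length(co$studies, 2 * 2 * 2 * 2)       # subjects x groups x tps x protocols
  co2 <- make_cohort(spec, n_per_group = 2, groups = c("WT", "G93A"),
                     timepoints = c("week10", "week17"),
                     protocols = list(pB, pC), seed = 5)
  expect_identical(co$studies[[1]]$data, co2$studies[[1]]$data)
  expect_identical(co$truth, co2$truth)
  # truth registry has one row per subject/timepoint/roi/metric
  expect_equal(nrow(co$truth), 4 * 2 * 6 * 4)
})

test_that("noise is the only stochastic element at fixed phantom parameters", {
  spec <- tiny_spec(grid = c(20, 20, 2), subject_cv = 0)
  pB <- builtin_protocol("B")
  sub <- make_subject(spec, "s1", "WT", "week17", seed = 1)
  rois <- roi_set(sub$label_map)
  md_mean <- function(seed) {
    st <- simulate_study(sub, pB, sigma = spec$noise_sigma, seed = seed)
    mm <- compute_metric_maps(st, mask = sub$label_map > 0)
    v <- extract_roi(mm$maps$MD, rois, "wholeWM")
    c(mean(v), sd(v) / sqrt(length(v)))
  }
  a <- md_mean(11); b <- md_mean(12)
  expect_lt(abs(a[1] - b[1]), 3 * sqrt(a[2]^2 + b[2]^2))
})

test_that("averaged protocol-B b0 SNR exceeds protocol-A weighted-volume SNR", {
  spec <- tiny_spec(grid = c(32, 32, 1))
  sub <- make_subject(spec, "s1", "WT", "week17", seed = 1)
  rois <- roi_set(sub$label_map)
  stA <- simulate_study(sub, builtin_protocol("A"), spec$noise_sigma, seed = 2)
  stB <- simulate_study(sub, builtin_protocol("B"), spec$noise_sigma, seed = 2)
  wA <- which(!scheme_is_b0(stA$scheme))[1]
  bB <- which(scheme_is_b0(stB$scheme))[1]
  vA <- stA$data[, , , wA]; dim(vA) <- dim(sub$label_map)
  vB <- stB$data[, , , bB]; dim(vB) <- dim(sub$label_map)
  snrA <- snr(vA, rois, "wholeWM")
  snrB <- snr(vB, rois, "wholeWM")
  expect_gt(snrB, snrA)
})
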