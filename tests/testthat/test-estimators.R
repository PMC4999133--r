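test_that("noiseless tensor fit is exact and matches a pseudo-inverse oracle", {
  spec <- tiny_spec(grid = c(16, 16, 1))
  fx <- tiny_study(builtin_protocol("B"), spec = spec)
  fit <- fit_tensor(fx$study, mask = fx$mask, method = "ols")
  truth <- subject_tensor_field(fx$subject)
  expect_lt(max(abs(fit$tensor - truth)), 1e-10)
  # intercept recovers S0 exactly
  s0_truth <- vapply(fx$subject$label_map[fx$mask],
                     function(l) fx$subject$tissue[[names(which(
                       cordti:::ROI_LABELS == l))]]$S0, numeric(1))
  expect_lt(max(abs(fit$s0 / s0_truth - 1)), 1e-8)
  # WLS agrees on noiseless data
  fitw <- fit_tensor(fx$study, mask = fx$mask, method = "wls")
  expect_lt(max(abs(fitw$tensor - truth)), 1e-9)

  # independent oracle: SVD pseudo-inverse normal-equations solution
  X <- design_matrix(fx$study$scheme)
  dims <- dim(fx$study$data)
  vox <- which(fx$mask)
  S <- matrix(fx$study$data, prod(dims[1:3]), dims[4])[vox[1:5], , drop = FALSE]
  Y <- t(log(S))
  sv <- svd(X)
  beta_or <- sv$v %*% (crossprod(sv$u, Y) / sv$d)
  expect_lt(max(abs(t(beta_or[1:6, ]) - fit$tensor[1:5, ])), 1e-10)

  expect_error(fit_tensor(dwi_study(array(1, c(2, 2, 1, 15)), c(1, 1, 1),
                                    builtin_protocol("C")$scheme, list())),
               "fit_adc_per_direction")
})

test_that("tensor_metrics matches hand values and a char-poly eigensolver", {
  iso <- tensor_metrics(c(0.7, 0.7, 0.7, 0, 0, 0))
  expect_equal(iso$FA, 0)
  expect_equal(iso$MD, 0.7)
  expect_equal(iso$AD, 0.7)
  expect_equal(iso$RD, 0.7)

  ax <- tensor_metrics(c(1.5, 0.3, 0.3, 0, 0, 0))
  expect_equal(ax$MD, 0.7, tolerance = 1e-12)
  expect_equal(ax$AD, 1.5, tolerance = 1e-12)
  expect_equal(ax$RD, 0.3, tolerance = 1e-12)
  # closed form: sqrt(3/2)*sqrt(0.64 + 2*0.16)/sqrt(2.25 + 2*0.09)
  expect_equal(ax$FA, sqrt(1.5 * 0.96 / 2.43), tolerance = 1e-12)
  expect_equal(ax$FA, 0.7698004, tolerance = 1e-7)

  r1 <- tensor_metrics(c(1, 0, 0, 0, 0, 0))
  expect_equal(r1$FA, 1)

  # characteristic-polynomial oracle on random symmetric tensors
  set.seed(42)
  for (i in 1:20) {
    d <- rnorm(6)
    tm <- tensor_metrics(d)
    Dm <- matrix(c(d[1], d[4], d[5], d[4], d[2], d[6], d[5], d[6], d[3]), 3, 3)
    ev <- sort(Re(polyroot(c(-det(Dm),
                             (Dm[1,1]*Dm[2,2] - Dm[1,2]^2 +
                              Dm[1,1]*Dm[3,3] - Dm[1,3]^2 +
                              Dm[2,2]*Dm[3,3] - Dm[2,3]^2),
                             -sum(diag(Dm)), 1))), decreasing = TRUE)
    expect_equal(as.numeric(tm$lambda), ev, tolerance = 1e-8)
  }

  # v1 sign convention and degenerate flag
  tl <- tensor_metrics(c(0.3, 0.3, 1.5, 0, 0, 0))
  expect_gte(tl$v1[1, 3], 0)
  dg <- tensor_metrics(c(1, 1, 0.2, 0, 0, 0))
  expect_true(dg$flag_degenerate)
  expect_true(is.na(angular_deviation(dg)))
})

test_that("per-direction ADC fit is exact and sensitive to bi-exponential decay", {
  # mono-exponential ADC = 0.5 over protocol-C b-values: exact recovery
  bset <- c(0, 0.2, 0.4, 0.8, 1.2, 1.5)
  dirs <- rbind(c(0, 0, 0), matrix(rep(c(0, 0, 1), 5), ncol = 3, byrow = TRUE))
  sch <- gradient_scheme(dirs, bset)
  S <- 500 * exp(-bset * 0.5)
  data <- array(rep(S, each = 4), dim = c(2, 2, 1, 6))
  st <- dwi_study(data, c(1, 1, 1), sch, list())
  f <- fit_adc_per_direction(st, "slice")
  expect_lt(max(abs(f$adc - 0.5)), 1e-12)

  # flat signal: ADC = 0
  st0 <- dwi_study(array(500, dim = c(2, 2, 1, 6)), c(1, 1, 1), sch, list())
  expect_lt(max(abs(fit_adc_per_direction(st0, "slice")$adc)), 1e-12)

  expect_error(fit_adc_per_direction(st, "read"), "read")

  # bi-exponential: fitted ADC below the b->0 tangent diffusivity
  f_ <- 0.7; Ds <- 0.5; Df <- 3 * Ds
  Sb <- 500 * (f_ * exp(-bset * Df) + (1 - f_) * exp(-bset * Ds))
  stb <- dwi_study(array(rep(Sb, each = 4), dim = c(2, 2, 1, 6)),
                   c(1, 1, 1), sch, list())
  fb <- fit_adc_per_direction(stb, "slice")
  tangent <- f_ * Df + (1 - f_) * Ds      # -d ln S/db at b=0
  expect_lt(fb$adc[1, 1, 1], tangent)
})

test_that("two-direction metrics follow the printed formulas", {
  m <- two_direction_metrics(0.7, 0.7)
  expect_equal(m$MD, 0.7)
  expect_equal(m$FA, 0)

  m2 <- two_direction_metrics(1.5, 0.3)
  expect_equal(m2$MD, 0.7, tolerance = 1e-12)
  expect_equal(m2$AD, 1.5)
  expect_equal(m2$RD, 0.3)
  expect_equal(m2$FA, sqrt(1.5 * 0.96 / 2.43), tolerance = 1e-12)

  m3 <- two_direction_metrics(0, 1)
  expect_equal(m3$MD, 2 / 3, tolerance = 1e-12)

  z <- two_direction_metrics(0, 0)
  expect_equal(z$FA, 0)
  expect_true(z$flag_zero)
  expect_true(two_direction_metrics(-0.1, 0.2)$flag_negative)
})

test_that("axisymmetric slice-aligned tensors give identical 2-dir and tensor metrics", {
  for (ad in c(0.8, 1.2, 1.5)) for (rd in c(0.2, 0.5, ad)) {
    tm <- tensor_metrics(cordti:::axisym_tensor(ad, rd, c(0, 0, 1)))
    td <- two_direction_metrics(ad, rd)
    expect_equal(td$FA, tm$FA, tolerance = 1e-12)
    expect_equal(td$MD, tm$MD, tolerance = 1e-12)
  }
})

test_that("angular deviation follows arccos of the slice component", {
  expect_equal(angular_deviation(c(0, 0, 1)), 0)
  expect_equal(angular_deviation(c(1, 0, 0)), 90)
  expect_equal(angular_deviation(c(0, 0.5, sqrt(3) / 2)), 30, tolerance = 1e-9)
  # antipodal symmetry
  expect_equal(angular_deviation(c(0, 0, -1)), 0)
  expect_error(angular_deviation(c(0, 0, 0)), "zero")
})

test_that("frame-projected metrics: trace invariance and tilt behaviour", {
  # diagonal tensor: frames coincide, all deviations 0
  fp <- frame_projected_metrics(c(0.3, 0.25, 1.5, 0, 0, 0))
  expect_equal(fp$deviation$FA, 0, tolerance = 1e-12)
  expect_equal(fp$deviation$AD, 0, tolerance = 1e-12)

  # MD invariance for random symmetric tensors
  set.seed(7)
  D <- matrix(rnorm(60), 10, 6)
  fpr <- frame_projected_metrics(D)
  tmr <- tensor_metrics(D)
  expect_lt(max(abs(fpr$MD - tmr$MD)), 1e-14)

  # axisymmetric tensor tilted 10 deg: AD' < AD, RD' > RD (brute rotation oracle)
  th <- 10 * pi / 180
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  Dm <- R %*% diag(c(0.3, 0.3, 1.5)) %*% t(R)   # principal axis near z
  d6 <- c(Dm[1, 1], Dm[2, 2], Dm[3, 3], Dm[1, 2], Dm[1, 3], Dm[2, 3])
  fpt <- frame_projected_metrics(d6)
  tmt <- tensor_metrics(d6)
  expect_lt(fpt$AD, tmt$AD)
  expect_gt(fpt$RD, tmt$RD)
  expect_equal(fpt$AD, Dm[3, 3], tolerance = 1e-12)
  # read-only RD variant picks the read-axis diagonal
  fpt2 <- frame_projected_metrics(d6, rd_mode = "read_only")
  expect_equal(fpt2$RD, Dm[1, 1], tolerance = 1e-12)

  expect_error(frame_projected_metrics(d6, axes = matrix(1, 3, 3)),
               "orthonormal")
})

test_that("floored non-positive signals are flagged", {
  sch <- gradient_scheme(rbind(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0),
                               c(0, 1, 0), c(1, 1, 0) / sqrt(2),
                               c(1, 0, 1) / sqrt(2), c(0, 1, 1) / sqrt(2)),
                         c(0, rep(1, 6)))
  data <- array(100, dim = c(1, 1, 1, 7))
  data[1, 1, 1, 2] <- 0
  st <- dwi_study(data, c(1, 1, 1), sch, list())
  fit <- fit_tensor(st, mask = array(TRUE, c(1, 1, 1)))
  expect_true(fit$flag_floored[1])
})
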