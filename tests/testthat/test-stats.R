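test_that("snr and cnr follow their defining formulas", {
  lm <- make_label_map(c(24, 24, 1))
  rois <- roi_set(lm)
  vol <- array(0, dim = dim(lm))
  vol[lm > 0] <- 200
  set.seed(1)
  vol[lm == 0] <- rnorm(sum(lm == 0), 0, 10)
  s <- snr(vol, rois, "wholeWM")
  expect_equal(s, 200 / sd(vol[lm == 0]), tolerance = 1e-12)
  expect_equal(s, 20, tolerance = 0.1)
  # noiseless image: degenerate
  expect_error(snr(array(rep(c(1, 0), length.out = length(lm)) * 0 + 5,
                         dim = dim(lm)), rois, "wholeWM"), "zero")

  # Rayleigh background: SNR ~ mean / (0.6551 sigma)
  sig <- 12
  set.seed(2)
  n_bg <- sum(lm == 0)
  vol2 <- array(0, dim = dim(lm))
  vol2[lm > 0] <- 300
  vol2[lm == 0] <- sqrt(rnorm(n_bg, 0, sig)^2 + rnorm(n_bg, 0, sig)^2)
  expect_equal(snr(vol2, rois, "wholeWM"), 300 / (sqrt(2 - pi / 2) * sig),
               tolerance = 0.05)

  # CNR hand value and antisymmetry
  m <- array(0, dim = dim(lm))
  set.seed(3)
  m[lm %in% 1:4] <- rnorm(sum(lm %in% 1:4), 0.65, 0.08)
  m[lm %in% 5:6] <- rnorm(sum(lm %in% 5:6), 0.25, 0.06)
  wm <- m[lm %in% 1:4]; gm <- m[lm %in% 5:6]
  hand <- (mean(wm) - mean(gm)) / sqrt((sd(wm)^2 + sd(gm)^2) / 2)
  expect_equal(cnr(m, rois), hand, tolerance = 1e-12)
  expect_equal(hand, 0.4 / sqrt(0.005), tolerance = 0.2)
  expect_equal(cnr(m, rois, "wholeGM", "wholeWM"), -hand, tolerance = 1e-12)
})

test_that("coefficients of variation match hand arithmetic and are scale-free", {
  expect_equal(cv_inter(c(8, 10, 12)), 0.2)
  expect_equal(cv_inter(c(5, 5, 5)), 0)
  expect_equal(cv_inter(c(8, 10, 12) * 10), cv_inter(c(8, 10, 12)))
  expect_error(cv_inter(7), ">= 2")
  expect_error(cv_inter(c(-1, 1)), "zero")

  expect_equal(cv_intra(list(a = c(2, 4)))$cv, sqrt(2) / 3, tolerance = 1e-12)
  expect_equal(cv_intra(list(c(3, 3, 3), c(5, 5)))$cv, 0)
  v <- list(s1 = rnorm(50, 10), s2 = rnorm(30, 20))
  expect_equal(cv_intra(v)$cv, cv_intra(lapply(v, function(x) 1000 * x))$cv,
               tolerance = 1e-12)
  expect_equal(cv_intra(v)$cv, cv_intra(lapply(v, rev))$cv)
  expect_error(cv_intra(list(s9 = c(1, -1))), "s9")
})

test_that("effect size is the control-referenced standardized difference", {
  ctrl <- c(0.65, 0.7, 0.75)   # mean 0.7, sd 0.05
  case <- c(0.45, 0.5, 0.55)   # mean 0.5
  expect_equal(effect_size(case, ctrl), -4, tolerance = 1e-12)
  expect_equal(effect_size(ctrl, ctrl), 0)
  expect_equal(effect_size(case + 3, ctrl + 3), effect_size(case, ctrl),
               tolerance = 1e-12)
  expect_error(effect_size(case, c(1, 1, 1)), "zero")
})

test_that("Mann-Whitney exact branch equals the base-R exact oracle (n, m <= 6)", {
  set.seed(123)
  for (n in 2:6) for (m in 2:6) {
    for (rep in 1:3) {
      x <- rnorm(n); y <- rnorm(m)
      mine <- mann_whitney(x, y)
      expect_equal(mine$method, "exact")
      oracle <- suppressWarnings(wilcox.test(x, y, exact = TRUE))
      expect_equal(mine$p, oracle$p.value, tolerance = 1e-12,
                   label = sprintf("p at n=%d m=%d", n, m))
      expect_equal(mine$U, unname(oracle$statistic))
    }
  }
  # hand-enumerated case: 2 of 20 arrangements as extreme
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1, tolerance = 1e-12)
  # identical samples: maximal p
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney approximation tracks the exact branch at n=m=8", {
  # sup over the whole U lattice of the continuity-corrected normal
  # approximation error; 0.012 is the enumerated supremum at n = m = 8
  sel <- utils::combn(16, 8)
  U_all <- colSums(sel) - 36
  for (u in 0:32) {
    x <- sel[, which(U_all == u)[1]]   # tie-free arrangement with U(x) = u
    y <- setdiff(1:16, x)
    pe <- mann_whitney(x, y, exact = TRUE)$p
    pa <- mann_whitney(x, y, exact = FALSE)$p
    expect_lt(abs(pe - pa), 0.012)
  }
})

test_that("Spearman correlation matches hand values and the base-R oracle", {
  expect_equal(spearman_cor(1:5, c(2, 3, 5, 7, 11))$rho, 1)
  expect_equal(spearman_cor(1:5, 5:1)$rho, -1)
  r <- spearman_cor(1:4, c(2, 1, 4, 3))
  expect_equal(r$rho, 0.6, tolerance = 1e-12)   # 1 - 6*4/(4*15)
  expect_error(spearman_cor(c(1, 1, 1), 1:3), "constant")
  expect_error(spearman_cor(1:2, 1:2), ">= 3")
  set.seed(5)
  x <- rnorm(7); y <- rnorm(7)
  expect_equal(spearman_cor(x, y)$rho,
               unname(cor(x, y, method = "spearman")), tolerance = 1e-12)
  # exact p equals base R's exact Spearman p
  or <- suppressWarnings(cor.test(x, y, method = "spearman", exact = TRUE))
  expect_equal(spearman_cor(x, y)$p, or$p.value, tolerance = 1e-9)
  # t approximation close to exact at n = 8
  x8 <- rnorm(8); y8 <- rnorm(8)
  expect_lt(abs(spearman_cor(x8, y8, exact = TRUE)$p -
                  spearman_cor(x8, y8, exact = FALSE)$p), 0.05)
})
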