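printed_TI <- c(30, 50, 100, 150, 200, 300, 500, 1000, 1500, 2500, 5000, 8000)

test_that("noise-free multi-TI fit recovers M0 and T1 within 0.1%", {
  M0 <- array(1000, c(3, 3)); T1 <- array(1500, c(3, 3))
  ser <- generate_asl_series(M0, T1, array(0, c(3, 3)), printed_TI,
                             noise_sd = 0, seed = 1)
  fit <- fit_inversion_recovery(ser)
  expect_true(all(fit$converged))
  expect_lt(max(abs(fit$M0 - 1000) / 1000), 0.001)
  expect_lt(max(abs(fit$T1_ms - 1500) / 1500), 0.001)
})

test_that("fitted M0 equals the long-TI plateau", {
  sig <- ir_signal(750, 900, printed_TI)
  fit <- fit_inversion_recovery(matrix(sig, nrow = 1), printed_TI)
  expect_equal(unname(fit$M0[1]), 750, tolerance = 1e-4)
  expect_equal(ir_signal(fit$M0[1], fit$T1_ms[1], 1e9), fit$M0[1],
               tolerance = 1e-6)
})

test_that("noisy T1 recovery: median relative error within 2% at 1% noise", {
  set.seed(77)
  n <- 500
  M0 <- array(1000, c(n, 1)); T1 <- array(1500, c(n, 1))
  ser <- generate_asl_series(M0, T1, array(0, c(n, 1)), printed_TI,
                             noise_sd = 10, seed = 99)
  fit <- fit_inversion_recovery(ser)
  rel <- abs(fit$T1_ms - 1500) / 1500
  expect_lte(median(rel, na.rm = TRUE), 0.02)
})

test_that("fit input validation", {
  expect_error(fit_inversion_recovery(matrix(1:4, 2, 2), c(100, 200)),
               "3 TI")
  expect_error(fit_inversion_recovery(matrix(c(1, NA, 3, 4, 5, 6), 2, 3),
                                      c(100, 200, 300)), "finite")
})

test_that("perfusion-weighted subtraction identities", {
  ctl <- array(rep(100, 8 * 10), c(2, 4, 10))
  expect_true(all(perfusion_weighted_signal(ctl, ctl) == 0))
  lab <- ctl + 5
  expect_true(all(perfusion_weighted_signal(ctl, lab) == 5))
  expect_error(perfusion_weighted_signal(ctl, lab[, , 1:5]), "identical")
})

test_that("averaging 10 repeats cuts dM variance about tenfold", {
  set.seed(5)
  nvox <- 2000
  mk <- function(nrep) {
    ctl <- array(rnorm(nvox * nrep, 100, 5), c(nvox, nrep))
    lab <- array(rnorm(nvox * nrep, 103, 5), c(nvox, nrep))
    var(perfusion_weighted_signal(ctl, lab))
  }
  v1 <- mk(1); v10 <- mk(10)
  expect_gt(v1 / v10, 6); expect_lt(v1 / v10, 15)
})

test_that("kinetic model reproduces the hand-evaluated oracle value", {
  # lambda 0.9 ml/g, M0 1, TI 2000 ms, T1 1500 ms, dM 0.01:
  # 0.9*0.01 / (2*1*2000*exp(-4/3)) = 8.5357e-6 /ms * ml/g -> 51.2
  rm <- rbf_map(array(0.01, c(1, 1)), array(1, c(1, 1)),
                array(1500, c(1, 1)), TI_label_ms = 2000,
                lambda_partition = 0.9)
  expect_equal(unname(rm$rbf[1, 1]), 51.2, tolerance = 0.01)
  expect_equal(unname(rm$rbf[1, 1]),
               0.9 * 0.01 / (2 * 1 * 2000 * exp(-2000 / 1500)) * 6e6,
               tolerance = 1e-12)
})

test_that("RBF is zero at zero dM and linear in dM", {
  M0 <- array(1000, c(4, 4)); T1 <- array(1400, c(4, 4))
  z <- rbf_map(array(0, c(4, 4)), M0, T1)
  expect_true(all(z$rbf == 0))
  a <- rbf_map(array(0.5, c(4, 4)), M0, T1)$rbf
  b <- rbf_map(array(1.0, c(4, 4)), M0, T1)$rbf
  expect_equal(b, 2 * a, tolerance = 1e-12)
})

test_that("invalid voxels are masked and counted", {
  M0 <- array(1000, c(2, 2)); M0[1, 1] <- -3
  T1 <- array(1400, c(2, 2)); T1[2, 2] <- 0
  rm <- rbf_map(array(1, c(2, 2)), M0, T1)
  expect_equal(rm$n_masked, 2)
  expect_true(is.na(rm$rbf[1, 1]) && is.na(rm$rbf[2, 2]))
  expect_true(all(is.finite(rm$rbf[cbind(c(2, 1), c(1, 2))])))
})

test_that("rbf_map inverts the forward simulator exactly (noise-free)", {
  set.seed(10)
  shp <- c(6, 5)
  M0 <- array(runif(30, 800, 1200), shp)
  T1 <- array(runif(30, 1100, 1900), shp)
  rbf_true <- array(runif(30, 100, 800), shp)
  ser <- generate_asl_series(M0, T1, rbf_true, printed_TI, noise_sd = 0,
                             seed = 3)
  dm <- perfusion_weighted_signal(ser)
  rm <- rbf_map(dm, M0, T1, ser$TI_label_ms, ser$lambda_partition)
  expect_equal(rm$rbf, rbf_true, tolerance = 1e-9)
})

test_that("recovery bias across RBF 100-800 at 2% noise stays within 5%", {
  set.seed(4)
  levels <- c(100, 300, 500, 800)
  for (rbf0 in levels) {
    n <- 400
    M0 <- array(1000, c(n, 1)); T1 <- array(1500, c(n, 1))
    ser <- generate_asl_series(M0, T1, array(rbf0, c(n, 1)), printed_TI,
                               noise_sd = 20, seed = rbf0 + 1)
    fit <- fit_inversion_recovery(ser)
    dm <- perfusion_weighted_signal(ser)
    rm <- rbf_map(dm, fit$M0, fit$T1_ms, ser$TI_label_ms)
    est <- mean(rm$rbf, na.rm = TRUE)
    expect_lt(abs(est - rbf0) / rbf0, 0.05)
  }
})

test_that("ROI summary: uniform maps, ordering, and failure modes", {
  vals <- array(NA_real_, c(10, 10))
  cortex <- array(FALSE, c(10, 10)); cortex[1:5, ] <- TRUE
  medulla <- !cortex
  vals[cortex] <- 600; vals[medulla] <- 450
  rs <- roi_summary(vals, list(cortex = cortex, medulla = medulla))
  expect_equal(rs$mean, c(600, 450))
  expect_equal(rs$sd, c(0, 0))
  expect_error(roi_summary(vals, list(empty = array(FALSE, c(10, 10)))),
               "empty")
  expect_error(roi_summary(vals, list(array(TRUE, c(10, 10)))), "named")
})

test_that("simulated cortex-medulla contrast is preserved through the pipeline", {
  ok <- 0; runs <- 20
  for (s in seq_len(runs)) {
    shp <- c(12, 12)
    cortex <- array(FALSE, shp); cortex[, 1:6] <- TRUE
    rbf_true <- array(450, shp); rbf_true[cortex] <- 600
    M0 <- array(1000, shp); T1 <- array(1500, shp)
    ser <- generate_asl_series(M0, T1, rbf_true, printed_TI,
                               noise_sd = 20, seed = 1000 + s)
    fit <- fit_inversion_recovery(ser)
    dm <- perfusion_weighted_signal(ser)
    rm <- rbf_map(dm, fit$M0, fit$T1_ms, ser$TI_label_ms)
    rs <- roi_summary(rm, list(cortex = cortex, medulla = !cortex))
    if (rs$mean[rs$roi == "cortex"] > rs$mean[rs$roi == "medulla"])
      ok <- ok + 1
  }
  expect_gte(ok / runs, 0.95)
})

test_that("excluding zero-flow cyst voxels raises the cortical mean", {
  shp <- c(16, 16)
  cortex <- array(TRUE, shp)
  cysts <- array(FALSE, shp); cysts[5:8, 5:8] <- TRUE
  rbf_true <- array(600, shp); rbf_true[cysts] <- 0
  ser <- generate_asl_series(array(1000, shp), array(1500, shp), rbf_true,
                             printed_TI, noise_sd = 5, seed = 21)
  fit <- fit_inversion_recovery(ser)
  dm <- perfusion_weighted_signal(ser)
  rm <- rbf_map(dm, fit$M0, fit$T1_ms, ser$TI_label_ms)
  rs <- roi_summary(rm, list(cortex = cortex,
                             cortex_cyst_free = cortex & !cysts))
  expect_gt(rs$mean[rs$roi == "cortex_cyst_free"],
            rs$mean[rs$roi == "cortex"])
})
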