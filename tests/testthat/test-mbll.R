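random_hemo <- function(seed, n = 200, fs = 10, nch = 2) {
  set.seed(seed)
  t <- (seq_len(n) - 1) / fs
  new_hemo_series(t, fs,
                  matrix(rnorm(n * nch, 0, 0.5), n, nch),
                  matrix(rnorm(n * nch, 0, 0.2), n, nch),
                  paste0("ch", seq_len(nch)))
}

test_that("optical density follows its log10 definition", {
  hemo <- random_hemo(1)
  raw <- forward_mbll(hemo)

  # constant intensity at the baseline value gives zero OD
  raw0 <- raw
  raw0$intensity[] <- 0.7
  od0 <- optical_density(raw0, baseline_window = c(0, 5))
  expect_lt(max(abs(od0$od)), 1e-14)

  # I = I0 / 10 at one sample gives OD = 1 there
  raw1 <- raw0
  raw1$intensity[50, 1, 1] <- 0.07
  od1 <- optical_density(raw1, baseline_window = c(0, 2))
  expect_equal(od1$od[50, 1, 1], -log10(raw1$intensity[50, 1, 1] /
                                          mean(raw1$intensity[1:20, 1, 1])),
               tolerance = 1e-12)

  # baseline I0 is the arithmetic mean of the window samples
  set.seed(2)
  rawn <- raw
  rawn$intensity[, 1, 1] <- 1 + 0.01 * rnorm(dim(raw$intensity)[1])
  odn <- optical_density(rawn, baseline_window = c(0, 5))
  i0_hat <- mean(rawn$intensity[rawn$time < 5, 1, 1])
  expect_equal(odn$od[, 1, 1], -log10(rawn$intensity[, 1, 1] / i0_hat),
               tolerance = 1e-12)

  rawbad <- raw
  rawbad$intensity[3, 1, 1] <- -1
  expect_error(optical_density(rawbad), class = "fnirseeg_domain")
  expect_error(optical_density(raw, baseline_window = c(100, 101)),
               class = "fnirseeg_invalid_parameter")
})

test_that("forward then inverse MBLL recovers concentrations to 1e-9", {
  for (seed in 1:5) {
    hemo <- random_hemo(seed)
    raw <- forward_mbll(hemo)
    rec <- invert_mbll(optical_density(raw, i0 = raw$i0))
    scale <- max(abs(hemo$hbo2))
    expect_lt(max(abs(rec$hbo2 - hemo$hbo2)) / scale, 1e-9)
    expect_lt(max(abs(rec$hbr - hemo$hbr)) / max(abs(hemo$hbr)), 1e-9)
  }
})

test_that("zero concentrations give exactly the baseline intensity", {
  hemo <- random_hemo(3)
  hemo$hbo2[] <- 0; hemo$hbr[] <- 0; hemo$hbt[] <- 0
  raw <- forward_mbll(hemo, i0 = c(0.9, 1.1))
  expect_true(all(raw$intensity[, , 1] == 0.9))
  expect_true(all(raw$intensity[, , 2] == 1.1))
})

test_that("optical density is linear in the pathlength d * DPF", {
  hemo <- random_hemo(4)
  g1 <- optode_geometry(hemo$channels, separation_mm = 30, dpf = c(6, 6))
  g2 <- optode_geometry(hemo$channels, separation_mm = 60, dpf = c(6, 6))
  od1 <- optical_density(forward_mbll(hemo, g1), i0 = c(1, 1))
  od2 <- optical_density(forward_mbll(hemo, g2), i0 = c(1, 1))
  expect_equal(od2$od, 2 * od1$od, tolerance = 1e-10)
})

test_that("inversion is linear and matches a per-sample Cramer solve", {
  hemo <- random_hemo(5)
  geom <- optode_geometry(hemo$channels)
  od <- optical_density(forward_mbll(hemo, geom), i0 = c(1, 1))

  od2 <- od; od2$od <- 2 * od$od
  r1 <- invert_mbll(od, geom)
  r2 <- invert_mbll(od2, geom)
  expect_equal(r2$hbo2, 2 * r1$hbo2, tolerance = 1e-10)

  # independent oracle: Cramer's rule per time point
  co <- extinction_defaults()
  E <- rbind(c(co$hbo2[1], co$hbr[1]), c(co$hbo2[2], co$hbr[2]))
  det_e <- E[1, 1] * E[2, 2] - E[1, 2] * E[2, 1]
  d_cm <- geom$separation_mm / 10
  for (i in c(1, 57, 200)) {
    b <- c(od$od[i, 1, 1] / (d_cm * geom$dpf[1]),
           od$od[i, 1, 2] / (d_cm * geom$dpf[2]))
    hbo2_cramer <- (b[1] * E[2, 2] - b[2] * E[1, 2]) / det_e * 1e3
    hbr_cramer <- (E[1, 1] * b[2] - E[2, 1] * b[1]) / det_e * 1e3
    expect_equal(unname(r1$hbo2[i, 1]), hbo2_cramer, tolerance = 1e-12)
    expect_equal(unname(r1$hbr[i, 1]), hbr_cramer, tolerance = 1e-12)
  }

  expect_lt(max(abs(r1$hbt - (r1$hbo2 + r1$hbr))), 1e-12)
})

test_that("proportional extinction rows are rejected as ill-conditioned", {
  bad <- data.frame(wavelength = c(760, 850), hbo2 = c(1, 2), hbr = c(2, 4))
  hemo <- random_hemo(6)
  expect_error(forward_mbll(hemo, coeffs = bad),
               class = "fnirseeg_ill_conditioned")
  expect_error(forward_mbll(hemo, i0 = c(-1, 1)),
               class = "fnirseeg_invalid_parameter")
  expect_error(optode_geometry(separation_mm = 0),
               class = "fnirseeg_invalid_parameter")
  expect_error(optode_geometry(wavelengths = c(760, 760)),
               class = "fnirseeg_invalid_parameter")
})
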