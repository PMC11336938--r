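test_that("frequency grid is log-spaced with exact endpoints", {
  g <- frequency_grid(1000, 100000, 30)
  expect_length(g, 30L)
  expect_identical(g[1], 1000)
  expect_identical(g[30], 100000)
  expect_true(all(diff(g) > 0))
  # consecutive ratio is constant, 100^(1/29) over two decades
  ratios <- g[-1] / g[-30]
  expect_equal(ratios, rep(100^(1 / 29), 29), tolerance = 1e-12)

  expect_equal(as.numeric(frequency_grid(500, 500, 1)), 500)
  expect_error(frequency_grid(-1, 10, 5), "positive")
  expect_error(frequency_grid(100, 10, 5), ">=")
  expect_error(frequency_grid(10, 100, 1), ">= 2")
})

test_that("Randles contact impedance matches complex arithmetic and limits", {
  m <- electrode_skin_model(R_d = 100, C_dl = 1e-6, R_e = 1e4)
  # independent oracle: direct complex evaluation of the parallel RC
  w <- 2 * pi * 1e3
  oracle <- 100 + 1 / (1i * w * 1e-6 + 1 / 1e4)
  z <- electrode_skin_impedance(m, 1e3)
  expect_equal(z, oracle, tolerance = 1e-12)
  expect_equal(Mod(z), 189.2891, tolerance = 1e-4)

  # low-frequency limit: capacitor open, Z -> R_d + R_e
  z0 <- electrode_skin_impedance(m, 1e-6)
  expect_equal(Mod(z0), 100 + 1e4, tolerance = 1e-4)
  # high-frequency limit: capacitor short, Z -> R_d
  zinf <- electrode_skin_impedance(m, 1e12)
  expect_equal(Mod(zinf), 100, tolerance = 1e-4)

  # real part bounded in [R_d, R_d + R_e], imaginary part <= 0
  f <- 10^seq(-2, 8, length.out = 50)
  zz <- electrode_skin_impedance(m, f)
  expect_true(all(Re(zz) >= 100 - 1e-9 & Re(zz) <= 100 + 1e4 + 1e-9))
  expect_true(all(Im(zz) <= 1e-12))

  expect_error(electrode_skin_impedance(m, 0), "positive")
  expect_error(electrode_skin_model(100, -1e-6, 1e4), "positive")
})

test_that("raising the double-layer capacitance lowers contact impedance", {
  lo <- electrode_skin_model(100, 0.1e-6, 1e4)
  hi <- electrode_skin_model(100, 1.0e-6, 1e4)
  for (f in c(1e3, 1e4, 1e5)) {
    expect_lt(Mod(electrode_skin_impedance(hi, f)),
              Mod(electrode_skin_impedance(lo, f)))
  }
})

test_that("literal series reading of the contact formula is exposed", {
  m <- electrode_skin_model(100, 1e-6, 1e4)
  z <- electrode_skin_impedance(m, 1e3, literal = TRUE)
  w <- 2 * pi * 1e3
  expect_equal(z, 100 + 1 / (1i * w * 1e-6) + 1e-4, tolerance = 1e-12)
})

test_that("Cole tissue dispersion has the right limits and monotone magnitude", {
  d <- tissue_dispersion(R0 = 2000, Rinf = 500, fc = 1e4, alpha = 1)
  expect_equal(Mod(tissue_path_impedance(d, 1e-6)), 2000, tolerance = 1e-3)
  expect_equal(Mod(tissue_path_impedance(d, 1e12)), 500, tolerance = 1e-3)
  # at the characteristic frequency with alpha = 1:
  # Z - Rinf = (R0 - Rinf) / (1 + j), magnitude (R0 - Rinf) / sqrt(2)
  z <- tissue_path_impedance(d, 1e4)
  expect_equal(Mod(z - 500), 1500 / sqrt(2), tolerance = 1e-9)

  for (alpha in c(0.6, 0.8, 1)) {
    da <- tissue_dispersion(2000, 500, 3e4, alpha)
    f <- 10^seq(0, 7, length.out = 60)
    mags <- Mod(tissue_path_impedance(da, f))
    expect_true(all(diff(mags) <= 1e-9))
  }
  expect_gte(Mod(tissue_path_impedance(d, 1e3)),
             Mod(tissue_path_impedance(d, 1e5)))

  expect_error(tissue_dispersion(500, 2000, 1e4, 1), "R0 > Rinf")
  expect_error(tissue_dispersion(2000, 500, 1e4, 1.5), "alpha")
  expect_error(tissue_dispersion(2000, 500, -1, 1), "fc")
})

test_that("pair enumeration matches brute force", {
  for (n in c(2L, 4L, 6L, 8L)) {
    geo <- sensor_geometry(n)
    # independent brute-force double loop
    brute <- NULL
    for (i in 0:(n - 2L)) for (j in (i + 1L):(n - 1L)) {
      brute <- rbind(brute, c(i, j))
    }
    expect_equal(nrow(geo$pairs), n * (n - 1L) / 2L)
    expect_equal(unname(geo$pairs), unname(brute))
    expect_false(any(duplicated(geo$pairs)))
  }
  expect_equal(nrow(sensor_geometry(6L)$pairs), 15L)
})

test_that("simulated matrices have the study shape and noise-free determinism", {
  geo <- sensor_geometry(6L)
  grid <- frequency_grid(1e3, 1e5, 30)
  cfg <- default_generator_config()
  mk_subject <- function(label, noise_sigma) {
    lv <- cfg$liver[[label]]
    subject_params(
      label,
      liver = tissue_dispersion(lv$R0, lv$Rinf, lv$fc, lv$alpha),
      background = with(cfg$background,
                        tissue_dispersion(R0, Rinf, fc, alpha)),
      contacts = replicate(6, with(cfg$contact,
                                   electrode_skin_model(R_d, C_dl, R_e)),
                           simplify = FALSE),
      noise_sigma = noise_sigma)
  }
  m <- simulate_matrix(mk_subject("healthy", 0.03), geo, grid, rng_seed = 5)
  expect_identical(dim(m$magnitudes), c(15L, 30L))
  expect_true(all(is.finite(m$magnitudes)) && all(m$magnitudes > 0))

  # noise_sigma = 0: different seeds give identical matrices
  a <- simulate_matrix(mk_subject("nafld", 0), geo, grid, rng_seed = 1)
  b <- simulate_matrix(mk_subject("nafld", 0), geo, grid, rng_seed = 999)
  expect_identical(a$magnitudes, b$magnitudes)

  # noise-free magnitudes are non-increasing along the frequency axis
  expect_true(all(t(apply(a$magnitudes, 1, diff)) <= 1e-9))

  # class contrast of the default parameter sets at the low-frequency end
  h <- simulate_matrix(mk_subject("healthy", 0), geo, grid, rng_seed = 1)
  expect_gt(mean(a$magnitudes[, 1:5]), mean(h$magnitudes[, 1:5]))
})

test_that("cohort generation is reproducible and label-balanced", {
  co <- generate_cohort(20, 20, seed = 11)
  expect_length(co$matrices, 40L)
  expect_equal(sum(co$labels == "healthy"), 20L)
  expect_equal(sum(co$labels == "nafld"), 20L)

  co2 <- generate_cohort(20, 20, seed = 11)
  expect_identical(cohort_array(co), cohort_array(co2))
  co3 <- generate_cohort(20, 20, seed = 12)
  expect_false(identical(cohort_array(co), cohort_array(co3)))

  empty <- generate_cohort(0, 0, seed = 1)
  expect_length(empty$matrices, 0L)
  expect_error(generate_cohort(-1, 5), "non-negative")
})

test_that("every default nafld subject dominates every healthy subject at low frequency", {
  cfg <- default_generator_config()
  cfg$noise_sigma <- 0
  co <- generate_cohort(20, 20, cfg, seed = 3)
  arr <- cohort_array(co)
  low <- apply(arr[, , 1:5], 1, mean)
  expect_gt(min(low[co$labels == "nafld"]), max(low[co$labels == "healthy"]))
})
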