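test_that("birdcage source set has mode-1 circular-polarization structure", {
  coil <- birdcage_coil()
  expect_equal(coil$n_rungs, 16L)
  bc <- build_birdcage_sources(coil, c(101, 101, 75), spacing = 4)

  # the 16 complex rung phasors sum to zero
  expect_lt(abs(sum(bc$phasors)), 1e-12)

  # instantaneous (t = 0) currents follow the cos(theta) azimuthal pattern
  th <- 2 * pi * (0:15) / 16
  expect_equal(Re(bc$phasors), cos(th), tolerance = 1e-12)

  # rotating the rung set by one slot multiplies all phasors by a unit twist
  twist <- bc$phasors[c(2:16, 1)] / bc$phasors
  expect_equal(twist, rep(twist[1], 16), tolerance = 1e-12)
  expect_equal(abs(twist[1]), 1, tolerance = 1e-12)

  expect_error(build_birdcage_sources(coil, c(40, 40, 75), spacing = 4),
               "fit")
})

test_that("required B1 follows the flip-angle relation", {
  expect_equal(required_b1(pi / 2, 3e-3) * 1e6, 1.957, tolerance = 1e-3)
  expect_equal(signif(required_b1(pi / 2, 3e-3) * 1e6, 1), 2)
  expect_equal(required_b1(pi, 3e-3), 2 * required_b1(pi / 2, 3e-3))
  expect_equal(required_b1(pi / 2, 6e-3) * 1e6, 0.979, tolerance = 1e-3)
  expect_error(required_b1(pi / 2, 0), "positive")
})

test_that("B1+ / B1- algebra matches the rotating-frame definitions", {
  d <- c(2, 2, 2)
  f <- structure(list(Bx = array(0i, d), By = array(0i, d)), class = "em_fields")
  expect_true(all(b1_plus(f) == 0))

  # pure CP field Bx = B0, By = -i B0  ->  |B1+| = B0, |B1-| = 0
  B0 <- 3e-6
  f$Bx <- array(complex(real = B0), d)
  f$By <- array(complex(imaginary = -B0), d)
  expect_equal(abs(b1_plus(f))[1], B0)
  expect_lt(abs(b1_minus(f))[1], 1e-20)

  # pure linear field Bx = B0 -> |B1+| = B0/2
  f$By <- array(0i, d)
  expect_equal(abs(b1_plus(f))[1], B0 / 2)
})

test_that("field normalization hits the target and scales SAR quadratically", {
  d <- c(3, 3, 3)
  mk <- function(b) structure(list(
    Ex = array(2 + 0i, d), Ey = array(0i, d), Ez = array(1i, d),
    Bx = array(complex(real = b), d), By = array(complex(imaginary = -b), d),
    Bz = array(0i, d), scale = 1), class = "em_fields")
  f <- mk(1e-6)
  out <- normalize_fields(f, target_b1_t = 2e-6)
  expect_equal(out$scale, 2)
  ref <- out$reference_voxel
  expect_equal(abs(b1_plus(out))[ref[1], ref[2], ref[3]], 2e-6,
               tolerance = 1e-15)

  sig <- array(0.5, d); rho <- array(1000, d); tis <- array(TRUE, d)
  s1 <- pointwise_sar(f, sig, rho, tis)
  s2 <- pointwise_sar(out, sig, rho, tis)
  expect_equal(s2, 4 * s1, tolerance = 1e-12, ignore_attr = TRUE)

  f0 <- mk(0)
  expect_error(normalize_fields(f0), "zero")

  # already at target: scale 1
  expect_equal(normalize_fields(mk(2e-6), 2e-6)$scale, 1)
})

test_that("pointwise SAR implements sigma |E|^2 / (2 rho) on tissue", {
  d <- c(2, 2, 1)
  f <- structure(list(Ex = array(1 + 0i, d), Ey = array(0i, d),
                      Ez = array(0i, d)), class = "em_fields")
  sig <- array(2, d); rho <- array(1000, d); tis <- array(TRUE, d)
  s <- pointwise_sar(f, sig, rho, tis)
  expect_equal(s[1], 1e-3)

  f2 <- f; f2$Ex <- 2 * f$Ex
  expect_equal(pointwise_sar(f2, sig, rho, tis)[1], 4e-3)

  f0 <- f; f0$Ex <- array(0i, d)
  expect_true(all(pointwise_sar(f0, sig, rho, tis) == 0))

  rho0 <- rho; rho0[1] <- 0
  expect_error(pointwise_sar(f, sig, rho0, tis), "density")

  # air voxels excluded
  tis2 <- tis; tis2[1] <- FALSE
  expect_equal(pointwise_sar(f, sig, rho, tis2)[1], 0)
})

test_that("total deposited power matches the field-side integral", {
  set.seed(21)
  d <- c(6, 6, 6)
  f <- structure(list(
    Ex = array(complex(real = rnorm(216), imaginary = rnorm(216)), d),
    Ey = array(complex(real = rnorm(216), imaginary = rnorm(216)), d),
    Ez = array(complex(real = rnorm(216), imaginary = rnorm(216)), d)),
    class = "em_fields")
  sig <- array(runif(216, 0.1, 2), d)
  rho <- array(runif(216, 900, 1100), d)
  tis <- array(TRUE, d)
  sar <- pointwise_sar(f, sig, rho, tis)
  vv <- 1e-9                              # 1 mm^3 voxels in m^3
  p_sar <- sum(sar * rho * vv)
  e2 <- Mod(f$Ex)^2 + Mod(f$Ey)^2 + Mod(f$Ez)^2
  p_field <- sum(0.5 * sig * e2 * vv)
  expect_equal(p_sar, p_field, tolerance = 1e-12)
})

test_that("10 g averaging equals the brute-force cube search on small grids", {
  set.seed(42)
  d <- c(13, 14, 12)
  rho <- array(1000 + 200 * runif(prod(d)), d)
  tissue <- array(runif(prod(d)) > 0.15, d)
  rho[!tissue] <- 0
  sar <- array(runif(prod(d)), d); sar[!tissue] <- 0
  res <- mass_averaged_sar(sar, rho, 8, tissue, target_mass_g = 10)
  bf <- mass_avg_sar_oracle(sar, rho, 8, tissue, 10)
  sel <- !is.na(bf)
  expect_equal(res$map[sel], bf[sel], tolerance = 1e-12)
  expect_equal(res$n_inherited, sum(tissue & is.na(bf)))
  # contraction: the averaged maximum never exceeds the pointwise maximum
  expect_lte(res$max, max(sar))
})

test_that("single hot voxel dilutes to s0 * m_v / 10 g", {
  d <- c(11, 11, 11)
  rho <- array(1000, d); tissue <- array(TRUE, d)
  sar <- array(0, d)
  s0 <- 5
  sar[6, 6, 6] <- s0
  sp <- 6                                 # voxel mass 0.216 g
  res <- mass_averaged_sar(sar, rho, sp, tissue)
  m_v <- sp^3 * 1e-9 * 1000 * 1e3
  expect_equal(res$max, s0 * m_v / 10, tolerance = 0.05 * s0 * m_v / 10)
  # the hot voxel itself attains the maximum (neighbors whose cube fully
  # contains it tie at exactly the same diluted value)
  expect_equal(res$map[6, 6, 6], res$max)
})

test_that("uniform SAR passes through 10 g averaging unchanged", {
  d <- c(9, 9, 9)
  rho <- array(1050, d); tissue <- array(TRUE, d)
  sar <- array(0, d); sar[tissue] <- 2.5
  res <- mass_averaged_sar(sar, rho, 7, tissue)
  expect_equal(range(res$map[tissue]), c(2.5, 2.5))
  expect_error(mass_averaged_sar(sar, array(1, d), 1, tissue), "below")
})

test_that("region-averaged SAR is the mass-weighted mean", {
  d <- c(4, 4, 2)
  sar <- array(1, d); sar[3:4, , ] <- 3   # two equal-mass halves at s and 3s
  rho <- array(1000, d)
  reg <- array(TRUE, d)
  expect_equal(region_average_sar(sar, rho, reg), 2)
  # uniform map: the average is the value
  expect_equal(region_average_sar(array(7, d), rho, reg), 7)
  # voxel ordering irrelevant
  perm <- sample(prod(d))
  expect_equal(sum(sar[perm] * rho[perm]) / sum(rho[perm]),
               region_average_sar(sar, rho, reg))
  expect_error(region_average_sar(sar, rho, array(FALSE, d)), "no tissue")
})

test_that("FDTD returns zero fields for zero sources", {
  d <- c(12, 10, 9)
  f <- fdtd_solve(list(eps_r = array(1, d), sigma = array(0, d), spacing = 5),
                  sources = data.frame(), freq_hz = 297.2e6,
                  min_periods = 2, max_periods = 4, tol = 0.01)
  expect_true(all(Mod(f$Ex) == 0) && all(Mod(f$Bz) == 0))
})

test_that("plane-wave decay in a conductor follows the skin-depth law", {
  # quasi-1D TEM channel: Mur along x, PEC walls normal to y (E is normal
  # there), PMC walls normal to z (E is tangential there)
  nx <- 220; ny <- 5; nz <- 5; sp <- 0.9
  eps <- array(1, c(nx, ny, nz)); sig <- array(0, c(nx, ny, nz))
  i0 <- 120; sigma_c <- 10
  sig[i0:nx, , ] <- sigma_c
  src <- expand.grid(j = 1:ny, k = 1:nz)
  sources <- data.frame(component = "y", i = 20, j = src$j, k = src$k,
                        amplitude = 1, phase = 0)
  f <- fdtd_solve(list(eps_r = eps, sigma = sig, spacing = sp),
                  sources = sources, freq_hz = 297.2e6,
                  boundary = c("mur", "pec", "pmc"),
                  min_periods = 6, max_periods = 40, tol = 0.005)
  omega <- 2 * pi * 297.2e6
  delta_mm <- sqrt(2 / (omega * 4e-7 * pi * sigma_c)) * 1000
  expect_gt(delta_mm / sp, 10)           # >= 10 cells per skin depth
  amp <- abs(f$Ey[, 3, 3])
  d_mm <- ((1:nx) - i0) * sp
  sel <- d_mm > 0.5 * delta_mm & d_mm < 3 * delta_mm
  fit <- stats::lm(log(amp[sel]) ~ d_mm[sel])
  delta_fit <- -1 / coef(fit)[[2]]
  expect_lt(abs(delta_fit - delta_mm) / delta_mm, 0.05)
})

test_that("scaling source currents scales fields linearly and SAR quadratically", {
  d <- c(16, 16, 14); sp <- 6
  eps <- array(1, d); sig <- array(0, d)
  eps[6:11, 6:11, 5:10] <- 50; sig[6:11, 6:11, 5:10] <- 0.8
  tis <- array(FALSE, d); tis[6:11, 6:11, 5:10] <- TRUE
  rho <- array(0, d); rho[tis] <- 1000
  src <- data.frame(component = "z", i = 3, j = 8, k = 4:11,
                    amplitude = 1, phase = 0)
  run <- function(alpha) {
    s <- src; s$amplitude <- alpha
    fdtd_solve(list(eps_r = eps, sigma = sig, spacing = sp), sources = s,
               freq_hz = 297.2e6, min_periods = 3, max_periods = 12,
               tol = 0.01)
  }
  f1 <- run(1); f2 <- run(2)
  expect_equal(f2$Ez, 2 * f1$Ez, tolerance = 1e-9)
  expect_equal(f2$Bx, 2 * f1$Bx, tolerance = 1e-9)
  s1 <- pointwise_sar(f1, sig, rho, tis)
  s2 <- pointwise_sar(f2, sig, rho, tis)
  expect_equal(s2, 4 * s1, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("empty coil in CP mode is circularly polarized on axis", {
  coil <- birdcage_coil()
  sp <- 8
  nxy <- 2 * (ceiling(coil$shield_diameter_mm / 2 / sp) + 6) + 1
  nzz <- 2 * (ceiling(coil$shield_length_mm / 2 / sp) + 6) + 1
  d <- c(nxy, nxy, nzz)
  bc <- build_birdcage_sources(coil, d, sp)
  f <- fdtd_solve(list(eps_r = array(1, d), sigma = array(0, d), spacing = sp),
                  sources = bc$sources, pec = bc$pec, freq_hz = coil$freq_hz,
                  ramp_periods = 4, min_periods = 6, max_periods = 20,
                  tol = 0.01, measure_periods = 4, on_nonconverged = "warn")
  ctr <- round(bc$center_voxel)
  bp <- abs(b1_plus(f))[ctr[1], ctr[2], ctr[3]]
  bm <- abs(b1_minus(f))[ctr[1], ctr[2], ctr[3]]
  expect_gt(bp, 0)
  expect_lt(bm / bp, 0.05)
})

test_that("CFL violations and bad sources are rejected", {
  d <- c(6, 6, 6)
  dom <- list(eps_r = array(1, d), sigma = array(0, d), spacing = 4)
  src <- data.frame(component = "z", i = 3, j = 3, k = 3,
                    amplitude = 1, phase = 0)
  expect_error(fdtd_solve(dom, sources = src, cfl = 1.5), "cfl")
  bad <- src; bad$i <- 99
  expect_error(fdtd_solve(dom, sources = bad), "outside")
  aniso <- dom; aniso$spacing <- c(4, 4, 5)
  expect_error(fdtd_solve(aniso, sources = src), "isotropic")
})
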