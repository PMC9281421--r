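test_that("a stick line broadens into a Gaussian of the requested HWHM", {
  m <- electronic_model(5.0, f_osc = 1)
  r <- propagate(m, initial_wavepacket(m, 1), t_final = 150, dt = 0.25)
  grid <- seq(4.88, 5.12, by = 2e-4)
  sp <- absorption_spectrum(r, hwhm = 0.04, energy_grid = grid)
  gauss <- exp(-log(2) * ((grid - 5.0) / 0.04)^2)
  expect_lt(max(abs(sp$data$total - gauss)), 1e-6)
})

test_that("a displaced oscillator shows a Poisson vibronic progression", {
  w <- 0.25; lam <- 0.25
  s_hr <- lam^2 / (2 * w^2)
  cpl <- array(lam, c(1, 1, 1))
  m <- lvc_model(normal_modes(w), lvc_states("b", oscillator_strength = 1),
                 matrix(5.5), cpl)
  r <- propagate(m, initial_wavepacket(m, 1, n_max = 25), t_final = 400, dt = 0.05)
  e00 <- diabatic_minimum(m, 1)$E_min
  lines <- e00 + w * (0:4)
  sp <- absorption_spectrum(r, hwhm = 0.01,
                            energy_grid = sort(unique(c(seq(5, 7, 0.001), lines))),
                            normalize = "none")
  peak <- sp$data$total[match(lines, sp$data$energy)]
  pois <- exp(-s_hr) * s_hr^(0:4) / factorial(0:4)
  expect_equal(peak / peak[1], pois / pois[1], tolerance = 0.01)
})

test_that("the total spectrum is the pointwise sum of its contributions", {
  m <- lvc_model(normal_modes(0.2),
                 lvc_states(c("b1", "b2"), oscillator_strength = c(0.5, 0.25)),
                 diag(c(5.0, 5.6)),
                 array(c(0.1, 0, 0, -0.08), c(2, 2, 1)))
  r1 <- propagate(m, initial_wavepacket(m, 1, n_max = 15), t_final = 120, dt = 0.25)
  r2 <- propagate(m, initial_wavepacket(m, 2, n_max = 15), t_final = 120, dt = 0.25)
  grid <- seq(4.5, 6.5, 0.002)
  both <- absorption_spectrum(list(r1, r2), hwhm = 0.04, energy_grid = grid)
  expect_equal(both$data$total, both$data$b1 + both$data$b2, tolerance = 1e-12)

  # and equals the sum of the single-state spectra before normalization
  s1 <- absorption_spectrum(r1, hwhm = 0.04, energy_grid = grid, normalize = "none")
  s2 <- absorption_spectrum(r2, hwhm = 0.04, energy_grid = grid, normalize = "none")
  raw <- absorption_spectrum(list(r1, r2), hwhm = 0.04, energy_grid = grid,
                             normalize = "none")
  expect_equal(raw$data$total, s1$data$total + s2$data$total, tolerance = 1e-12)
})

test_that("shifting all diabatic constants shifts the spectrum rigidly", {
  m <- two_mode_model()
  delta <- 0.3
  m_shift <- lvc_model(m$modes, m$states, m$constant_matrix + delta * diag(2),
                       m$couplings)
  r <- propagate(m, initial_wavepacket(m, 1, n_max = 8), t_final = 120, dt = 0.25)
  rs <- propagate(m_shift, initial_wavepacket(m_shift, 1, n_max = 8),
                  t_final = 120, dt = 0.25)
  grid <- seq(4.5, 6.5, 0.01)
  sp <- absorption_spectrum(r, energy_grid = grid, normalize = "none")
  sps <- absorption_spectrum(rs, energy_grid = grid + delta, normalize = "none")
  expect_equal(sps$data$total, sp$data$total, tolerance = 1e-8)
})

test_that("broadening lowers peak heights and the zeroth moment tracks f", {
  m <- electronic_model(c(5.0, 5.8), f_osc = c(0.6, 0.2))
  r1 <- propagate(m, initial_wavepacket(m, 1), t_final = 400, dt = 0.25)
  r2 <- propagate(m, initial_wavepacket(m, 2), t_final = 400, dt = 0.25)
  grid <- seq(4, 7, 0.001)
  peaks <- purrr::map_dbl(c(0.02, 0.04, 0.08, 0.16), function(hw) {
    max(absorption_spectrum(list(r1, r2), hwhm = hw, energy_grid = grid,
                            normalize = "none")$data$total)
  })
  expect_true(all(diff(peaks) < 0))

  sp <- absorption_spectrum(list(r1, r2), hwhm = 0.04, energy_grid = grid,
                            normalize = "none")
  mom <- c(sum(sp$data$E1), sum(sp$data$E2))
  expect_equal(mom[1] / mom[2], 0.6 / 0.2, tolerance = 1e-6)
})

test_that("a too-short time grid is rejected with the required length", {
  m <- electronic_model(5.0, f_osc = 1)
  r <- propagate(m, initial_wavepacket(m, 1), t_final = 10, dt = 0.25)
  expect_error(absorption_spectrum(r, hwhm = 0.04), "t_final >=")
})

test_that("spectrum objects tidy and glance coherently", {
  m <- electronic_model(5.0, f_osc = 1)
  r <- propagate(m, initial_wavepacket(m, 1), t_final = 150, dt = 0.25)
  sp <- absorption_spectrum(r, hwhm = 0.04, shift = -0.7,
                            energy_grid = seq(4.5, 5.5, 0.001))
  td <- tidy(sp)
  expect_equal(sort(unique(td$component)), c("E1", "total"))
  expect_true(all(td$intensity >= 0))
  gl <- glance(sp)
  expect_equal(gl$peak_energy, 5.0 - 0.7, tolerance = 1e-6)
  expect_equal(gl$peak_intensity, 1)
})
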