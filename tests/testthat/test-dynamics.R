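test_that("the initial wavepacket is the oscillator vacuum on one state", {
  m <- two_mode_model()
  psi <- initial_wavepacket(m, 1, n_max = 6)
  res <- propagate(m, psi, t_final = 1, dt = 1)
  expect_equal(res$populations[1, ], c(S1 = 1, S2 = 0))

  # vacuum moments: <q> = 0, <q^2> = 1/2 per mode
  ops <- lvcdyn:::lvc_operators(m, psi$basis)
  v <- psi$coefficients[, 1]
  for (a in 1:2) {
    qv <- as.vector(ops$qs[[a]] %*% Re(v))
    expect_equal(sum(Re(v) * qv), 0)
    expect_equal(sum(qv^2), 0.5)
  }

  # <V_ii> at t = 0 is the constant plus a quarter of each quantum
  expect_equal(res$pes[1, 1],
               m$constant_matrix[1, 1] + 0.25 * sum(m$modes$frequencies),
               ignore_attr = TRUE)
  expect_error(initial_wavepacket(m, 5), "state index")
})

test_that("uncoupled electronic blocks keep their populations", {
  cpl <- array(0, c(2, 2, 2))
  cpl[1, 1, ] <- c(0.1, 0)
  cpl[2, 2, ] <- c(0, -0.1)
  m <- lvc_model(normal_modes(c(0.2, 0.15)), lvc_states(c("a", "b")),
                 diag(c(5, 5.3)), cpl)
  res <- propagate(m, initial_wavepacket(m, 1, n_max = 8), t_final = 60, dt = 1)
  expect_lt(max(abs(res$populations[, 1] - 1)), 1e-12)
  expect_true(all(is.na(res$pes[, 2])))

  # with no gradient either, the vacuum is stationary and every unmasked PES
  # expectation is constant in time
  m0 <- lvc_model(normal_modes(c(0.2, 0.15)), lvc_states(c("a", "b")),
                  diag(c(5, 5.3)), array(0, c(2, 2, 2)))
  res0 <- propagate(m0, initial_wavepacket(m0, 1, n_max = 4), t_final = 60, dt = 5)
  expect_lt(max(abs(res0$pes[, 1] - res0$pes[1, 1])), 1e-10)
})

test_that("a purely electronic two-level system shows exact Rabi flopping", {
  m <- electronic_model(c(5, 5), coupling = 0.1)
  res <- propagate(m, initial_wavepacket(m, 1), t_final = 100, dt = 0.5)
  expect_equal(res$populations[, 2], sin(0.1 * res$times / hbar_ev_fs)^2,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("all three propagators agree with the dense oracle", {
  m <- two_mode_model()
  times <- seq(0, 40, by = 1)
  ora <- oracle_populations(m, n_max = 8, initial_state = 1, times = times)
  psi0 <- initial_wavepacket(m, 1, n_max = 8)
  for (method in c("expm", "lanczos", "chebyshev")) {
    res <- propagate(m, psi0, t_final = 40, dt = 1, method = method)
    expect_lt(max(abs(res$populations - ora)), 1e-8)
    expect_lt(max(abs(res$norm - 1)), 1e-8)
    expect_lt(max(abs(res$energy - res$energy[1])), 1e-8)
  }
})

test_that("propagation is time reversible and preserves autocorrelation symmetry", {
  m <- two_mode_model()
  psi0 <- initial_wavepacket(m, 1, n_max = 8)
  fwd <- propagate(m, psi0, t_final = 30, dt = 30)
  psi_t <- fwd$psi_final
  back <- propagate(m, wavepacket(Conj(psi_t$coefficients), psi_t$basis),
                    t_final = 30, dt = 30)
  expect_lt(max(Mod(Conj(back$psi_final$coefficients) - psi0$coefficients)), 1e-7)

  # real initial state, real Hamiltonian: C(-t) = C(t)*; the backward value
  # is reconstructed through the conjugated propagation above
  c_minus <- sum(Conj(psi0$coefficients) * Conj(psi_t$coefficients))
  expect_equal(c_minus, Conj(fwd$autocorrelation[length(fwd$times)]),
               tolerance = 1e-10)
})

test_that("doubling the basis leaves converged populations unchanged", {
  m <- two_mode_model()
  r1 <- propagate(m, initial_wavepacket(m, 1, n_max = 14), t_final = 50, dt = 2.5)
  r2 <- propagate(m, initial_wavepacket(m, 1, n_max = 28), t_final = 50, dt = 2.5)
  expect_lt(max(abs(r1$populations - r2$populations)), 1e-6)
})

test_that("basis caps and invalid inputs raise informative errors", {
  m <- two_mode_model()
  psi <- initial_wavepacket(m, 1, n_max = 10)
  expect_error(propagate(m, psi, t_final = -1), "t_final")
  expect_error(propagate(m, psi, t_final = 1, basis_cap = 10), "exceeds the cap")
  expect_error(propagate(m, psi, t_final = 1, method = "expm", dense_cap = 10),
               "dense diagonalization")
  m3 <- electronic_model(c(1, 2, 3))
  expect_error(propagate(m3, psi, t_final = 1), "electronic states")
})

test_that("mode reduction keeps the most strongly coupled modes", {
  m <- make_truth_model(n_states = 4, n_modes = 6, seed = 33)
  red <- reduce_modes(m, 2)
  expect_equal(n_modes(red), 2)
  score <- purrr::map_dbl(1:6, ~ sum(m$couplings[, , .x]^2))
  keep <- sort(order(score, decreasing = TRUE)[1:2])
  expect_equal(red$modes$frequencies, m$modes$frequencies[keep])
  expect_equal(red$couplings, m$couplings[, , keep, drop = FALSE])
  expect_identical(reduce_modes(m, 6), m)
})

test_that("population and PES tables are tidy with per-row unit norm", {
  m <- two_mode_model()
  res <- propagate(m, initial_wavepacket(m, 1, n_max = 8), t_final = 20, dt = 5)
  pop <- diabatic_populations(res)
  expect_equal(names(pop), c("time", "state", "population"))
  sums <- dplyr::summarise(dplyr::group_by(pop, time),
                           total = sum(population))$total
  expect_equal(sums, rep(1, 5), tolerance = 1e-8)
  pes <- pes_expectations(res)
  expect_equal(nrow(pes), 10)
  gl <- glance(res)
  expect_equal(gl$initial_state, "S1")
  expect_lt(gl$norm_drift, 1e-8)
})
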