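test_that("potential matrix reproduces the LVC functional form", {
  m <- two_mode_model()
  expect_equal(potential_matrix(m, c(0, 0)), m$constant_matrix)

  m1 <- lvc_model(normal_modes(0.2), lvc_states("s"), matrix(5.0),
                  array(0.1, c(1, 1, 1)))
  expect_equal(potential_matrix(m1, 1)[1, 1], 5.0 + 0.1 + 0.1)

  # no harmonic term on the off-diagonal
  cpl <- array(0, c(2, 2, 1))
  cpl[1, 2, ] <- cpl[2, 1, ] <- 0.02
  m2 <- lvc_model(normal_modes(0.3), lvc_states(c("a", "b")),
                  matrix(c(5, 0.05, 0.05, 6), 2), cpl)
  expect_equal(potential_matrix(m2, 2)[1, 2], 0.05 + 0.02 * 2)

  expect_error(potential_matrix(m, c(0, 0, 0)), "modes")
})

test_that("the potential is quadratic on the diagonal and linear off it", {
  m <- random_model(4, 3, seed = 11)
  q0 <- withr::with_seed(12, rnorm(3))
  h <- 0.05
  for (a in 1:3) {
    e <- numeric(3); e[a] <- h
    second <- (potential_matrix(m, q0 + e) + potential_matrix(m, q0 - e) -
                 2 * potential_matrix(m, q0)) / h^2
    expect_equal(diag(second), rep(m$modes$frequencies[a], 4), tolerance = 1e-9)
    off <- second; diag(off) <- 0
    expect_lt(max(abs(off)), 1e-9)
  }
})

test_that("adiabatic energies are sorted with a deterministic sign convention", {
  m_diag <- lvc_model(normal_modes(0.2),
                      lvc_states(c("a", "b", "c")),
                      diag(c(6.2, 5.1, 5.9)), array(0, c(3, 3, 1)))
  expect_equal(adiabatic_energies(m_diag, 0), c(5.1, 5.9, 6.2))

  m2 <- electronic_model(c(5, 5), coupling = 0.1)
  expect_equal(adiabatic_energies(m2, numeric(0)), c(4.9, 5.1))

  m <- random_model(5, 4, seed = 21)
  q <- withr::with_seed(22, rnorm(4))
  r1 <- adiabatic_energies(m, q, return_vectors = TRUE)
  r2 <- adiabatic_energies(m, q, return_vectors = TRUE)
  expect_identical(r1$vectors, r2$vectors)
  for (k in 1:5) {
    expect_gt(r1$vectors[which.max(abs(r1$vectors[, k])), k], 0)
  }
})

test_that("symmetry blocks stay decoupled along totally symmetric displacements", {
  m <- make_truth_model(seed = 5)
  a1 <- which(m$modes$symmetry == "a'")
  q <- numeric(n_modes(m))
  q[a1] <- withr::with_seed(6, rnorm(length(a1), sd = 0.5))
  v <- potential_matrix(m, q)
  odd <- m$states$symmetry == "A''"
  expect_equal(max(abs(v[odd, !odd])), 0)
})

test_that("diabatic minima match the closed form and a numeric minimizer", {
  m0 <- lvc_model(normal_modes(0.2), lvc_states("s"), matrix(5.0),
                  array(0, c(1, 1, 1)))
  expect_equal(diabatic_minimum(m0, 1), list(q_min = 0, E_min = 5.0))

  m1 <- lvc_model(normal_modes(0.2), lvc_states("s"), matrix(5.0),
                  array(0.1, c(1, 1, 1)))
  expect_equal(diabatic_minimum(m1, 1), list(q_min = -0.5, E_min = 4.975))
  expect_equal(reorganization_energy(m1, 1), 0.025)

  m <- random_model(3, 5, seed = 31)
  for (i in 1:3) {
    cf <- diabatic_minimum(m, i)
    vii <- function(q) potential_matrix(m, q)[i, i]
    opt <- optim(rep(0, 5), vii, method = "BFGS",
                 control = list(reltol = 1e-15, maxit = 500))
    expect_lt(abs(cf$E_min - opt$value), 1e-10)
    # internal consistency: reorganization energy = vertical minus minimum
    expect_equal(reorganization_energy(m, i),
                 potential_matrix(m, rep(0, 5))[i, i] - cf$E_min,
                 tolerance = 1e-12)
    # variational bound: some adiabatic level lies at or below the diabatic
    # surface at its own minimum
    expect_lte(min(adiabatic_energies(m, cf$q_min)), vii(cf$q_min) + 1e-12)
  }
})

test_that("state labels resolve and bad indices fail loudly", {
  m <- two_mode_model()
  expect_equal(diabatic_minimum(m, "S2"), diabatic_minimum(m, 2))
  expect_error(diabatic_minimum(m, "nope"), "unknown state label")
  expect_error(reorganization_energy(m, 7), "state index")
})

test_that("model constructor enforces its invariants", {
  expect_error(normal_modes(c(0.1, -0.2)), "positive")
  bad <- matrix(c(5, 0.1, 0.2, 6), 2)
  expect_error(lvc_model(normal_modes(0.1), lvc_states(c("a", "b")), bad),
               "symmetric")
  cpl <- array(0, c(2, 2, 1)); cpl[1, 2, 1] <- 0.1
  expect_error(lvc_model(normal_modes(0.1), lvc_states(c("a", "b")),
                         diag(c(5, 6)), cpl), "symmetric in i <-> j")
  # selection-rule audit
  cpl2 <- array(0, c(2, 2, 1))
  cpl2[1, 2, 1] <- cpl2[2, 1, 1] <- 0.1
  expect_warning(
    lvc_model(normal_modes(0.1, symmetry = "a'"),
              lvc_states(c("a", "b"), symmetry = c("A'", "A''")),
              diag(c(5, 6)), cpl2),
    "selection rule")
})

test_that("tidy and glance summarize a model", {
  m <- make_truth_model(seed = 2)
  td <- tidy(m)
  expect_equal(nrow(td), 12)
  expect_true(all(c("label", "energy_vertical", "energy_minimum",
                    "reorganization") %in% names(td)))
  expect_equal(td$energy_vertical - td$energy_minimum, td$reorganization,
               tolerance = 1e-12)
  gl <- glance(m)
  expect_equal(gl$n_states, 12L)
  expect_equal(gl$max_reorganization,
               max(td$reorganization))
})
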