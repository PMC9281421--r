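test_that("displacement protocol enumerates 2F + 1 tagged geometries", {
  modes <- normal_modes(c(0.1, 0.3))
  p <- displacement_grid(modes, 0.1)
  expect_equal(p$plan$geometry_tag, c("FC", "m1+", "m1-", "m2+", "m2-"))
  expect_equal(protocol_q(p, "FC"), c(0, 0))
  expect_equal(protocol_q(p, "m2-"), c(0, -0.1))

  pv <- displacement_grid(modes, c(0.1, 0.2))
  expect_equal(protocol_q(pv, "m2+"), c(0, 0.2))
  expect_error(displacement_grid(modes, -0.1), "positive")
  expect_error(protocol_q(p, "m9+"), "unknown geometry tag")
})

test_that("central differences recover ground-truth couplings exactly", {
  truth <- make_truth_model(n_states = 5, n_modes = 4, seed = 41)
  recs <- generate_records(truth_spec(truth), displacement_grid(truth$modes, 0.1))
  fit <- suppressWarnings(
    build_lvc_model(recs, truth$modes, 5, strategy = "FrD", states = truth$states)
  )
  expect_lt(max(abs(fit$constant_matrix - truth$constant_matrix)), 1e-10)
  expect_lt(max(abs(fit$couplings - truth$couplings)), 1e-8)
  # recovered couplings symmetric by construction
  expect_equal(fit$couplings, aperm(fit$couplings, c(2, 1, 3)))
  # symmetry-forbidden pairs stay numerically zero
  viol <- lvcdyn:::symmetry_violations(
    lvc_model(truth$modes, truth$states, fit$constant_matrix, fit$couplings,
              check_symmetry = "none"), tol = 1e-10)
  expect_equal(nrow(viol), 0L)
})

test_that("cubic anharmonicity enters the couplings at order delta squared", {
  # 2-state potential with a cubic contamination c*q^3 on state 1
  cc <- 0.02
  vfun <- function(q) {
    matrix(c(5.0 + 0.5 * 0.2 * q^2 + 0.1 * q + cc * q^3, 0.01,
             0.01, 5.5 + 0.5 * 0.2 * q^2 - 0.05 * q), 2)
  }
  modes <- normal_modes(0.2)
  est <- function(delta) {
    p <- displacement_grid(modes, delta)
    recs <- list(record_from_potential(vfun, 0, "FC"),
                 record_from_potential(vfun, delta, "m1+"),
                 record_from_potential(vfun, -delta, "m1-"))
    fit <- build_lvc_model(recs, modes, 2, strategy = "FrD", protocol = p)
    fit$couplings[1, 1, 1]
  }
  err1 <- est(0.2) - 0.1
  err2 <- est(0.1) - 0.1
  # central difference of c q^3 is exactly c delta^2: Richardson ratio 4
  expect_equal(err1 / err2, 4, tolerance = 0.05)
  expect_equal(err2, cc * 0.1^2, tolerance = 0.05)
})

test_that("the curvature diagnostic reports omega on-diagonal and zero off it", {
  truth <- make_truth_model(n_states = 4, n_modes = 3, seed = 43)
  recs <- generate_records(truth_spec(truth), displacement_grid(truth$modes, 0.1))
  fit <- suppressWarnings(
    build_lvc_model(recs, truth$modes, 4, strategy = "FrD")
  )
  dg <- fit$provenance$diagnostic
  expect_lt(max(dg$diag_curvature_dev), 1e-8)
  expect_lt(max(dg$offdiag_curvature_dev), 1e-8)
  expect_false(any(dg$flagged))

  # even-order anharmonicity must be flagged (odd terms cancel in the second
  # difference by symmetry and surface instead in the coupling extraction)
  ccc <- 0.5
  h <- function(q) matrix(5 + 0.5 * 0.2 * q^2 + ccc * q^4, 1, 1)
  modes1 <- normal_modes(0.2)
  p <- displacement_grid(modes1, 0.3)
  dg2 <- lvc_validity_diagnostic(list(h(0.3)), list(h(-0.3)), h(0),
                                 modes1, p, threshold = 0.01)
  expect_true(dg2$flagged)
})

test_that("the standard strategy yields exactly zero constant couplings", {
  truth <- make_truth_model(n_states = 5, n_modes = 3, seed = 44)
  spec <- truth_spec(truth, reference_type = "adiabatic_fc")
  recs <- generate_records(spec, displacement_grid(truth$modes, 0.1))
  fit <- suppressWarnings(build_lvc_model(recs, truth$modes, 5, strategy = "St"))
  off <- fit$constant_matrix; diag(off) <- 0
  expect_equal(max(abs(off)), 0)
  expect_equal(diag(fit$constant_matrix),
               adiabatic_energies(truth, rep(0, 3))[1:5], tolerance = 1e-12)
})

test_that("missing or inconsistent records fail with informative errors", {
  truth <- make_truth_model(n_states = 4, n_modes = 2, seed = 45)
  prot <- displacement_grid(truth$modes, 0.1)
  recs <- generate_records(truth_spec(truth), prot)
  expect_error(
    suppressWarnings(build_lvc_model(recs[-3], truth$modes, 4)),
    "m1-")
  expect_error(
    suppressWarnings(build_lvc_model(recs[-1], truth$modes, 4)),
    "FC")
  mixed <- recs
  mixed[[2]]$adiabatic_energies <- mixed[[2]]$adiabatic_energies[1:3]
  mixed[[2]]$overlap <- mixed[[2]]$overlap[, 1:3]
  expect_error(suppressWarnings(build_lvc_model(mixed, truth$modes, 4)),
               "inconsistent")
})

test_that("recovery error grows monotonically with reference mixing", {
  truth <- make_truth_model(n_states = 6, n_modes = 4, seed = 47)
  prot <- displacement_grid(truth$modes, 0.1)
  errs <- purrr::map_dbl(c(0, 0.02, 0.05, 0.1), function(theta) {
    spec <- truth_spec(truth, reference_mixing_angle = theta, seed = 99)
    recs <- generate_records(spec, prot)
    fit <- suppressWarnings(
      build_lvc_model(recs, truth$modes, 6, strategy = "FrD"))
    max(abs(fit$constant_matrix - truth$constant_matrix))
  })
  expect_equal(errs[1], 0, tolerance = 1e-10)
  expect_true(all(diff(errs) > 0))
  # mixed references leave reference weights below 1
  spec <- truth_spec(truth, reference_mixing_angle = 0.05, seed = 99)
  w <- reference_weights(generate_record(spec, rep(0, 4))$overlap)
  expect_true(all(w < 1))
})
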