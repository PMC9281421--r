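# Small fixture models and independent oracles used across the suite.

# 2-state / 2-mode model with every LVC ingredient present
two_mode_model <- function() {
  modes <- normal_modes(c(0.18, 0.09))
  cpl <- array(0, c(2, 2, 2))
  cpl[1, 1, ] <- c(0.12, -0.05)
  cpl[2, 2, ] <- c(-0.08, 0.10)
  cpl[1, 2, ] <- cpl[2, 1, ] <- c(0.03, 0.02)
  lvc_model(
    normal_modes(c(0.18, 0.09)),
    lvc_states(c("S1", "S2"), oscillator_strength = c(0.2, 0.1)),
    matrix(c(5.0, 0.04, 0.04, 5.2), 2),
    cpl
  )
}

# seeded random LVC model without symmetry labels
random_model <- function(n, f, seed, coupling_scale = 0.05) {
  withr::with_seed(seed, {
    modes <- normal_modes(runif(f, 0.02, 0.35))
    cm <- matrix(rnorm(n * n, sd = coupling_scale), n)
    cm <- (cm + t(cm)) / 2
    diag(cm) <- sort(runif(n, 4.5, 7))
    cpl <- array(rnorm(n * n * f, sd = coupling_scale), c(n, n, f))
    cpl <- (cpl + aperm(cpl, c(2, 1, 3))) / 2
    lvc_model(modes, lvc_states(paste0("D", seq_len(n))), cm, cpl)
  })
}

# zero-mode purely electronic model
electronic_model <- function(energies, coupling = 0, f_osc = 0) {
  n <- length(energies)
  cm <- matrix(coupling, n, n)
  diag(cm) <- energies
  lvc_model(normal_modes(numeric(0)),
            lvc_states(paste0("E", seq_len(n)), oscillator_strength = f_osc),
            cm, array(0, c(n, n, 0)))
}

# Independent dense-Hamiltonian oracle: enumerates the oscillator product
# basis from scratch (its own state ordering) and assembles matrix elements
# directly from the LVC formulas; shares no code with the package operators.
oracle_dense <- function(model, n_max) {
  n <- nrow(model$states)
  f <- model$modes$n_modes
  w <- model$modes$frequencies
  grids <- if (f > 0) lapply(rep(n_max, length.out = f), function(k) 0:k) else list()
  vib <- if (f > 0) as.matrix(expand.grid(grids)) else matrix(0, 1, 0)
  dv <- nrow(vib)
  d <- dv * n
  h <- matrix(0, d, d)
  idx <- function(el, v) (el - 1) * dv + v
  for (v1 in seq_len(dv)) {
    for (v2 in v1:dv) {
      dn <- vib[v2, ] - vib[v1, ]
      nz <- which(dn != 0)
      if (length(nz) == 0) {
        evib <- sum(w * (vib[v1, ] + 0.5))
        for (i in seq_len(n)) for (j in seq_len(n)) {
          val <- model$constant_matrix[i, j] + if (i == j) evib else 0
          h[idx(i, v1), idx(j, v2)] <- h[idx(j, v2), idx(i, v1)] <- val
        }
      } else if (length(nz) == 1 && abs(dn[nz]) == 1) {
        a <- nz
        qel <- sqrt(max(vib[v1, a], vib[v2, a]) / 2)
        for (i in seq_len(n)) for (j in seq_len(n)) {
          val <- model$couplings[i, j, a] * qel
          h[idx(i, v1), idx(j, v2)] <- h[idx(j, v2), idx(i, v1)] <- val
        }
      }
    }
  }
  list(h = h, dv = dv, vib = vib, idx = idx)
}

# oracle populations: exact exp(-iHt) via eigendecomposition of the oracle H
oracle_populations <- function(model, n_max, initial_state, times) {
  or <- oracle_dense(model, n_max)
  e <- eigen(or$h, symmetric = TRUE)
  psi0 <- numeric(nrow(or$h))
  vac <- which(rowSums(or$vib) == 0)
  psi0[or$idx(initial_state, vac)] <- 1
  phi0 <- crossprod(e$vectors, psi0)
  n <- nrow(model$states)
  pops <- matrix(0, length(times), n)
  for (k in seq_along(times)) {
    psi <- e$vectors %*% (exp(-1i * e$values * times[k] / hbar_ev_fs) * phi0)
    for (i in seq_len(n)) {
      rows <- or$idx(i, seq_len(or$dv))
      pops[k, i] <- sum(Mod(psi[rows])^2)
    }
  }
  pops
}

# record with identity references built directly from an arbitrary potential
# function (used to inject anharmonic contamination)
record_from_potential <- function(vfun, q, tag) {
  v <- vfun(q)
  e <- eigen(v, symmetric = TRUE)
  ord <- order(e$values)
  u <- e$vectors[, ord, drop = FALSE]
  # identity references in the diabatic basis: S_im = <e_i | a_m> = U[i, m]
  es_record(tag, q, e$values[ord], u)
}
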