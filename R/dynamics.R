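#' Harmonic-oscillator product basis for wavepacket propagation
#'
#' Truncated direct-product basis: each mode alpha keeps oscillator levels
#' 0..n_max_alpha of the ground-state harmonic surface, times the N diabatic
#' electronic states. In this basis the LVC Hamiltonian is exactly
#' representable: the vibrational part is diagonal,
#' \eqn{\sum_\alpha \omega_\alpha (n_\alpha + 1/2)}, and each dimensionless
#' coordinate is the tridiagonal ladder combination
#' \eqn{q = (a + a^\dagger)/\sqrt 2}, so the only approximation is the
#' truncation itself.
#'
#' @param model An [lvc_model()].
#' @param n_max Highest oscillator quantum number kept, scalar or one per
#'   mode.
#' @return An object of class `ho_basis`.
#' @export
ho_basis <- function(model, n_max) {
  f <- n_modes(model)
  n_max <- as.integer(rep_len(n_max, f))
  if (f > 0 && any(n_max < 1)) stop("`n_max` must be >= 1 for every mode", call. = FALSE)
  nb <- n_max + 1L
  structure(
    list(n_max = n_max, nb = nb,
         dim_vib = as.integer(prod(nb)),
         n_states = n_states(model),
         dim_total = as.integer(prod(nb)) * n_states(model)),
    class = "ho_basis"
  )
}

#' @export
print.ho_basis <- function(x, ...) {
  cat("<ho_basis> ", x$n_states, " electronic x ", x$dim_vib,
      " vibrational = ", x$dim_total, " basis states\n", sep = "")
  invisible(x)
}

# tridiagonal matrix of q = (a + a^dagger)/sqrt(2) on levels 0..n_max
q_matrix <- function(nb) {
  off <- sqrt(seq_len(nb - 1) / 2)
  m <- matrix(0, nb, nb)
  m[cbind(seq_len(nb - 1), seq_len(nb - 1) + 1)] <- off
  m[cbind(seq_len(nb - 1) + 1, seq_len(nb - 1))] <- off
  m
}

# sparse q_alpha on the full vibrational product space (mode 1 fastest index)
mode_q_operator <- function(basis, alpha) {
  f <- length(basis$nb)
  op <- NULL
  for (m in seq_len(f)) {
    blk <- if (m == alpha) {
      Matrix::Matrix(q_matrix(basis$nb[m]), sparse = TRUE)
    } else {
      Matrix::Diagonal(basis$nb[m])
    }
    op <- if (is.null(op)) blk else Matrix::kronecker(blk, op)
  }
  op
}

# diagonal vibrational energy sum_alpha omega_alpha (n_alpha + 1/2)
vib_energies <- function(model, basis) {
  f <- n_modes(model)
  if (f == 0) return(0)
  eps <- 0
  for (m in seq_len(f)) {
    lev <- model$modes$frequencies[m] * (seq_len(basis$nb[m]) - 0.5)
    eps <- rep(eps, times = basis$nb[m]) +
      rep(lev, each = if (m == 1) 1L else prod(basis$nb[seq_len(m - 1)]))
  }
  eps
}

# real sparse matrix times complex dense matrix (Matrix has no complex class)
smul <- function(A, x) {
  as.matrix(A %*% Re(x)) + 1i * as.matrix(A %*% Im(x))
}

# Assembled operator set: everything propagation and observables need.
lvc_operators <- function(model, basis) {
  f <- n_modes(model)
  n <- n_states(model)
  qs <- purrr::map(seq_len(f), ~ mode_q_operator(basis, .x))
  eps <- vib_energies(model, basis)
  lam <- purrr::map(seq_len(f), ~ model$couplings[, , .x])
  e0 <- model$constant_matrix
  # per-state potential operator minus its constant: 1/2 sum omega q^2 + lambda_ii . q
  vharm <- NULL
  if (f > 0) {
    vharm <- Reduce(`+`, purrr::map(seq_len(f), function(a) {
      (model$modes$frequencies[a] / 2) * (qs[[a]] %*% qs[[a]])
    }))
  }
  vdiag <- purrr::map(seq_len(n), function(i) {
    w <- vharm
    for (a in seq_len(f)) {
      lii <- model$couplings[i, i, a]
      if (lii != 0) w <- w + lii * qs[[a]]
    }
    w
  })
  apply_h <- function(psi) {
    out <- eps * psi + psi %*% e0
    for (a in seq_len(f)) {
      if (any(lam[[a]] != 0)) out <- out + smul(qs[[a]], psi) %*% lam[[a]]
    }
    out
  }
  list(qs = qs, eps = eps, e0 = e0, lam = lam, vdiag = vdiag, apply_h = apply_h,
       basis = basis, n = n, f = f)
}

# dense (or sparse) full Hamiltonian on the stacked space, vec(psi) with the
# vibrational index fastest within each electronic block
full_hamiltonian <- function(model, basis, ops = lvc_operators(model, basis)) {
  dv <- basis$dim_vib
  n <- n_states(model)
  h <- Matrix::kronecker(Matrix::Matrix(ops$e0, sparse = TRUE), Matrix::Diagonal(dv)) +
    Matrix::kronecker(Matrix::Diagonal(n), Matrix::Diagonal(x = rep_len(ops$eps, dv)))
  for (a in seq_len(ops$f)) {
    if (any(ops$lam[[a]] != 0)) {
      h <- h + Matrix::kronecker(Matrix::Matrix(ops$lam[[a]], sparse = TRUE), ops$qs[[a]])
    }
  }
  h
}

#' Wavepacket on the electronic x vibrational product basis
#'
#' @param coefficients Complex `dim_vib x n_states` matrix; columns are the
#'   vibrational amplitudes on each diabatic state.
#' @param basis A [ho_basis()].
#' @param time Time stamp in fs.
#' @return An object of class `wavepacket`.
#' @export
wavepacket <- function(coefficients, basis, time = 0) {
  coefficients <- as.matrix(coefficients)
  storage.mode(coefficients) <- "complex"
  if (nrow(coefficients) != basis$dim_vib || ncol(coefficients) != basis$n_states) {
    stop("coefficients must be ", basis$dim_vib, " x ", basis$n_states, call. = FALSE)
  }
  nrm <- sum(Mod(coefficients)^2)
  if (abs(nrm - 1) > 1e-9) {
    stop("wavepacket norm is ", format(nrm), "; must be 1 within 1e-9", call. = FALSE)
  }
  structure(list(coefficients = coefficients, basis = basis, time = time),
            class = "wavepacket")
}

#' Initial wavepacket for vertical excitation
#'
#' Places the vibrational ground state of the electronic ground surface (the
#' vacuum of every oscillator, since the diabatic surfaces share the S0
#' frequencies) on diabatic state `i`: the sudden-approximation state after
#' photoexcitation to that state.
#'
#' @param model An [lvc_model()].
#' @param i Diabatic state index or label (typically a bright state).
#' @param n_max Basis truncation, passed to [ho_basis()].
#' @return A [wavepacket()] with unit population on state `i`.
#' @export
initial_wavepacket <- function(model, i, n_max = 10) {
  i <- resolve_state(model, i)
  basis <- ho_basis(model, n_max)
  coef <- matrix(0 + 0i, basis$dim_vib, basis$n_states)
  coef[1, i] <- 1 + 0i
  wavepacket(coef, basis)
}

#' Keep the most strongly coupled modes of a model
#'
#' Reduced-dimensionality helper: ranks modes by total squared coupling
#' \eqn{\sum_{ij} \lambda_{ij,\alpha}^2} and keeps the top `k`, dropping the
#' others from the model (their couplings are discarded; constants are
#' unchanged). Mirrors the common practice of allocating propagation effort
#' to the modes with the largest vibronic couplings.
#'
#' @param model An [lvc_model()].
#' @param k Number of modes to keep.
#' @return An [lvc_model()] with `k` modes.
#' @export
reduce_modes <- function(model, k) {
  f <- n_modes(model)
  if (k >= f) return(model)
  score <- purrr::map_dbl(seq_len(f), ~ sum(model$couplings[, , .x]^2))
  keep <- sort(order(score, decreasing = TRUE)[seq_len(k)])
  modes <- normal_modes(model$modes$frequencies[keep],
                        labels = model$modes$labels[keep],
                        symmetry = model$modes$symmetry[keep])
  lvc_model(modes, model$states, model$constant_matrix,
            model$couplings[, , keep, drop = FALSE], check_symmetry = "none",
            provenance = c(model$provenance, list(modes_kept = keep)))
}

#' Propagate a wavepacket under an LVC Hamiltonian
#'
#' Numerically exact propagation \eqn{\psi(t) = e^{-iHt/\hbar}\psi(0)} on the
#' truncated oscillator product basis. Three propagators are available:
#' `"expm"` diagonalizes the full (real symmetric) Hamiltonian once and is
#' exact on the basis; `"lanczos"` uses short-iterative Krylov steps with
#' adaptive substepping; `"chebyshev"` uses a Chebyshev polynomial expansion
#' per output step. `"auto"` picks `"expm"` below `dense_cap` basis states
#' and `"lanczos"` above.
#'
#' Observables are sampled every `dt`: diabatic populations, the expectation
#' of each diabatic potential surface (conditional on the electronic
#' component by default; see `pes_convention`), the autocorrelation function
#' \eqn{\langle\psi(0)|\psi(t)\rangle}, total energy and norm.
#'
#' @param model An [lvc_model()].
#' @param psi0 A [wavepacket()] (see [initial_wavepacket()]).
#' @param t_final Propagation time in fs (> 0); default 250 fs.
#' @param dt Output sampling step in fs (default 0.25).
#' @param method `"auto"`, `"expm"`, `"lanczos"` or `"chebyshev"`.
#' @param pes_convention `"conditional"` divides
#'   \eqn{\langle\psi_i|V_{ii}|\psi_i\rangle} by the population (the energy a
#'   detector conditioned on state i would see) and is the default;
#'   `"unconditional"` reports the raw matrix element. The choice is recorded
#'   in the result metadata.
#' @param population_floor Populations below this leave the conditional PES
#'   expectation masked (`NA`) rather than dividing by ~0.
#' @param dense_cap Largest basis size for the dense-diagonalization path.
#' @param basis_cap Hard cap on the basis size for any method.
#' @param lanczos_tol,lanczos_m Krylov step tolerance and subspace size.
#' @return An object of class `lvc_propagation` with fields `times`,
#'   `populations` (T x N), `pes` (T x N, masked), `autocorrelation`,
#'   `energy`, `norm`, `psi_final`, `model`, `metadata`.
#' @export
propagate <- function(model, psi0, t_final = 250, dt = 0.25,
                      method = c("auto", "expm", "lanczos", "chebyshev"),
                      pes_convention = c("conditional", "unconditional"),
                      population_floor = 1e-8,
                      dense_cap = 4000, basis_cap = 500000,
                      lanczos_tol = 1e-12, lanczos_m = 40) {
  method <- match.arg(method)
  pes_convention <- match.arg(pes_convention)
  stopifnot(inherits(psi0, "wavepacket"))
  if (!is.numeric(t_final) || t_final <= 0) {
    stop("`t_final` must be > 0 fs", call. = FALSE)
  }
  basis <- psi0$basis
  if (basis$n_states != n_states(model)) {
    stop("wavepacket has ", basis$n_states, " electronic states but the model has ",
         n_states(model), call. = FALSE)
  }
  if (basis$dim_total > basis_cap) {
    stop("basis size ", basis$dim_total, " exceeds the cap of ", basis_cap,
         " states; reduce `n_max` or the number of modes", call. = FALSE)
  }
  if (method == "auto") {
    method <- if (basis$dim_total <= dense_cap) "expm" else "lanczos"
  }
  if (method == "expm" && basis$dim_total > dense_cap) {
    stop("dense diagonalization requested for ", basis$dim_total,
         " basis states (cap ", dense_cap, "); use lanczos or chebyshev",
         call. = FALSE)
  }
  ops <- lvc_operators(model, basis)
  times <- seq(0, t_final, by = dt)
  if (times[length(times)] < t_final - 1e-9) times <- c(times, t_final)
  nt <- length(times)

  psi_list <- switch(method,
    expm = propagate_expm(model, basis, ops, psi0$coefficients, times),
    lanczos = propagate_krylov(ops, psi0$coefficients, times,
                               tol = lanczos_tol, m = lanczos_m),
    chebyshev = propagate_chebyshev(ops, psi0$coefficients, times)
  )

  n <- n_states(model)
  pops <- matrix(NA_real_, nt, n)
  pes <- matrix(NA_real_, nt, n)
  energy <- numeric(nt)
  nrm <- numeric(nt)
  autoc <- complex(nt)
  psi0_vec <- as.vector(psi0$coefficients)
  for (k in seq_len(nt)) {
    psi <- psi_list[[k]]
    p <- colSums(Mod(psi)^2)
    pops[k, ] <- p
    nrm[k] <- sum(p)
    autoc[k] <- sum(Conj(psi0_vec) * as.vector(psi))
    energy[k] <- Re(sum(Conj(psi) * ops$apply_h(psi)))
    for (i in seq_len(n)) {
      vii <- Re(sum(Conj(psi[, i]) *
                      (if (is.null(ops$vdiag[[i]])) 0 else smul(ops$vdiag[[i]], psi[, i, drop = FALSE])))) +
        ops$e0[i, i] * p[i]
      if (pes_convention == "conditional") {
        pes[k, i] <- if (p[i] > population_floor) vii / p[i] else NA_real_
      } else {
        pes[k, i] <- vii
      }
    }
  }
  colnames(pops) <- colnames(pes) <- model$states$label
  structure(
    list(times = times, populations = pops, pes = pes,
         autocorrelation = autoc, energy = energy, norm = nrm,
         psi_final = wavepacket(psi_list[[nt]] / sqrt(sum(Mod(psi_list[[nt]])^2)),
                                basis, time = times[nt]),
         model = model,
         metadata = list(method = method, dt = dt, t_final = t_final,
                         n_max = basis$n_max, dim_total = basis$dim_total,
                         pes_convention = pes_convention,
                         initial_state = which.max(colSums(Mod(psi0$coefficients)^2)))),
    class = "lvc_propagation"
  )
}

propagate_expm <- function(model, basis, ops, coef0, times) {
  h <- as.matrix(full_hamiltonian(model, basis, ops))
  e <- eigen((h + t(h)) / 2, symmetric = TRUE)
  phi0 <- crossprod(e$vectors, as.vector(coef0))  # complex amplitudes
  phases <- exp(outer(e$values, times, function(v, t) -1i * v * t / hbar_ev_fs))
  psi_all <- e$vectors %*% (phases * as.vector(phi0))
  purrr::map(seq_along(times), function(k) {
    matrix(psi_all[, k], basis$dim_vib, basis$n_states)
  })
}

# one adaptive short-iterative-Lanczos step of length dt
krylov_step <- function(apply_h_vec, v, dt, tol, m) {
  d <- length(v)
  m_eff <- min(m, d)
  beta0 <- sqrt(sum(Mod(v)^2))
  vs <- matrix(0i, d, m_eff)
  vs[, 1] <- v / beta0
  alpha <- numeric(m_eff); beta <- numeric(m_eff)
  j_used <- m_eff
  for (j in seq_len(m_eff)) {
    w <- apply_h_vec(vs[, j])
    if (j > 1) w <- w - beta[j - 1] * vs[, j - 1]
    alpha[j] <- Re(sum(Conj(vs[, j]) * w))
    w <- w - alpha[j] * vs[, j]
    # full reorthogonalization; m is small
    proj <- crossprod(Conj(vs[, seq_len(j), drop = FALSE]), w)
    w <- w - vs[, seq_len(j), drop = FALSE] %*% proj
    bj <- sqrt(sum(Mod(w)^2))
    if (j < m_eff) {
      if (bj < 1e-14) { j_used <- j; break }
      beta[j] <- bj
      vs[, j + 1] <- w / bj
    }
    j_used <- j
  }
  tmat <- diag(alpha[seq_len(j_used)], j_used)
  if (j_used > 1) {
    idx <- seq_len(j_used - 1)
    tmat[cbind(idx, idx + 1)] <- beta[idx]
    tmat[cbind(idx + 1, idx)] <- beta[idx]
  }
  te <- eigen(tmat, symmetric = TRUE)
  coef <- te$vectors %*% (exp(-1i * te$values * dt / hbar_ev_fs) * te$vectors[1, ])
  err <- if (j_used == m_eff) Mod(coef[j_used]) else 0
  list(psi = beta0 * (vs[, seq_len(j_used), drop = FALSE] %*% coef), err = err)
}

propagate_krylov <- function(ops, coef0, times, tol, m, max_split = 12) {
  dv <- nrow(coef0); n <- ncol(coef0)
  apply_h_vec <- function(x) as.vector(ops$apply_h(matrix(x, dv, n)))
  out <- vector("list", length(times))
  out[[1]] <- coef0
  v <- as.vector(coef0)
  for (k in seq_along(times)[-1]) {
    dt <- times[k] - times[k - 1]
    nsub <- 1; done <- FALSE
    for (s in seq_len(max_split)) {
      vtry <- v; ok <- TRUE
      for (ss in seq_len(nsub)) {
        st <- krylov_step(apply_h_vec, vtry, dt / nsub, tol, m)
        if (st$err > tol) { ok <- FALSE; break }
        vtry <- st$psi
      }
      if (ok) { v <- vtry; done <- TRUE; break }
      nsub <- nsub * 2
    }
    if (!done) {
      stop("Lanczos step did not converge below tolerance ", format(tol),
           " (residual ", format(st$err), ") even with ", nsub,
           " substeps; increase `lanczos_m`", call. = FALSE)
    }
    out[[k]] <- matrix(v, dv, n)
  }
  out
}

propagate_chebyshev <- function(ops, coef0, times, tail_tol = 1e-15) {
  dv <- nrow(coef0); n <- ncol(coef0)
  apply_h_vec <- function(x) as.vector(ops$apply_h(matrix(x, dv, n)))
  d <- dv * n
  # spectral bounds from a short Lanczos sweep, padded by 10%
  m_est <- min(40, d)
  v <- complex(real = stats::rnorm(d)); v <- v / sqrt(sum(Mod(v)^2))
  alpha <- numeric(m_est); beta <- numeric(m_est)
  vprev <- 0i * v
  for (j in seq_len(m_est)) {
    w <- apply_h_vec(v)
    if (j > 1) w <- w - beta[j - 1] * vprev
    alpha[j] <- Re(sum(Conj(v) * w))
    w <- w - alpha[j] * v
    bj <- sqrt(sum(Mod(w)^2))
    beta[j] <- bj
    if (bj < 1e-12) { m_est <- j; break }
    vprev <- v; v <- w / bj
  }
  tmat <- diag(alpha[seq_len(m_est)], m_est)
  if (m_est > 1) {
    idx <- seq_len(m_est - 1)
    tmat[cbind(idx, idx + 1)] <- beta[idx]
    tmat[cbind(idx + 1, idx)] <- beta[idx]
  }
  ev <- eigen(tmat, symmetric = TRUE, only.values = TRUE)$values
  span <- max(ev) - min(ev)
  emin <- min(ev) - 0.1 * span - 1e-6
  emax <- max(ev) + 0.1 * span + 1e-6
  ebar <- (emax + emin) / 2
  r <- (emax - emin) / 2
  apply_hnorm <- function(x) (apply_h_vec(x) - ebar * x) / r

  out <- vector("list", length(times))
  out[[1]] <- coef0
  vcur <- as.vector(coef0)
  for (k in seq_along(times)[-1]) {
    dt <- times[k] - times[k - 1]
    tau <- r * dt / hbar_ev_fs
    kmax <- max(20, ceiling(tau + 40 * (1 + tau^(1 / 3))))
    jk <- besselJ(tau, 0:kmax)  # jk[k + 1] = J_k(tau)
    last_order <- min(max(which(abs(jk) > tail_tol)) - 1, kmax - 1)
    t0 <- vcur
    t1 <- apply_hnorm(vcur)
    acc <- jk[1] * t0 + 2 * (-1i) * jk[2] * t1
    if (last_order >= 2) {
      for (kk in 2:last_order) {
        t2 <- 2 * apply_hnorm(t1) - t0
        acc <- acc + 2 * (-1i)^kk * jk[kk + 1] * t2
        t0 <- t1; t1 <- t2
      }
    }
    vcur <- exp(-1i * ebar * dt / hbar_ev_fs) * acc
    out[[k]] <- matrix(vcur, dv, n)
  }
  out
}

#' Diabatic populations of a propagation as a tidy table
#'
#' @param result An [propagate()] result.
#' @return Tibble with columns `time`, `state`, `population`.
#' @export
diabatic_populations <- function(result) {
  stopifnot(inherits(result, "lvc_propagation"))
  tibble::as_tibble(result$populations) |>
    dplyr::mutate(time = result$times) |>
    tidyr::pivot_longer(-"time", names_to = "state", values_to = "population") |>
    dplyr::mutate(state = factor(.data$state, levels = colnames(result$populations)))
}

#' Expectation of the diabatic potential surfaces over time
#'
#' The energy of each diabatic potential surface evaluated over (by default)
#' the corresponding electronic component of the wavepacket; masked (`NA`)
#' where that component's population is below the floor used during
#' propagation.
#'
#' @inheritParams diabatic_populations
#' @return Tibble with columns `time`, `state`, `pes_expectation` (eV).
#' @export
pes_expectations <- function(result) {
  stopifnot(inherits(result, "lvc_propagation"))
  tibble::as_tibble(result$pes) |>
    dplyr::mutate(time = result$times) |>
    tidyr::pivot_longer(-"time", names_to = "state", values_to = "pes_expectation") |>
    dplyr::mutate(state = factor(.data$state, levels = colnames(result$pes)))
}

#' @export
print.lvc_propagation <- function(x, ...) {
  cat("<lvc_propagation> ", length(x$times), " samples to ",
      x$times[length(x$times)], " fs, method ", x$metadata$method,
      ", basis ", x$metadata$dim_total, "\n", sep = "")
  cat("  final populations: ",
      paste(format(round(x$populations[nrow(x$populations), ], 3)), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' @rdname diabatic_populations
#' @param x An `lvc_propagation`.
#' @param ... Unused.
#' @method tidy lvc_propagation
#' @export
tidy.lvc_propagation <- function(x, ...) diabatic_populations(x)

#' @rdname diabatic_populations
#' @method glance lvc_propagation
#' @export
glance.lvc_propagation <- function(x, ...) {
  tibble::tibble(
    t_final = x$times[length(x$times)],
    method = x$metadata$method,
    dim_total = x$metadata$dim_total,
    norm_drift = max(abs(x$norm - 1)),
    energy_drift = max(abs(x$energy - x$energy[1])),
    initial_state = colnames(x$populations)[x$metadata$initial_state]
  )
}
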