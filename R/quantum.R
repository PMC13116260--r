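# Quantum analysis of the confined ion pair: finite-difference Hamiltonian
# on the 2D PMF, sparse eigensolve (shift-invert ARPACK), and comparison
# against the analytic coupled-quantum-harmonic-oscillator (CQHO) reference
# whose Hermite-Gaussian eigenstates fingerprint the oscillation modes.

#' Discrete Hamiltonian on a 2D PMF grid
#'
#' Builds the symmetric sparse operator `H = -(hbar^2/2m)(d2/dz1^2 +
#' d2/dz2^2) + U(z1, z2)` by 5-point central differences on the uniform
#' displacement mesh, with Dirichlet boundaries. Masked (unsampled) PMF bins
#' are filled with a confining plateau `max(U) + 0.1 eV`.
#'
#' @param pmf A 2D `pmf_grid` (see [pmf_1d()]) on a uniform mesh (or a list with `mids`,
#'   `mids2` (A) and `energy` matrix in eV).
#' @param mass Mass on each coordinate, kg (the single-ion Ca2+ mass).
#' @return List of class `schrodinger_grid`: sparse `H` (J), grid vectors
#'   `z1`, `z2` (m), spacing `dx` (m), `U` (J, plateau-filled) and `mass`.
#' @export
build_hamiltonian <- function(pmf, mass = .ca_mass) {
  stopifnot(!is.null(pmf$mids), !is.null(pmf$mids2))
  z1 <- pmf$mids * .const$ang
  z2 <- pmf$mids2 * .const$ang
  d1 <- diff(z1); d2 <- diff(z2)
  if (max(abs(d1 - d1[1])) > 1e-9 * d1[1] ||
      max(abs(d2 - d2[1])) > 1e-9 * d2[1] ||
      abs(d1[1] - d2[1]) > 1e-9 * d1[1])
    stop("the Hamiltonian requires a uniform square mesh")
  dx <- d1[1]
  U <- pmf$energy * .const$eV
  if (anyNA(U)) {
    plateau <- max(U, na.rm = TRUE) + 0.1 * .const$eV
    U[is.na(U)] <- plateau
  }
  n1 <- length(z1); n2 <- length(z2)
  t0 <- .const$hbar^2 / (2 * mass * dx^2)
  # 1D second-difference operator (Dirichlet)
  lap1 <- function(n) Matrix::bandSparse(n, n, k = c(-1, 0, 1),
                                         diagonals = list(rep(1, n - 1),
                                                          rep(-2, n),
                                                          rep(1, n - 1)),
                                         symmetric = FALSE)
  I1 <- Matrix::Diagonal(n1); I2 <- Matrix::Diagonal(n2)
  K <- -t0 * (Matrix::kronecker(I2, lap1(n1)) +
              Matrix::kronecker(lap1(n2), I1))
  H <- K + Matrix::Diagonal(n1 * n2, as.numeric(U))
  H <- methods::as(Matrix::forceSymmetric(H), "CsparseMatrix")
  structure(list(H = H, z1 = z1, z2 = z2, dx = dx, U = U, mass = mass,
                 n1 = n1, n2 = n2),
            class = "schrodinger_grid")
}

#' Lowest eigenstates of the discrete Hamiltonian
#'
#' Computes the `k` lowest eigenpairs by shift-invert Lanczos (ARPACK on the
#' sparse Cholesky-factored operator), normalizes the probability densities
#' on the grid, and reports transition frequencies from the ground state.
#'
#' @param H A `schrodinger_grid` from [build_hamiltonian()].
#' @param k Number of states (>= 4 for mode fingerprinting).
#' @return An object of class `eigen_solution`: `energies` (J), `energies_meV`,
#'   `transitions_THz` (state 0 has 0), `densities` (list of matrices summing
#'   to 1 times the cell area... normalized so `sum(d) * dx^2 = 1`), grid
#'   vectors in angstrom, and empty labels (see [classify_mode()]).
#' @export
solve_eigenstates <- function(H, k = 6) {
  stopifnot(inherits(H, "schrodinger_grid"), k >= 1)
  n <- nrow(H$H)
  scale <- .const$eV                       # solve in eV units for conditioning
  Hs <- H$H / scale
  vals <- NULL; vecs <- NULL
  res <- tryCatch({
    ch <- Matrix::Cholesky(Hs, LDL = FALSE, perm = TRUE)
    fn <- function(x, extra = NULL)
      as.numeric(Matrix::solve(ch, x, system = "A"))
    igraph::arpack(fn, sym = TRUE,
                   options = list(n = n, nev = k, ncv = max(4 * k, 20),
                                  which = "LM", maxiter = 3000))
  }, error = function(e) NULL)
  if (!is.null(res)) {
    ord <- order(res$values, decreasing = TRUE)   # largest 1/E = smallest E
    vals <- (1 / res$values[ord]) * scale
    vecs <- res$vectors[, ord, drop = FALSE]
  } else {
    if (n > 6400)
      stop("sparse eigensolver failed to converge on a grid too large for ",
           "the dense fallback")
    es <- eigen(as.matrix(Hs), symmetric = TRUE)
    sel <- rev(seq(n - k + 1, n))
    vals <- es$values[sel] * scale
    vecs <- es$vectors[, sel, drop = FALSE]
  }
  dens <- lapply(seq_len(k), function(i) {
    psi <- matrix(vecs[, i], H$n1, H$n2)
    d <- psi^2
    d / (sum(d) * H$dx^2)
  })
  structure(list(
    energies = vals,
    energies_meV = vals / .const$eV * 1e3,
    transitions_THz = (vals - vals[1]) / .const$h / .const$THz,
    densities = dens,
    z1 = H$z1 / .const$ang, z2 = H$z2 / .const$ang, dx = H$dx,
    mass = H$mass,
    labels = rep(NA_character_, k),
    quantum_numbers = matrix(NA_integer_, k, 2,
                             dimnames = list(NULL, c("n_s", "n_a")))
  ), class = "eigen_solution")
}

# 1D quantum harmonic oscillator eigenfunction (normalized), x in m
.qho_psi <- function(n, x, mass, omega) {
  xi <- x * sqrt(mass * omega / .const$hbar)
  # Hermite recurrence H_{k+1} = 2 xi H_k - 2k H_{k-1}
  Hk <- rep(1, length(xi)); Hkm1 <- rep(0, length(xi))
  if (n > 0) {
    for (kk in seq_len(n)) {
      Hkp1 <- 2 * xi * Hk - 2 * (kk - 1) * Hkm1
      Hkm1 <- Hk; Hk <- Hkp1
    }
  }
  (mass * omega / (pi * .const$hbar))^0.25 / sqrt(2^n * factorial(n)) *
    Hk * exp(-xi^2 / 2)
}

#' Analytic coupled-quantum-harmonic-oscillator reference states
#'
#' Eigenstates of the separable oscillator in the rotated normal-mode
#' coordinates `s = (dz1 + dz2)/sqrt(2)` (symmetric/in-phase, frequency
#' `f_in`) and `a = (dz1 - dz2)/sqrt(2)` (anti-symmetric/out-of-phase,
#' `f_out`): `E(n_s, n_a) = h f_in (n_s + 1/2) + h f_out (n_a + 1/2)`, with
#' Hermite-Gaussian probability densities evaluated on the grid. These serve
#' as fingerprints for labeling the PMF-derived states.
#'
#' @param f_in,f_out Mode frequencies in THz.
#' @param z1,z2 Grid bin centers in angstrom (displacement coordinates).
#' @param mass Single-ion mass, kg.
#' @param k Number of states (lowest `k` by energy).
#' @return An `eigen_solution` with quantum-number labels filled in.
#' @export
cqho_reference <- function(f_in = 1.65, f_out = 2.84, z1, z2 = z1,
                           mass = .ca_mass, k = 6) {
  stopifnot(f_in > 0, f_out > 0)
  om_s <- 2 * pi * f_in * .const$THz
  om_a <- 2 * pi * f_out * .const$THz
  nmax <- k + 4
  combos <- expand.grid(n_s = 0:nmax, n_a = 0:nmax)
  combos$E <- .const$h * (f_in * (combos$n_s + 0.5) +
                          f_out * (combos$n_a + 0.5)) * .const$THz
  combos <- combos[order(combos$E, combos$n_a), ][seq_len(k), ]
  g1 <- z1 * .const$ang
  g2 <- z2 * .const$ang
  dx <- g1[2] - g1[1]
  S <- outer(g1, g2, function(a, b) (a + b) / sqrt(2))
  A <- outer(g1, g2, function(a, b) (a - b) / sqrt(2))
  dens <- vector("list", k)
  for (i in seq_len(k)) {
    ps <- .qho_psi(combos$n_s[i], as.numeric(S), mass, om_s)
    pa <- .qho_psi(combos$n_a[i], as.numeric(A), mass, om_a)
    d <- matrix((ps * pa)^2, length(g1), length(g2))
    dens[[i]] <- d / (sum(d) * dx^2)
  }
  labels <- ifelse(combos$n_a == 0 & combos$n_s > 0, "in-phase",
                   ifelse(combos$n_s == 0 & combos$n_a > 0, "out-of-phase",
                          ifelse(combos$n_s == 0 & combos$n_a == 0,
                                 "ground", "mixed")))
  structure(list(
    energies = combos$E,
    energies_meV = combos$E / .const$eV * 1e3,
    transitions_THz = (combos$E - combos$E[1]) / .const$h / .const$THz,
    densities = dens,
    z1 = z1, z2 = z2, dx = dx, mass = mass,
    labels = labels,
    quantum_numbers = cbind(n_s = combos$n_s, n_a = combos$n_a)
  ), class = "eigen_solution")
}

#' Label an eigenstate against the CQHO fingerprint
#'
#' Assigns the reference state with the maximal density-overlap integral
#' `sum(sqrt(d1 * d2)) * dx^2` (1 for identical densities) and reports the
#' corresponding oscillation-mode label and quantum numbers.
#'
#' @param state A density matrix, or an `eigen_solution` plus `which` index.
#' @param reference A reference `eigen_solution` (see [cqho_reference()]) on
#'   the same grid.
#' @param which State index in `state` when it is an `eigen_solution`.
#' @return List with `label`, `n_s`, `n_a`, `overlap` and the reference state
#'   `index`. Overlaps below 0.5 yield label `"mixed"` with a warning.
#' @export
classify_mode <- function(state, reference, which = 1) {
  stopifnot(inherits(reference, "eigen_solution"))
  d <- if (inherits(state, "eigen_solution")) state$densities[[which]] else state
  stopifnot(all(dim(d) == dim(reference$densities[[1]])))
  dx2 <- reference$dx^2
  ov <- vapply(reference$densities,
               function(r) sum(sqrt(pmax(d, 0) * pmax(r, 0))) * dx2,
               numeric(1))
  i <- which.max(ov)
  out <- list(label = reference$labels[i],
              n_s = unname(reference$quantum_numbers[i, 1]),
              n_a = unname(reference$quantum_numbers[i, 2]),
              overlap = ov[i], index = i)
  if (ov[i] < 0.5) {
    warning("all fingerprint overlaps below 0.5; labeling as mixed")
    out$label <- "mixed"
  }
  out
}

#' Label all states of an eigensolution
#'
#' Convenience wrapper applying [classify_mode()] to every state.
#'
#' @param solution An `eigen_solution`.
#' @param reference A reference `eigen_solution` on the same grid.
#' @return `solution` with `labels` and `quantum_numbers` filled and an
#'   `overlaps` vector added.
#' @export
classify_modes <- function(solution, reference) {
  stopifnot(inherits(solution, "eigen_solution"))
  k <- length(solution$energies)
  ov <- numeric(k)
  for (i in seq_len(k)) {
    cl <- classify_mode(solution, reference, which = i)
    solution$labels[i] <- cl$label
    solution$quantum_numbers[i, ] <- c(cl$n_s, cl$n_a)
    ov[i] <- cl$overlap
  }
  solution$overlaps <- ov
  solution
}

#' @export
print.eigen_solution <- function(x, ...) {
  k <- length(x$energies)
  cat(sprintf("eigen_solution: %d states on a %d x %d grid\n", k,
              length(x$z1), length(x$z2)))
  df <- data.frame(state = seq_len(k) - 1,
                   E_meV = round(x$energies_meV, 4),
                   dE_THz = round(x$transitions_THz, 4),
                   label = x$labels,
                   n_s = x$quantum_numbers[, 1],
                   n_a = x$quantum_numbers[, 2])
  if (!is.null(x$overlaps)) df$overlap <- round(x$overlaps, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.eigen_solution <- function(x, which = 1, ...) {
  graphics::image(x$z1, x$z2, x$densities[[which]],
                  xlab = expression(Delta * z[1] ~ "[Å]"),
                  ylab = expression(Delta * z[2] ~ "[Å]"),
                  main = sprintf("state %d density%s", which - 1,
                                 if (!is.na(x$labels[which]))
                                   paste0(" (", x$labels[which], ")") else ""),
                  ...)
  invisible(x)
}
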