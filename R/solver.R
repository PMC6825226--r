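# Linear solution of the assembled Stokes/Brinkman saddle-point system.
#
# Primary method: pressure Schur complement. The viscous block A is SPD and
# component-block-diagonal; it is factorised once (CHOLMOD), and conjugate
# gradients run on S = Bt' A^-1 Bt, which is spectrally close to a mass
# matrix and converges in a few dozen iterations with Jacobi scaling.
# Momentum is then satisfied to factorisation accuracy and the CG residual
# *is* the discrete mass residual, which maps directly onto the convergence
# criterion (relative RMS mass residual <= tol).

solve_saddle_schur <- function(sys, tol = 1e-4, maxit = NULL) {
  A <- sys$A; Bt <- sys$Bt; b <- sys$b; g <- sys$g
  nc <- length(g)
  maxit <- maxit %||% max(200L, as.integer(10 * ceiling(sqrt(nc))))
  ch <- Matrix::Cholesky(methods::as(A, "symmetricMatrix"), LDL = FALSE)
  solveA <- function(x) as.numeric(Matrix::solve(ch, x, system = "A"))
  B <- Matrix::t(Bt)

  Ainv_b <- solveA(b)
  rhs_s <- as.numeric(B %*% Ainv_b) + g
  rhs_norm <- sqrt(sum(rhs_s^2))
  if (rhs_norm == 0) {
    return(list(u = numeric(nrow(Bt)), p = numeric(nc),
                rel_mass_residual = 0, iterations = 0L,
                residual_history = numeric(0)))
  }

  # Jacobi preconditioner: diag(S) ~ colSums(Bt^2 / diag(A))
  dA <- Matrix::diag(A)
  Bt2 <- Bt
  Bt2@x <- Bt2@x^2 / dA[Bt2@i + 1L]
  dS <- pmax(Matrix::colSums(Bt2), .Machine$double.eps)

  apply_s <- function(p) as.numeric(B %*% solveA(as.numeric(Bt %*% p)))

  p <- numeric(nc)
  r <- rhs_s
  z <- r / dS
  d <- z
  rz <- sum(r * z)
  hist <- numeric(0)
  it <- 0L
  repeat {
    it <- it + 1L
    Sd <- apply_s(d)
    alpha <- rz / sum(d * Sd)
    p <- p + alpha * d
    r <- r - alpha * Sd
    rel <- sqrt(sum(r^2)) / rhs_norm
    hist <- c(hist, rel)
    if (rel <= tol || it >= maxit) break
    z <- r / dS
    rz_new <- sum(r * z)
    d <- z + (rz_new / rz) * d
    rz <- rz_new
  }
  if (hist[length(hist)] > tol)
    stop_pf(paste0("Stokes solve did not converge: relative mass residual ",
                   "%.3e after %d iterations (tol %.1e); residual history ",
                   "tail: %s"),
            hist[length(hist)], it, tol,
            paste(signif(utils::tail(hist, 5), 3), collapse = ", "))
  u <- solveA(b - as.numeric(Bt %*% p))
  list(u = u, p = p, rel_mass_residual = hist[length(hist)],
       rel_momentum_residual = 0,
       iterations = it, residual_history = hist)
}

# Full-system preconditioned MINRES with block-Jacobi scaling: 1/diag(A) on
# velocities and the inverse of the Schur-diagonal estimate on pressures.
# Faster than the Schur route on large domains (no factorisation, matvec
# cost only); restarted with a tighter tolerance if the discrete mass
# residual has not yet met `tol`.
solve_saddle_minres <- function(sys, tol = 1e-4, maxit = NULL) {
  A <- sys$A; Bt <- sys$Bt; b <- sys$b; g <- sys$g
  nvel <- nrow(Bt); nc <- ncol(Bt)
  maxit <- maxit %||% max(2000L, as.integer(40 * ceiling(sqrt(nvel + nc))))
  K <- rbind(cbind(A, Bt), cbind(Matrix::t(Bt), Matrix::Matrix(0, nc, nc)))
  K <- methods::as(K, "CsparseMatrix")
  rhs <- c(b, -g)
  if (all(rhs == 0)) {
    return(list(u = numeric(nvel), p = numeric(nc), rel_mass_residual = 0,
                rel_momentum_residual = 0, iterations = 0L,
                residual_history = numeric(0)))
  }
  dA <- Matrix::diag(A)
  Bt2 <- Bt
  Bt2@x <- Bt2@x^2 / dA[Bt2@i + 1L]
  dS <- pmax(Matrix::colSums(Bt2), .Machine$double.eps)
  Mi <- c(1 / dA, 1 / dS)

  g_norm <- sqrt(sum(g^2))
  b_norm <- sqrt(sum(b^2))
  Bt_abs <- abs(Bt)
  # mass residual relative to the cell-wise gross flux of the solution
  # (equivalently, for velocity-driven runs, to the inflow forcing)
  mass_rel <- function(u) {
    r <- as.numeric(Matrix::crossprod(Bt, u)) + g
    ref <- max(g_norm, sqrt(sum(as.numeric(Matrix::crossprod(Bt_abs,
                                                             abs(u)))^2)) / 2)
    if (ref == 0) return(0)
    sqrt(sum(r^2)) / ref
  }
  mom_rel <- function(u, p) {
    r <- b - as.numeric(A %*% u) - as.numeric(Bt %*% p)
    sqrt(sum(r^2)) / max(b_norm, 1e-300)
  }

  x <- numeric(nvel + nc)
  total_it <- 0L
  tol_k <- tol
  hist <- numeric(0)
  for (round in 1:4) {
    r0 <- rhs - as.numeric(K %*% x)
    st <- minres_core(K, r0, Mi, tol_k, maxit - total_it)
    x <- x + st$x
    total_it <- total_it + st$iters
    u <- x[seq_len(nvel)]; p <- x[nvel + seq_len(nc)]
    m_rel <- mass_rel(u)
    hist <- c(hist, m_rel)
    if (m_rel <= tol || total_it >= maxit) break
    tol_k <- tol_k / 20
  }
  if (m_rel > tol)
    stop_pf(paste0("Stokes solve did not converge: relative mass residual ",
                   "%.3e after %d MINRES iterations (tol %.1e)"),
            m_rel, total_it, tol)
  list(u = u, p = p, rel_mass_residual = m_rel,
       rel_momentum_residual = mom_rel(u, p),
       iterations = total_it, residual_history = hist)
}

# textbook preconditioned MINRES (Paige & Saunders) on K x = r0, x0 = 0
minres_core <- function(K, r0, Mi, tol, maxit) {
  x <- numeric(length(r0))
  z <- Mi * r0
  beta1 <- sqrt(sum(r0 * z))
  if (beta1 == 0 || maxit < 1) return(list(x = x, iters = 0L))
  v_old <- numeric(length(r0)); v <- r0 / beta1; z <- z / beta1
  beta <- beta1
  d_old <- numeric(length(r0)); d_oold <- numeric(length(r0))
  c_old <- 1; s_old <- 0; c_oold <- 1; s_oold <- 0
  eta <- beta1
  it <- 0L
  repeat {
    it <- it + 1L
    av <- as.numeric(K %*% z)
    alpha <- sum(z * av)
    w <- av - alpha * v - beta * v_old
    v_old <- v
    zw <- Mi * w
    beta_new <- sqrt(max(sum(w * zw), 0))
    delta <- c_old * alpha - c_oold * s_old * beta
    rho1 <- sqrt(delta^2 + beta_new^2)
    rho2 <- s_old * alpha + c_oold * c_old * beta
    rho3 <- s_oold * beta
    c_new <- delta / rho1; s_new <- beta_new / rho1
    d_new <- (z - rho3 * d_oold - rho2 * d_old) / rho1
    x <- x + c_new * eta * d_new
    eta <- -s_new * eta
    d_oold <- d_old; d_old <- d_new
    c_oold <- c_old; s_oold <- s_old; c_old <- c_new; s_old <- s_new
    if (beta_new == 0 || abs(eta) / beta1 <= tol || it >= maxit) break
    v <- w / beta_new
    z <- zw / beta_new
    beta <- beta_new
  }
  list(x = x, iters = it)
}

# dispatch: factorised Schur complement for small or high-accuracy systems,
# MINRES for large ones at engineering tolerances (its iteration count, not
# a factorisation, sets the cost, so it wins when tol is loose)
solve_saddle <- function(sys, tol, maxit = NULL, method = c("auto", "schur",
                                                            "minres")) {
  method <- match.arg(method)
  n_tot <- nrow(sys$Bt) + ncol(sys$Bt)
  if (method == "auto") {
    cutoff <- if (tol <= 1e-6) 250000L else 120000L
    method <- if (n_tot <= cutoff) "schur" else "minres"
  }
  if (method == "schur") solve_saddle_schur(sys, tol, maxit)
  else solve_saddle_minres(sys, tol, maxit)
}
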