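# Staggered-grid (marker-and-cell) finite-volume assembly of the Stokes /
# Brinkman saddle-point system on a binary voxel domain.
#
# Unknowns are face-normal velocities on faces between two fluid cells plus,
# depending on boundary conditions, the open inlet/outlet faces; pressures
# live at fluid cell centres. Solid voxels are excluded from the unknown set,
# so no-slip on the pore walls holds by construction: wall-normal neighbour
# velocities are identically zero, and wall-tangential neighbours are folded
# in through reflecting ghost values (-u), placing the no-slip plane halfway
# between face centres (the staircase wall).
#
# All equations are scaled by h^2, giving the symmetric system
#     [ A   Bt ] [u]   [b ]
#     [ Bt' 0  ] [p] = [-g]
# with A SPD (viscous + Brinkman drag), Bt the (scaled) discrete gradient,
# and continuity D u = g where D = -t(Bt). Entries: A ~ mu, Bt ~ h.
#
# Boundary conditions:
#   inlet  (-z): uniform velocity u_in (plug, zero tangential), or a uniform
#                normal traction (pressure p_in with free tangential slip)
#   outlet (+z): pressure p_out (free outflow, developed-flow truncation)
#   lateral x/y: "symmetric" (zero normal velocity, zero normal gradient of
#                tangential velocity) or "no_slip"
# Prescribed pressures act at ghost centres half a voxel outside the box, so
# a pressure-driven column has effective length H + h; the pressure-drop
# accessors account for this.

unit3 <- function(a) { e <- c(0L, 0L, 0L); e[a] <- 1L; e }

# id[f + e] on the same face lattice, 0 outside
shift_id <- function(id, e) shift_array(id, -e[1], -e[2], -e[3], fill = 0L)

in_lattice <- function(dims_f, e) {
  shift_array(array(TRUE, dims_f), -e[1], -e[2], -e[3], fill = FALSE)
}

# Build the discrete system. mask: logical (nx,ny,nz); h in m; mu in Pa.s;
# bc: list(inlet_kind, inlet_value, outlet_pressure, lateral_kind);
# invk: optional per-cell inverse permeability (1/m^2) for Brinkman drag.
assemble_stokes <- function(mask, h, mu, bc, invk = NULL) {
  d <- dim(mask)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  press_in <- bc$inlet_kind == "pressure"

  cid <- array(0L, d)
  cid[mask] <- seq_len(sum(mask))
  nc <- sum(mask)

  # unknown-face masks per component
  ufl <- array(FALSE, c(nx + 1, ny, nz))
  if (nx > 1) ufl[2:nx, , ] <- mask[1:(nx - 1), , ] & mask[2:nx, , ]
  vfl <- array(FALSE, c(nx, ny + 1, nz))
  if (ny > 1) vfl[, 2:ny, ] <- mask[, 1:(ny - 1), ] & mask[, 2:ny, ]
  wfl <- array(FALSE, c(nx, ny, nz + 1))
  if (nz > 1) wfl[, , 2:nz] <- mask[, , 1:(nz - 1)] & mask[, , 2:nz]
  if (press_in) wfl[, , 1] <- mask[, , 1]
  wfl[, , nz + 1] <- mask[, , nz]

  fids <- list(array(0L, dim(ufl)), array(0L, dim(vfl)), array(0L, dim(wfl)))
  n_u <- sum(ufl); n_v <- sum(vfl); n_w <- sum(wfl)
  fids[[1]][ufl] <- seq_len(n_u)
  fids[[2]][vfl] <- n_u + seq_len(n_v)
  fids[[3]][wfl] <- n_u + n_v + seq_len(n_w)
  nvel <- n_u + n_v + n_w
  if (nvel == 0L) stop_pf("domain has no velocity unknowns (blocked?)")

  # per-cell Brinkman inverse permeability, 0 = free fluid
  if (is.null(invk)) invk <- array(0, d)

  ti <- vector("list", 64); tj <- ti; tx <- ti; nt <- 0L
  bi <- vector("list", 16); bj <- bi; bx <- bi; nb <- 0L
  push <- function(i, j, x) {
    nt <<- nt + 1L; ti[[nt]] <<- i; tj[[nt]] <<- j; tx[[nt]] <<- x
  }
  pushB <- function(i, j, x) {
    nb <<- nb + 1L; bi[[nb]] <<- i; bj[[nb]] <<- j; bx[[nb]] <<- x
  }

  rhs <- numeric(nvel)

  for (comp in 1:3) {
    fid <- fids[[comp]]
    dims_f <- dim(fid)
    unk <- fid > 0L
    diag_acc <- array(0, dims_f)
    rhs_acc <- array(0, dims_f)

    for (a in 1:3) for (s in c(-1L, 1L)) {
      e <- s * unit3(a)
      nid <- shift_id(fid, e)
      inl <- in_lattice(dims_f, e)
      link <- unk & nid > 0L
      if (any(link)) {
        push(fid[link], nid[link], rep(-mu, sum(link)))
        diag_acc[link] <- diag_acc[link] + mu
      }
      rest <- unk & !(nid > 0L)
      if (!any(rest)) next
      if (a == comp) {
        # wall-normal / prescribed-value neighbours: exact zero (or u_in)
        par_in <- rest & inl
        diag_acc[par_in] <- diag_acc[par_in] + mu
        if (comp == 3L && s == -1L && !press_in && bc$inlet_value != 0) {
          # neighbour is the prescribed inlet face (k = 1, fluid column)
          infl <- par_in
          infl[, , -2] <- FALSE  # only faces at k = 2 see the inlet
          rhs_acc[infl] <- rhs_acc[infl] + mu * bc$inlet_value
        }
        # out-of-lattice parallel neighbours (open in/outflow): free
      } else {
        tang_in <- rest & inl
        diag_acc[tang_in] <- diag_acc[tang_in] + 2 * mu  # staircase ghost
        out <- rest & !inl
        if (any(out)) {
          if (a < 3L) {
            if (bc$lateral_kind == "no_slip")
              diag_acc[out] <- diag_acc[out] + 2 * mu
            # symmetric: mirror ghost, no contribution
          } else if (s == -1L && !press_in) {
            # plug inlet: zero tangential velocity at the inlet plane
            diag_acc[out] <- diag_acc[out] + 2 * mu
          }
          # pressure inlet: free tangential slip; outlet: developed flow
        }
      }
    }

    # Brinkman drag: face coefficient from the mean of adjacent-cell 1/kappa
    if (any(invk > 0)) {
      ik_hi <- cells_at_faces(invk, comp, side = "hi", fill = NA)
      ik_lo <- cells_at_faces(invk, comp, side = "lo", fill = NA)
      nn <- (!is.na(ik_hi)) + (!is.na(ik_lo))
      ik_hi[is.na(ik_hi)] <- 0; ik_lo[is.na(ik_lo)] <- 0
      drag <- h^2 * mu * (ik_lo + ik_hi) / pmax(nn, 1)
      diag_acc[unk] <- diag_acc[unk] + drag[unk]
    }

    push(fid[unk], fid[unk], diag_acc[unk])
    rhs[fid[unk]] <- rhs[fid[unk]] + rhs_acc[unk]

    # pressure gradient entries (Bt) and known-pressure contributions
    chi <- cells_at_faces(cid, comp, side = "hi", fill = 0L)
    clo <- cells_at_faces(cid, comp, side = "lo", fill = 0L)
    sel <- unk & chi > 0L
    if (any(sel)) pushB(fid[sel], chi[sel], rep(h, sum(sel)))
    sel <- unk & clo > 0L
    if (any(sel)) pushB(fid[sel], clo[sel], rep(-h, sum(sel)))
    if (comp == 3L) {
      if (press_in) {
        fin <- unk & clo == 0L & slice3(dims_f, 1L)
        rhs[fid[fin]] <- rhs[fid[fin]] + h * bc$inlet_value
      }
      fout <- unk & chi == 0L & slice3(dims_f, dims_f[3])
      rhs[fid[fout]] <- rhs[fid[fout]] - h * bc$outlet_pressure
    }
  }

  A <- Matrix::sparseMatrix(
    i = unlist(ti[seq_len(nt)]), j = unlist(tj[seq_len(nt)]),
    x = unlist(tx[seq_len(nt)]), dims = c(nvel, nvel)
  )
  Bt <- Matrix::sparseMatrix(
    i = unlist(bi[seq_len(nb)]), j = unlist(bj[seq_len(nb)]),
    x = unlist(bx[seq_len(nb)]), dims = c(nvel, nc)
  )

  g <- numeric(nc)
  if (!press_in && bc$inlet_value != 0) {
    bottom <- cid[, , 1]
    g[bottom[bottom > 0L]] <- h * bc$inlet_value
  }

  list(A = A, Bt = Bt, b = rhs, g = g,
       cid = cid, fids = fids, masks = list(ufl, vfl, wfl),
       h = h, mu = mu, press_in = press_in)
}

# Map a cell-centred array onto the face lattice of axis `comp`.
# side = "hi": value of the cell on the high side of each face (cell index
# equal to the face index along comp); "lo": the cell on the low side (face
# index - 1). Faces with no such cell get `fill`.
cells_at_faces <- function(cells, comp, side, fill) {
  d <- dim(cells)
  dims_f <- d; dims_f[comp] <- d[comp] + 1L
  out <- array(fill, dims_f)
  nd <- d[comp]
  src <- lapply(1:3, function(a) seq_len(d[a]))
  dst <- src
  dst[[comp]] <- if (side == "hi") seq_len(nd) else 2L:(nd + 1L)
  out[dst[[1]], dst[[2]], dst[[3]]] <- cells[src[[1]], src[[2]], src[[3]]]
  out
}

# logical array TRUE on plane k == k0 of the third axis
slice3 <- function(dims_f, k0) {
  out <- array(FALSE, dims_f)
  out[, , k0] <- TRUE
  out
}
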