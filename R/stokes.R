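#' Direct Stokes solve on a masked grid
#'
#' Assembles the creeping-flow (Stokes) limit of the same staggered-grid
#' finite-volume discretization used by [solve_steady()] — diffusion-only
#' momentum plus cell continuity, identical boundary treatment — as one
#' sparse linear system and solves it with a sparse LU factorization. This
#' is a convection-free direct solution used to validate the SIMPLE
#' iteration at low Reynolds number; it is assembled once and involves no
#' outer iteration.
#'
#' @param mask a `domain_mask`.
#' @param fluid a `fluid_properties`.
#' @param bcs a `boundary_conditions`.
#' @return A `flow_field`-shaped list (`u`, `v`, `p`, `converged = TRUE`)
#'   usable with [boundary_flux()] and friends.
#' @export
stokes_solve <- function(mask, fluid = fluid_properties(),
                         bcs = boundary_conditions()) {
  label <- mask$label
  nx <- mask$nx
  ny <- mask$ny
  h <- mask$h / 1000
  mu <- fluid$mu
  vin <- bcs$v_inlet
  isf <- label == MASK_FLUID | label >= MASK_INLET
  flu <- function(i, j) i >= 1 && i <= nx && j >= 1 && j <= ny && isf[i, j]

  # face types: 0 fixed0, 1 active, 2 outlet, 3 inlet(fixed vin)
  utype <- matrix(0L, nx + 1, ny)
  for (j in seq_len(ny)) {
    if (label[1, j] == MASK_INLET) utype[1, j] <- 3L
    if (label[nx, j] == MASK_AORTIC_OUTLET) utype[nx + 1, j] <- 2L
    for (i in 2:nx) if (isf[i - 1, j] && isf[i, j]) utype[i, j] <- 1L
  }
  vtype <- matrix(0L, nx, ny + 1)
  for (i in seq_len(nx)) {
    if (label[i, ny] == MASK_BRANCH_OUTLET) vtype[i, ny + 1] <- 2L
    for (j in 2:ny) if (isf[i, j - 1] && isf[i, j]) vtype[i, j] <- 1L
  }

  uid <- matrix(0L, nx + 1, ny)
  vid <- matrix(0L, nx, ny + 1)
  pid <- matrix(0L, nx, ny)
  nun <- 0L
  for (j in seq_len(ny)) for (i in seq_len(nx + 1)) {
    if (utype[i, j] %in% c(1L, 2L)) { nun <- nun + 1L; uid[i, j] <- nun }
  }
  for (j in seq_len(ny + 1)) for (i in seq_len(nx)) {
    if (vtype[i, j] %in% c(1L, 2L)) { nun <- nun + 1L; vid[i, j] <- nun }
  }
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    if (isf[i, j]) { nun <- nun + 1L; pid[i, j] <- nun }
  }

  ti <- integer(0); tj <- integer(0); tv <- numeric(0)
  rhs <- numeric(nun)
  add <- function(r, c, val) {
    ti[[length(ti) + 1L]] <<- r; tj[[length(tj) + 1L]] <<- c
    tv[[length(tv) + 1L]] <<- val
  }
  uval <- function(i, j) if (utype[i, j] == 3L) vin else 0  # fixed-face value

  # ---- u momentum ------------------------------------------------------
  for (j in seq_len(ny)) for (i in seq_len(nx + 1)) {
    tt <- utype[i, j]
    if (!(tt %in% c(1L, 2L))) next
    r <- uid[i, j]
    aP <- 0
    nb <- function(ii, jj, D) {
      # neighbour u face with diffusion coefficient D
      aP <<- aP + D
      if (uid[ii, jj] > 0) add(r, uid[ii, jj], -D)
      else rhs[r] <<- rhs[r] + D * uval(ii, jj)
    }
    if (tt == 1L) {
      nb(i + 1, j, mu); nb(i - 1, j, mu)
      if (j < ny) {
        both_solid <- !flu(i - 1, j + 1) && !flu(i, j + 1)
        if (both_solid) aP <- aP + 2 * mu else nb(i, j + 1, mu)
      }
      if (j == 1) aP <- aP + 2 * mu
      else {
        both_solid <- !flu(i - 1, j - 1) && !flu(i, j - 1)
        if (both_solid) aP <- aP + 2 * mu else nb(i, j - 1, mu)
      }
      add(r, pid[i - 1, j], -h); add(r, pid[i, j], h)
    } else { # outlet, i == nx + 1
      nb(i - 1, j, mu)
      if (j < ny) { if (flu(nx, j + 1)) nb(i, j + 1, mu) else aP <- aP + 2 * mu }
      if (j == 1) aP <- aP + 2 * mu
      else if (flu(nx, j - 1)) nb(i, j - 1, mu) else aP <- aP + 2 * mu
      add(r, pid[nx, j], -h)  # ghost pressure is gauge 0
    }
    add(r, r, aP)
  }

  # ---- v momentum ------------------------------------------------------
  vval <- function(i, j) 0
  for (j in seq_len(ny + 1)) for (i in seq_len(nx)) {
    tt <- vtype[i, j]
    if (!(tt %in% c(1L, 2L))) next
    r <- vid[i, j]
    aP <- 0
    nb <- function(ii, jj, D) {
      aP <<- aP + D
      if (vid[ii, jj] > 0) add(r, vid[ii, jj], -D)
    }
    if (tt == 1L) {
      nb(i, j + 1, mu); nb(i, j - 1, mu)
      if (i < nx) {
        both_solid <- !flu(i + 1, j - 1) && !flu(i + 1, j)
        if (both_solid) aP <- aP + 2 * mu else nb(i + 1, j, mu)
      }
      if (i == 1) aP <- aP + 2 * mu
      else {
        both_solid <- !flu(i - 1, j - 1) && !flu(i - 1, j)
        if (both_solid) aP <- aP + 2 * mu else nb(i - 1, j, mu)
      }
      add(r, pid[i, j - 1], -h); add(r, pid[i, j], h)
    } else { # outlet, j == ny + 1
      nb(i, j - 1, mu)
      if (i < nx) { if (flu(i + 1, ny)) nb(i + 1, j, mu) else aP <- aP + 2 * mu }
      if (i == 1) aP <- aP + 2 * mu
      else if (flu(i - 1, ny)) nb(i - 1, j, mu) else aP <- aP + 2 * mu
      add(r, pid[i, ny], -h)
    }
    add(r, r, aP)
  }

  # ---- continuity ------------------------------------------------------
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    if (!isf[i, j]) next
    r <- pid[i, j]
    faces <- list(list(uid[i + 1, j], h, utype[i + 1, j], uval(i + 1, j)),
                  list(uid[i, j], -h, utype[i, j], uval(i, j)),
                  list(vid[i, j + 1], h, vtype[i, j + 1], 0),
                  list(vid[i, j], -h, vtype[i, j], 0))
    for (f in faces) {
      if (f[[1]] > 0) add(r, f[[1]], f[[2]])
      else rhs[r] <- rhs[r] - f[[2]] * f[[4]]
    }
  }

  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tv, dims = c(nun, nun))
  sol <- as.numeric(Matrix::solve(A, rhs))

  U <- matrix(0, nx + 1, ny)
  V <- matrix(0, nx, ny + 1)
  P <- matrix(0, nx, ny)
  U[uid > 0] <- sol[uid[uid > 0]]
  U[utype == 3L] <- vin
  V[vid > 0] <- sol[vid[vid > 0]]
  P[pid > 0] <- sol[pid[pid > 0]]
  structure(list(u = U, v = V, p = P + bcs$p_outlet,
                 residual_history = NULL, converged = TRUE, iterations = 0L,
                 mask = mask, fluid = fluid, bcs = bcs, settings = NULL),
            class = "flow_field")
}
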