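#' Material model
#'
#' Plane-stress linear elastic material, isotropic or orthotropic, together
#' with the fracture toughness `G_c` used by the Griffith criterion. Defaults
#' are the corneal constants used throughout the package: stiffness
#' E = 9.82 MPa and critical energy release rate G_c = 5.40 kJ/m^2 (porcine
#' cornea at a 3 mm/min strain rate); Poisson's ratio defaults to 0.49
#' (near-incompressible soft tissue).
#'
#' @param kind `"isotropic"` or `"orthotropic"`.
#' @param E Young's modulus, Pa (isotropic).
#' @param nu Poisson ratio (isotropic), in [0, 0.5).
#' @param E_x,E_y In-plane moduli, Pa (orthotropic; `E_y` is along the
#'   vertical symmetry axis of the incision, `E_x` along the incision).
#' @param nu_xy Major Poisson ratio (orthotropic); the reciprocal ratio
#'   `nu_yx = nu_xy * E_y / E_x` is implied.
#' @param G_xy In-plane shear modulus, Pa (orthotropic).
#' @param G_c Critical energy release rate, J/m^2.
#' @return An object of class `material`.
#' @export
material <- function(kind = c("isotropic", "orthotropic"),
                     E = 9.82e6, nu = 0.49,
                     E_x = NULL, E_y = NULL, nu_xy = NULL, G_xy = NULL,
                     G_c = 5400) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(G_c), G_c > 0)
  if (kind == "isotropic") {
    stopifnot(is.numeric(E), E > 0, is.numeric(nu), nu >= 0, nu < 0.5)
    m <- list(kind = kind, E = E, nu = nu, G_c = G_c)
  } else {
    stopifnot(is.numeric(E_x), E_x > 0, is.numeric(E_y), E_y > 0,
              is.numeric(nu_xy), nu_xy >= 0, is.numeric(G_xy), G_xy > 0)
    nu_yx <- nu_xy * E_y / E_x
    if (nu_xy * nu_yx >= 1)
      stop(sprintf("orthotropic stability violated: nu_xy * nu_yx = %.3g >= 1", nu_xy * nu_yx))
    m <- list(kind = kind, E_x = E_x, E_y = E_y, nu_xy = nu_xy, nu_yx = nu_yx,
              G_xy = G_xy, G_c = G_c)
  }
  structure(m, class = "material")
}

#' Orthotropic material from a modulus ratio
#'
#' Builds the orthotropic material for an orthotropy ratio
#' `eta = E_x / E_y`, mimicking corneal fibril anisotropy: for `eta >= 1`,
#' `(E_x, E_y) = (eta * E, E)`; for `eta < 1`, `(E_x, E_y) = (E, E / eta)`.
#' The auxiliary constants not fixed by the ratio are completed as
#' `nu_xy = nu * sqrt(eta)` and
#' `G_xy = sqrt(E_x * E_y) / (2 * (1 + sqrt(nu_xy * nu_yx)))`, which reduce
#' exactly to the isotropic material at `eta = 1`.
#'
#' @param eta Orthotropy ratio `E_x / E_y`.
#' @param E Reference modulus, Pa.
#' @param nu Reference Poisson ratio.
#' @param G_c Critical energy release rate, J/m^2.
#' @return A `material` of kind `"orthotropic"` (or isotropic when `eta = 1`).
#' @export
orthotropic_material <- function(eta, E = 9.82e6, nu = 0.49, G_c = 5400) {
  stopifnot(is.numeric(eta), eta > 0)
  if (eta == 1) return(material("isotropic", E = E, nu = nu, G_c = G_c))
  if (eta >= 1) { E_x <- eta * E; E_y <- E } else { E_x <- E; E_y <- E / eta }
  nu_xy <- min(nu * sqrt(eta), 0.95 * sqrt(eta))
  nu_yx <- nu_xy * E_y / E_x
  G_xy <- sqrt(E_x * E_y) / (2 * (1 + sqrt(nu_xy * nu_yx)))
  material("orthotropic", E_x = E_x, E_y = E_y, nu_xy = nu_xy, G_xy = G_xy, G_c = G_c)
}

#' Equibiaxial load case
#'
#' Uniform outward normal traction of magnitude `sigma0` on all four outer
#' edges of the plate (the mode-I opening load of the incision model).
#'
#' @param sigma0 Traction magnitude, Pa (> 0 for the physical load; any sign
#'   is accepted for verification studies).
#' @return An object of class `load_case`.
#' @export
load_case <- function(sigma0) {
  stopifnot(is.numeric(sigma0), length(sigma0) == 1L, is.finite(sigma0))
  structure(list(sigma0 = sigma0), class = "load_case")
}

# plane-stress constitutive matrix, Voigt order (e_xx, e_yy, gamma_xy)
dmat_plane_stress <- function(mat) {
  if (mat$kind == "isotropic") {
    E <- mat$E; nu <- mat$nu
    d <- E / (1 - nu^2)
    matrix(c(d, nu * d, 0, nu * d, d, 0, 0, 0, E / (2 * (1 + nu))), 3, 3)
  } else {
    den <- 1 - mat$nu_xy * mat$nu_yx
    matrix(c(mat$E_x / den, mat$nu_xy * mat$E_y / den, 0,
             mat$nu_xy * mat$E_y / den, mat$E_y / den, 0,
             0, 0, mat$G_xy), 3, 3)
  }
}

# Q4 shape-function derivatives wrt (xi, eta) at one Gauss point: 4 x 2
q4_dshape <- function(xi, eta) {
  xa <- c(-1, 1, 1, -1); ya <- c(-1, -1, 1, 1)
  cbind(xa * (1 + ya * eta) / 4, ya * (1 + xa * xi) / 4)
}

# Per-element Cartesian shape gradients and Jacobian determinants at a Gauss
# point, vectorised over elements. X, Y: n x 4 corner coordinate matrices.
q4_gradients <- function(X, Y, xi, eta) {
  dn <- q4_dshape(xi, eta)
  J11 <- X %*% dn[, 1]; J12 <- Y %*% dn[, 1]
  J21 <- X %*% dn[, 2]; J22 <- Y %*% dn[, 2]
  det <- as.vector(J11 * J22 - J12 * J21)
  Bx <- (outer(as.vector(J22), dn[, 1]) - outer(as.vector(J12), dn[, 2])) / det
  By <- (outer(as.vector(J11), dn[, 2]) - outer(as.vector(J21), dn[, 1])) / det
  list(Bx = Bx, By = By, det = det)
}

# stiffness triplet block for one integration point: given Bx, By (n x m
# node-gradient matrices) and weight w (n vector incl. detJ), returns the
# n x (2m)^2 matrix of element stiffness entries in row-major (p,q) order.
ke_block <- function(Bx, By, w, D) {
  m <- ncol(Bx); nd <- 2L * m
  kev <- matrix(0, nrow(Bx), nd * nd)
  d11 <- D[1, 1]; d12 <- D[1, 2]; d22 <- D[2, 2]; d33 <- D[3, 3]
  for (A in seq_len(m)) for (B in seq_len(m)) {
    p1 <- 2L * A - 1L; q1 <- 2L * B - 1L
    col <- function(p, q) (p - 1L) * nd + q
    kev[, col(p1, q1)] <- kev[, col(p1, q1)] + w * (d11 * Bx[, A] * Bx[, B] + d33 * By[, A] * By[, B])
    kev[, col(p1, q1 + 1L)] <- kev[, col(p1, q1 + 1L)] + w * (d12 * Bx[, A] * By[, B] + d33 * By[, A] * Bx[, B])
    kev[, col(p1 + 1L, q1)] <- kev[, col(p1 + 1L, q1)] + w * (d12 * By[, A] * Bx[, B] + d33 * Bx[, A] * By[, B])
    kev[, col(p1 + 1L, q1 + 1L)] <- kev[, col(p1 + 1L, q1 + 1L)] + w * (d22 * By[, A] * By[, B] + d33 * Bx[, A] * Bx[, B])
  }
  kev
}

# T3 constant-strain gradients: returns Bx, By (n x 3) and areas
t3_gradients <- function(X, Y) {
  x1 <- X[, 1]; x2 <- X[, 2]; x3 <- X[, 3]
  y1 <- Y[, 1]; y2 <- Y[, 2]; y3 <- Y[, 3]
  A2 <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  list(Bx = cbind(y2 - y3, y3 - y1, y1 - y2) / A2,
       By = cbind(x3 - x2, x1 - x3, x2 - x1) / A2,
       area = A2 / 2)
}

assemble_stiffness <- function(mesh, mat) {
  D <- dmat_plane_stress(mat)
  el <- mesh$elems
  tri <- is.na(el[, 4])
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  g <- 1 / sqrt(3)
  if (any(!tri)) {
    q <- el[!tri, , drop = FALSE]
    X <- matrix(mesh$nodes[q, 1], nrow(q)); Y <- matrix(mesh$nodes[q, 2], nrow(q))
    kev <- 0
    for (gp in list(c(-g, -g), c(g, -g), c(g, g), c(-g, g))) {
      gr <- q4_gradients(X, Y, gp[1], gp[2])
      if (any(gr$det <= 0)) stop("inverted quadrilateral element in assembly")
      kev <- kev + ke_block(gr$Bx, gr$By, gr$det, D)
    }
    ed <- matrix(0L, nrow(q), 8)
    ed[, seq(1, 8, 2)] <- 2L * q - 1L; ed[, seq(2, 8, 2)] <- 2L * q
    ii <- c(ii, as.vector(ed[, rep(1:8, each = 8)]))
    jj <- c(jj, as.vector(ed[, rep(1:8, times = 8)]))
    vv <- c(vv, as.vector(kev))
  }
  if (any(tri)) {
    t3 <- el[tri, 1:3, drop = FALSE]
    X <- matrix(mesh$nodes[t3, 1], nrow(t3)); Y <- matrix(mesh$nodes[t3, 2], nrow(t3))
    gr <- t3_gradients(X, Y)
    if (any(gr$area <= 0)) stop("inverted triangular element in assembly")
    kev <- ke_block(gr$Bx, gr$By, gr$area, D)
    ed <- matrix(0L, nrow(t3), 6)
    ed[, c(1, 3, 5)] <- 2L * t3 - 1L; ed[, c(2, 4, 6)] <- 2L * t3
    ii <- c(ii, as.vector(ed[, rep(1:6, each = 6)]))
    jj <- c(jj, as.vector(ed[, rep(1:6, times = 6)]))
    vv <- c(vv, as.vector(kev))
  }
  nd <- 2L * nrow(mesh$nodes)
  Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(nd, nd))
}

# consistent nodal forces for uniform outward normal traction on the outer
# boundary
traction_forces <- function(mesh, sigma0) {
  nd <- 2L * nrow(mesh$nodes)
  f <- numeric(nd)
  nrm <- rbind(left = c(-1, 0), right = c(1, 0), bottom = c(0, -1), top = c(0, 1))
  bd <- mesh$boundary
  p1 <- mesh$nodes[bd$n1, , drop = FALSE]; p2 <- mesh$nodes[bd$n2, , drop = FALSE]
  L <- sqrt(rowSums((p2 - p1)^2))
  nvec <- nrm[bd$side, , drop = FALSE]
  for (k in seq_len(nrow(bd))) {
    fe <- sigma0 * nvec[k, ] * L[k] / 2
    d1 <- c(2L * bd$n1[k] - 1L, 2L * bd$n1[k])
    d2 <- c(2L * bd$n2[k] - 1L, 2L * bd$n2[k])
    f[d1] <- f[d1] + fe
    f[d2] <- f[d2] + fe
  }
  f
}

# default rigid-body constraints: pin the mid-left boundary node and the
# vertical component of the mid-right boundary node
default_constraints <- function(mesh) {
  W <- mesh$plate$width
  dl <- (mesh$nodes[, 1] + W / 2)^2 + mesh$nodes[, 2]^2
  dr <- (mesh$nodes[, 1] - W / 2)^2 + mesh$nodes[, 2]^2
  nl <- which.min(dl); nr <- which.min(dr)
  c(2L * nl - 1L, 2L * nl, 2L * nr)
}

#' Solve the plane-stress problem
#'
#' Assembles the linear elastic stiffness (bilinear quadrilaterals with 2x2
#' Gauss integration, constant-strain triangles at the tip fans), applies the
#' equibiaxial edge traction as consistent nodal loads, removes the three
#' planar rigid-body modes, and solves the sparse system by Cholesky
#' factorisation. Seam node pairs carry no coupling, so the crack faces are
#' free to separate.
#'
#' @param mesh A [build_mesh()] result.
#' @param mat A [material()].
#' @param load A [load_case()] or a bare traction magnitude in Pa.
#' @param fixed_dofs Optional integer vector of fixed degrees of freedom
#'   (dof `2i-1`/`2i` are the x/y displacements of node `i`); the default
#'   pins the mid-left node and the vertical motion of the mid-right node.
#' @return An object of class `plane_stress_solution`: `u` (n x 2 nodal
#'   displacements, metres), `sigma0`, `mat`, `strain_energy`,
#'   `external_work` (J per metre thickness) and `residual_rel` (relative
#'   residual of the linear solve).
#' @export
assemble_and_solve <- function(mesh, mat, load, fixed_dofs = NULL) {
  stopifnot(inherits(mesh, "crack_mesh"), inherits(mat, "material"))
  sigma0 <- if (inherits(load, "load_case")) load$sigma0 else as.numeric(load)
  K <- assemble_stiffness(mesh, mat)
  f <- traction_forces(mesh, sigma0)
  fixed <- fixed_dofs %||% default_constraints(mesh)
  if (length(fixed) < 3L)
    stop("insufficient constraints: at least the three planar rigid-body modes must be fixed")
  nd <- nrow(K)
  free <- setdiff(seq_len(nd), fixed)
  Kff <- methods::as(Matrix::forceSymmetric(K[free, free]), "CsparseMatrix")
  uf <- tryCatch(as.vector(Matrix::solve(Kff, f[free])),
                 error = function(e) stop("singular stiffness system: ", conditionMessage(e)))
  u <- numeric(nd)
  u[free] <- uf
  r <- as.vector(K %*% u - f)
  fn <- sqrt(sum(f^2))
  residual_rel <- if (fn > 0) sqrt(sum(r[free]^2)) / fn else sqrt(sum(r[free]^2))
  se <- 0.5 * sum(u * as.vector(K %*% u))
  wk <- 0.5 * sum(f * u)
  structure(list(u = matrix(u, ncol = 2, byrow = TRUE), sigma0 = sigma0, mat = mat,
                 fixed_dofs = fixed, strain_energy = se, external_work = wk,
                 residual_rel = residual_rel),
            class = "plane_stress_solution")
}

#' @export
print.plane_stress_solution <- function(x, ...) {
  cat(sprintf("<plane_stress_solution> sigma0 = %.4g MPa, strain energy %.4g J/m, residual %.2e\n",
              x$sigma0 / 1e6, x$strain_energy, x$residual_rel))
  invisible(x)
}

#' Crack opening profile
#'
#' Separation of the two incision faces: for every seam node pair, the
#' displacement jump projected on the local crack normal. The midpoint value
#' (chevron apex / arc midpoint / centre) is the quantity calibrated to the
#' injector diameter.
#'
#' @param sol A [assemble_and_solve()] result.
#' @param mesh The mesh the solution was computed on.
#' @return A list: `profile` (data frame `s`, `opening` in metres),
#'   `midpoint`, `max`, and `interpenetration` (TRUE if any separation is
#'   negative, which signals an invalid load direction since the model has
#'   no contact).
#' @export
crack_opening <- function(sol, mesh) {
  stopifnot(inherits(sol, "plane_stress_solution"), inherits(mesh, "crack_mesh"))
  if (nrow(mesh$seam) == 0L) stop("mesh has no seam (uncracked plate)")
  du <- sol$u[mesh$seam$up, , drop = FALSE] - sol$u[mesh$seam$lo, , drop = FALSE]
  opening <- du[, 1] * mesh$seam$nx + du[, 2] * mesh$seam$ny
  scale <- max(abs(opening), 1e-300)
  list(profile = data.frame(s = mesh$seam$s, opening = opening),
       midpoint = opening[mesh$midpoint_pair],
       max = max(opening),
       interpenetration = any(opening < -1e-9 * scale))
}

# per-element centroid stress (rows: s_xx, s_yy, s_xy) and von Mises scalar
element_stress <- function(mesh, sol) {
  D <- dmat_plane_stress(sol$mat)
  el <- mesh$elems
  tri <- is.na(el[, 4])
  sig <- matrix(NA_real_, nrow(el), 3)
  ux <- sol$u[, 1]; uy <- sol$u[, 2]
  if (any(!tri)) {
    q <- el[!tri, , drop = FALSE]
    X <- matrix(mesh$nodes[q, 1], nrow(q)); Y <- matrix(mesh$nodes[q, 2], nrow(q))
    gr <- q4_gradients(X, Y, 0, 0)
    UX <- matrix(ux[q], nrow(q)); UY <- matrix(uy[q], nrow(q))
    exx <- rowSums(gr$Bx * UX); eyy <- rowSums(gr$By * UY)
    gxy <- rowSums(gr$By * UX) + rowSums(gr$Bx * UY)
    sig[!tri, ] <- cbind(exx, eyy, gxy) %*% t(D)
  }
  if (any(tri)) {
    t3 <- el[tri, 1:3, drop = FALSE]
    X <- matrix(mesh$nodes[t3, 1], nrow(t3)); Y <- matrix(mesh$nodes[t3, 2], nrow(t3))
    gr <- t3_gradients(X, Y)
    UX <- matrix(ux[t3], nrow(t3)); UY <- matrix(uy[t3], nrow(t3))
    exx <- rowSums(gr$Bx * UX); eyy <- rowSums(gr$By * UY)
    gxy <- rowSums(gr$By * UX) + rowSums(gr$Bx * UY)
    sig[tri, ] <- cbind(exx, eyy, gxy) %*% t(D)
  }
  vm <- sqrt(sig[, 1]^2 - sig[, 1] * sig[, 2] + sig[, 2]^2 + 3 * sig[, 3]^2)
  list(sigma = sig, von_mises = vm)
}
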