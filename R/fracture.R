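#' Energy release rate at a crack tip
#'
#' Equivalent-domain form of the J-integral evaluated over the spider-web
#' rings around the requested tip: for ring `k`, the virtual-extension
#' function `q` is 1 on nodes inside ring `k-1` (and at the tip) and ramps to
#' 0 across ring `k`, giving
#' `J_k = sum over ring-k elements of (sigma_ij u_{i,1} - W delta_{1j}) q_{,j}`
#' in local tip coordinates with the 1-axis along the crack-extension
#' direction (the tangent at the tip, i.e. self-similar straight-ahead
#' extension). The reported `G` is the arithmetic mean of rings 4--10;
#' rings 1--3 are discarded as tip-affected.
#'
#' @param sol A [assemble_and_solve()] result.
#' @param mesh The mesh the solution was computed on.
#' @param tip `"left"` or `"right"`.
#' @return An object of class `err_result`: `per_ring_G` (J/m^2, ring 1 to
#'   `n_rings`), `G` (mean of rings 4--10), `scatter` (relative standard
#'   deviation over the averaged rings), `converged` (scatter < 2%), `tip`,
#'   and `extension_direction`.
#' @export
err_at_tip <- function(sol, mesh, tip = c("right", "left")) {
  stopifnot(inherits(sol, "plane_stress_solution"), inherits(mesh, "crack_mesh"))
  tip <- match.arg(tip)
  if (nrow(mesh$seam) == 0L)
    stop("cannot evaluate a contour integral on a merged-seam (uncracked) mesh")
  tp <- mesh$tips[[tip]]
  nr <- mesh$params$n_rings
  if (nr < 10L) stop("tip has fewer than 10 contour rings")
  D <- dmat_plane_stress(sol$mat)
  e1 <- tp$tangent / sqrt(sum(tp$tangent^2))
  e2 <- c(-e1[2], e1[1])
  R <- rbind(e1, e2)  # global -> local rotation
  level <- tp$level
  ux <- sol$u[, 1]; uy <- sol$u[, 2]
  g <- 1 / sqrt(3)

  ring_J <- numeric(nr)
  for (k in seq_len(nr)) {
    q_node <- function(ids) as.numeric(level[ids] <= k - 1L)  # levels are never NA on ring elems
    Jk <- 0
    el <- mesh$elems[tp$rings[[k]], , drop = FALSE]
    tri <- is.na(el[, 4])
    eval_gp <- function(Bx, By, wdet, idsmat) {
      # Bx, By: n x m; idsmat: n x m node ids; wdet: n weights incl. detJ
      qv <- matrix(q_node(idsmat), nrow(idsmat))
      UX <- matrix(ux[idsmat], nrow(idsmat)); UY <- matrix(uy[idsmat], nrow(idsmat))
      dqx <- rowSums(Bx * qv); dqy <- rowSums(By * qv)
      h11 <- rowSums(Bx * UX); h12 <- rowSums(By * UX)
      h21 <- rowSums(Bx * UY); h22 <- rowSums(By * UY)
      exx <- h11; eyy <- h22; gxy <- h12 + h21
      sg <- cbind(exx, eyy, gxy) %*% t(D)
      W <- 0.5 * (sg[, 1] * exx + sg[, 2] * eyy + sg[, 3] * gxy)
      # rotate to tip-local axes
      sxx <- R[1, 1]^2 * sg[, 1] + R[1, 2]^2 * sg[, 2] + 2 * R[1, 1] * R[1, 2] * sg[, 3]
      syy <- R[2, 1]^2 * sg[, 1] + R[2, 2]^2 * sg[, 2] + 2 * R[2, 1] * R[2, 2] * sg[, 3]
      sxy <- R[1, 1] * R[2, 1] * sg[, 1] + R[1, 2] * R[2, 2] * sg[, 2] +
             (R[1, 1] * R[2, 2] + R[1, 2] * R[2, 1]) * sg[, 3]
      # H' = R H R^T ; only column 1 (d/dx1') is needed
      hp11 <- R[1, 1] * (h11 * R[1, 1] + h12 * R[1, 2]) + R[1, 2] * (h21 * R[1, 1] + h22 * R[1, 2])
      hp21 <- R[2, 1] * (h11 * R[1, 1] + h12 * R[1, 2]) + R[2, 2] * (h21 * R[1, 1] + h22 * R[1, 2])
      gq1 <- R[1, 1] * dqx + R[1, 2] * dqy
      gq2 <- R[2, 1] * dqx + R[2, 2] * dqy
      integrand <- sxx * hp11 * gq1 + sxy * hp11 * gq2 +
                   sxy * hp21 * gq1 + syy * hp21 * gq2 - W * gq1
      sum(integrand * wdet)
    }
    if (any(!tri)) {
      q4 <- el[!tri, , drop = FALSE]
      X <- matrix(mesh$nodes[q4, 1], nrow(q4)); Y <- matrix(mesh$nodes[q4, 2], nrow(q4))
      for (gp in list(c(-g, -g), c(g, -g), c(g, g), c(-g, g))) {
        gr <- q4_gradients(X, Y, gp[1], gp[2])
        Jk <- Jk + eval_gp(gr$Bx, gr$By, gr$det, q4)
      }
    }
    if (any(tri)) {
      t3 <- el[tri, 1:3, drop = FALSE]
      X <- matrix(mesh$nodes[t3, 1], nrow(t3)); Y <- matrix(mesh$nodes[t3, 2], nrow(t3))
      gr <- t3_gradients(X, Y)
      Jk <- Jk + eval_gp(gr$Bx, gr$By, gr$area, t3)
    }
    ring_J[k] <- Jk
  }
  avg_rings <- 4:min(10L, nr)
  G <- mean(ring_J[avg_rings])
  scatter <- stats::sd(ring_J[avg_rings]) / abs(G)
  res <- structure(list(per_ring_G = ring_J, G = G, scatter = scatter,
                        converged = scatter < 0.02, tip = tip,
                        extension_direction = e1, avg_rings = avg_rings),
                   class = "err_result")
  if (!res$converged)
    warning(sprintf("contour integrals not converged at %s tip: ring scatter %.2f%% >= 2%%",
                    tip, 100 * scatter))
  res
}

#' @export
print.err_result <- function(x, ...) {
  cat(sprintf("<err_result> %s tip: G = %.4g kJ/m^2 (rings %d-%d, scatter %.2f%%)%s\n",
              x$tip, x$G / 1e3, min(x$avg_rings), max(x$avg_rings), 100 * x$scatter,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Griffith stability verdict
#'
#' Compares an energy release rate with the material toughness: the incision
#' is stable (no further tearing) when `G <= G_c`; the boundary case
#' `G = G_c` is classified as non-tearing.
#'
#' @param G Energy release rate, J/m^2 (scalar, >= 0), or an [err_at_tip()]
#'   result.
#' @param mat A [material()] (or a bare `G_c` value in J/m^2).
#' @return An object of class `stability_verdict`: `G`, `G_c`, `stable`.
#' @export
griffith_verdict <- function(G, mat) {
  if (inherits(G, "err_result")) G <- G$G
  stopifnot(is.numeric(G), length(G) == 1L, G >= 0)
  G_c <- if (inherits(mat, "material")) mat$G_c else as.numeric(mat)
  structure(list(G = G, G_c = G_c, stable = G <= G_c), class = "stability_verdict")
}

#' @export
print.stability_verdict <- function(x, ...) {
  cat(sprintf("<stability_verdict> G = %.4g kJ/m^2 vs G_c = %.4g kJ/m^2: %s\n",
              x$G / 1e3, x$G_c / 1e3,
              if (x$stable) "stable (no further tear)" else "UNSTABLE (tear may propagate)"))
  invisible(x)
}

#' Closed-form centre crack in an infinite plate
#'
#' Plane-stress Griffith solution for a straight crack of half-length `a`
#' under remote biaxial tension `sigma0`: stress intensity factor
#' `K_I = sigma0 * sqrt(pi * a)`, energy release rate `G = K_I^2 / E`, and
#' opening profile `delta(x) = (4 * sigma0 / E) * sqrt(a^2 - x^2)`. Serves as
#' the independent oracle for the finite-element pipeline in the large-plate
#' limit.
#'
#' @param sigma0 Remote stress, Pa.
#' @param a Crack half-length, metres.
#' @param E Young's modulus, Pa.
#' @return A list: `K_I` (Pa sqrt(m)), `G` (J/m^2), and `opening(x)`
#'   (a vectorised function of position along the crack, metres).
#' @export
analytic_center_crack <- function(sigma0, a, E) {
  stopifnot(sigma0 > 0, a > 0, E > 0)
  K_I <- sigma0 * sqrt(pi * a)
  list(K_I = K_I,
       G = K_I^2 / E,
       opening = function(x) (4 * sigma0 / E) * sqrt(pmax(a^2 - x^2, 0)))
}
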