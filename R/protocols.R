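# Internal pipeline: mesh + solve + opening + both-tip ERR for one incision
# at unit load (1 MPa), from which any load follows by linearity.
solve_unit_case <- function(shape, mat, plate, params, n_segments = 64L) {
  path <- make_crack_path(shape, n_segments)
  mesh <- build_mesh(path, plate = plate, params = params)
  sol <- assemble_and_solve(mesh, mat, load_case(1e6))
  op <- crack_opening(sol, mesh)
  eL <- err_at_tip(sol, mesh, "left")
  eR <- err_at_tip(sol, mesh, "right")
  list(path = path, mesh = mesh, sol = sol, opening = op, err_left = eL, err_right = eR)
}

#' Evaluate one incision case
#'
#' Full pipeline for a single incision: mesh, plane-stress solve, crack
#' opening, and tip energy release rates. With `sigma0 = NULL` (default) the
#' load is calibrated so the mid-incision opening equals `d_target` (the IOL
#' injector diameter); the calibration is exact by linearity of the solver.
#' The reported `G` is the maximum over the two tips (they coincide for the
#' symmetric shapes studied here).
#'
#' @param shape An [incision_shape()].
#' @param mat A [material()].
#' @param plate A [plate_spec()].
#' @param params A [mesh_params()].
#' @param d_target Target mid-incision opening, metres (default 1.73e-3).
#' @param sigma0 Applied equibiaxial stress in Pa, or `NULL` to calibrate.
#' @param n_segments Crack-path discretization passed to [make_crack_path()].
#' @return An object of class `study_record`: shape parameters, `sigma0`
#'   (applied or calibrated load, Pa), `G`, `G_left`, `G_right` (J/m^2),
#'   `scatter`, `converged`, `opening_mid`/`opening_max` (metres, at
#'   `sigma0`), `stable` (Griffith verdict), and mesh metadata.
#' @export
incision_case <- function(shape, mat = material(), plate = plate_spec(),
                          params = mesh_params(), d_target = 1.73e-3,
                          sigma0 = NULL, n_segments = 64L) {
  stopifnot(inherits(shape, "incision_shape"))
  u <- solve_unit_case(shape, mat, plate, params, n_segments)
  sigma_u <- u$sol$sigma0
  if (is.null(sigma0)) {
    if (u$opening$midpoint <= 0) stop("zero or negative opening at unit load: degenerate geometry")
    sigma0 <- sigma_u * d_target / u$opening$midpoint
  }
  sc <- (sigma0 / sigma_u)^2
  G_left <- u$err_left$G * sc
  G_right <- u$err_right$G * sc
  G <- max(G_left, G_right)
  structure(list(
    family = shape$family, length = 2 * shape$a, angle = shape$angle,
    sigma0 = sigma0, G = G, G_left = G_left, G_right = G_right,
    scatter = max(u$err_left$scatter, u$err_right$scatter),
    converged = u$err_left$converged && u$err_right$converged,
    opening_mid = u$opening$midpoint * sigma0 / sigma_u,
    opening_max = u$opening$max * sigma0 / sigma_u,
    stable = G <= mat$G_c, G_c = mat$G_c,
    n_nodes = nrow(u$mesh$nodes), n_elems = nrow(u$mesh$elems),
    unit_case = u
  ), class = "study_record")
}

#' @export
print.study_record <- function(x, ...) {
  ang <- if (is.na(x$angle)) "" else sprintf(" %g deg", x$angle)
  cat(sprintf("<study_record> %s%s 2a = %.4g mm: sigma0 = %.4g MPa, G = %.4g kJ/m^2 (%s)\n",
              x$family, ang, x$length * 1e3, x$sigma0 / 1e6, x$G / 1e3,
              if (x$stable) "stable" else "unstable"))
  invisible(x)
}

#' @export
as.data.frame.study_record <- function(x, ...) {
  data.frame(family = x$family, length = x$length, angle = x$angle,
             sigma0 = x$sigma0, G = x$G, G_left = x$G_left, G_right = x$G_right,
             scatter = x$scatter, converged = x$converged,
             opening_mid = x$opening_mid, opening_max = x$opening_max,
             stable = x$stable, n_nodes = x$n_nodes, n_elems = x$n_elems)
}

#' Calibrate the applied load to the injector opening
#'
#' Finds the equibiaxial stress at which the mid-incision opening equals the
#' target `d` (the IOL injector diameter): one solve at unit load gives the
#' opening per unit stress, the calibrated load follows exactly by linearity,
#' and a confirming solve at the calibrated load re-verifies the opening.
#'
#' @inheritParams incision_case
#' @param d_target Target opening, metres.
#' @return An object of class `calibration_result`: `sigma0_star` (Pa),
#'   `d_target`, `achieved_opening` (from the confirming solve).
#' @export
calibrate_load <- function(shape, mat = material(), plate = plate_spec(),
                           params = mesh_params(), d_target = 1.73e-3) {
  stopifnot(d_target > 0)
  u <- solve_unit_case(shape, mat, plate, params)
  if (u$opening$midpoint <= 0) stop("zero or negative opening at unit load: degenerate geometry")
  sigma0_star <- u$sol$sigma0 * d_target / u$opening$midpoint
  conf <- assemble_and_solve(u$mesh, mat, load_case(sigma0_star))
  achieved <- crack_opening(conf, u$mesh)$midpoint
  if (abs(achieved - d_target) / d_target >= 1e-6)
    warning(sprintf("calibration verification off by %.2e relative", abs(achieved - d_target) / d_target))
  structure(list(sigma0_star = sigma0_star, d_target = d_target,
                 achieved_opening = achieved, shape = shape),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> %s: sigma0* = %.4g MPa for opening %.4g mm (achieved %.6g mm)\n",
              x$shape$family, x$sigma0_star / 1e6, x$d_target * 1e3, x$achieved_opening * 1e3))
  invisible(x)
}

# shared sweep driver: evaluates calibrated records over an angle grid with
# optional 1-degree refinement around the detected minimum
run_sweep <- function(family, angles, length, mat, plate, params, d_target,
                      refine, refine_radius, angle_bounds) {
  one <- function(ang) {
    rec <- tryCatch(
      incision_case(incision_shape(family, length = length, angle = ang),
                    mat = mat, plate = plate, params = params, d_target = d_target),
      error = function(e) {
        warning(sprintf("%s angle %g: %s", family, ang, conditionMessage(e)))
        NULL
      })
    if (is.null(rec)) return(NULL)
    rec$unit_case <- NULL
    as.data.frame(rec)
  }
  recs <- do.call(rbind, lapply(angles, one))
  if (refine && nrow(recs) > 1L) {
    amin <- recs$angle[which.min(recs$G)]
    cand <- setdiff(seq(max(angle_bounds[1], amin - refine_radius),
                        min(angle_bounds[2], amin + refine_radius), by = 1),
                    recs$angle)
    if (length(cand)) recs <- rbind(recs, do.call(rbind, lapply(cand, one)))
  }
  recs <- recs[order(recs$angle), , drop = FALSE]
  rownames(recs) <- NULL
  recs
}

# linear interpolation of the angle where G crosses G_c; `above_low = TRUE`
# means G >= G_c on the low-angle side of the crossing
gc_crossing <- function(angle, G, G_c) {
  dG <- G - G_c
  sgn <- sign(dG)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (!length(idx)) {
    if (any(dG == 0)) return(angle[which(dG == 0)[1]])
    return(NA_real_)
  }
  i <- idx[1]
  angle[i] + (angle[i + 1] - angle[i]) * (0 - dG[i]) / (dG[i + 1] - dG[i])
}

#' Chevron angle sweep
#'
#' Energy release rate of chevron incisions over a grid of arm angles at
#' fixed incision length, each case at its own load calibrated to the target
#' mid-incision opening. The default grid spans the clinically reported range
#' 120--180 degrees in 5-degree steps, with 1-degree refinement around the
#' detected minimum.
#'
#' @param alphas Arm angles in degrees (within `[120, 180]`).
#' @param length Incision length `2a`, metres.
#' @inheritParams incision_case
#' @param refine Refine the grid to 1-degree spacing near the minimum.
#' @return An object of class `incision_sweep`: `records` (one row per
#'   angle), `argmin` / `G_min`, and `crossing` (the angle where G crosses
#'   `G_c`, by linear interpolation; G exceeds `G_c` on the small-angle side).
#' @export
sweep_chevron <- function(alphas = seq(120, 180, by = 5), length = 2.2e-3,
                          mat = material(), plate = plate_spec(),
                          params = mesh_params(), d_target = 1.73e-3,
                          refine = TRUE) {
  stopifnot(all(alphas >= 120 & alphas <= 180))
  recs <- run_sweep("chevron", alphas, length, mat, plate, params, d_target,
                    refine, 4, c(120, 180))
  structure(list(family = "chevron", records = recs,
                 argmin = recs$angle[which.min(recs$G)], G_min = min(recs$G),
                 crossing = gc_crossing(recs$angle, recs$G, mat$G_c),
                 G_c = mat$G_c, d_target = d_target, length = length),
            class = "incision_sweep")
}

#' Frown central-angle sweep
#'
#' As [sweep_chevron()], over the central angle of the frown arc (default
#' 5--50 degrees in 5-degree steps, refined to 1-degree spacing near the
#' minimum; the arc degenerates to the straight incision as the angle goes
#' to zero).
#'
#' @param betas Central angles in degrees (within `(0, 50]`).
#' @inheritParams sweep_chevron
#' @return An `incision_sweep`; its `crossing` is the central angle where G
#'   crosses `G_c` (G below `G_c` on the small-angle side).
#' @export
sweep_frown <- function(betas = seq(5, 50, by = 5), length = 2.2e-3,
                        mat = material(), plate = plate_spec(),
                        params = mesh_params(), d_target = 1.73e-3,
                        refine = TRUE) {
  stopifnot(all(betas > 0 & betas <= 50))
  recs <- run_sweep("frown", betas, length, mat, plate, params, d_target,
                    refine, 3, c(1, 50))
  structure(list(family = "frown", records = recs,
                 argmin = recs$angle[which.min(recs$G)], G_min = min(recs$G),
                 crossing = gc_crossing(recs$angle, recs$G, mat$G_c),
                 G_c = mat$G_c, d_target = d_target, length = length),
            class = "incision_sweep")
}

#' @export
print.incision_sweep <- function(x, ...) {
  cat(sprintf("<incision_sweep> %s, %d angles: min G = %.4g kJ/m^2 at %g deg; G_c crossing at %s deg\n",
              x$family, nrow(x$records), x$G_min / 1e3, x$argmin,
              if (is.na(x$crossing)) "none" else sprintf("%.3g", x$crossing)))
  invisible(x)
}

#' @export
plot.incision_sweep <- function(x, ...) {
  graphics::plot(x$records$angle, x$records$G / 1e3, type = "b", pch = 16,
                 xlab = sprintf("%s angle [deg]", x$family),
                 ylab = "G [kJ/m^2]", ...)
  graphics::abline(h = x$G_c / 1e3, lty = 2)
  graphics::legend("topright", c("G", "G_c"), lty = c(1, 2), pch = c(16, NA), bty = "n")
  invisible(x)
}

#' Critical incision length
#'
#' The incision length `2a*` at which the energy release rate under the
#' calibrated load equals the toughness `G_c`. Since the opening is held at
#' the injector diameter, G decreases with incision length (for the straight
#' incision, `G = pi*E*d^2/(16*a)` in closed form), so incisions shorter than
#' `2a*` tear. Solved by root bracketing with a full remesh and recalibration
#' at every iterate.
#'
#' @param family `"straight"`, `"chevron"` or `"frown"`.
#' @param angle Shape angle in degrees (ignored for straight).
#' @inheritParams incision_case
#' @param bracket Optional length interval `c(lo, hi)` in metres straddling
#'   the root; the default is derived from the near-inverse scaling of G with
#'   length.
#' @param tol Root tolerance on `2a*`, metres.
#' @return An object of class `critical_length_result`: `length_crit`
#'   (`2a*`, metres), `G_at_crit` (re-evaluated, J/m^2), `bracket`, `tol`.
#' @export
critical_length <- function(family, angle = NA, mat = material(),
                            plate = plate_spec(), params = mesh_params(),
                            d_target = 1.73e-3, bracket = NULL, tol = 1e-6) {
  g_of <- function(L) {
    sh <- if (family == "straight") incision_shape("straight", length = L)
          else incision_shape(family, length = L, angle = angle)
    rec <- incision_case(sh, mat = mat, plate = plate, params = params,
                         d_target = d_target)
    rec$G
  }
  if (is.null(bracket)) {
    L0 <- 2.2e-3
    G0 <- g_of(L0)
    Lp <- L0 * G0 / mat$G_c        # G * L is nearly constant at fixed opening
    bracket <- Lp * c(0.85, 1.2)
  }
  flo <- g_of(bracket[1]) - mat$G_c
  fhi <- g_of(bracket[2]) - mat$G_c
  if (flo * fhi > 0)
    stop(sprintf("bracket [%.4g, %.4g] mm does not straddle G_c (G - G_c: %.3g, %.3g)",
                 bracket[1] * 1e3, bracket[2] * 1e3, flo, fhi))
  root <- stats::uniroot(function(L) g_of(L) - mat$G_c, interval = bracket,
                         f.lower = flo, f.upper = fhi, tol = tol)
  Gv <- root$f.root + mat$G_c
  structure(list(family = family, angle = angle, length_crit = root$root,
                 G_at_crit = Gv, G_c = mat$G_c, bracket = bracket, tol = tol,
                 iterations = root$iter, d_target = d_target),
            class = "critical_length_result")
}

#' @export
print.critical_length_result <- function(x, ...) {
  ang <- if (is.na(x$angle)) "" else sprintf(" %g deg", x$angle)
  cat(sprintf("<critical_length_result> %s%s: 2a* = %.4g mm (G there %.4g kJ/m^2, G_c %.4g)\n",
              x$family, ang, x$length_crit * 1e3, x$G_at_crit / 1e3, x$G_c / 1e3))
  invisible(x)
}

#' Orthotropy table
#'
#' Energy release rate of chevron incisions across orthotropy ratios
#' `eta = E_x / E_y` and arm angles, each cell at its own calibrated load;
#' mirrors the material-anisotropy study of corneal fibril organisation.
#' Materials come from [orthotropic_material()]; `eta = 1` reduces exactly to
#' the isotropic sweep entries.
#'
#' @param etas Orthotropy ratios.
#' @param alphas Chevron arm angles, degrees (180 is the straight incision).
#' @inheritParams sweep_chevron
#' @param E,nu,G_c Reference isotropic constants passed to
#'   [orthotropic_material()].
#' @return An object of class `orthotropy_table`: `records` (long format),
#'   `G` (matrix, rows = etas, cols = alphas, J/m^2), and `argmin_eta` (per
#'   angle, the ratio minimising G).
#' @export
orthotropy_table <- function(etas = c(2, 1.5, 1, 0.75, 0.5),
                             alphas = c(165, 170, 175, 180),
                             length = 2.2e-3, plate = plate_spec(),
                             params = mesh_params(), d_target = 1.73e-3,
                             E = 9.82e6, nu = 0.49, G_c = 5400) {
  recs <- list()
  G <- matrix(NA_real_, length(etas), length(alphas),
              dimnames = list(eta = as.character(etas), alpha = as.character(alphas)))
  for (i in seq_along(etas)) {
    mat <- orthotropic_material(etas[i], E = E, nu = nu, G_c = G_c)
    for (j in seq_along(alphas)) {
      rec <- incision_case(incision_shape("chevron", length = length, angle = alphas[j]),
                           mat = mat, plate = plate, params = params, d_target = d_target)
      rec$unit_case <- NULL
      df <- as.data.frame(rec)
      df$eta <- etas[i]
      df$E_x <- if (mat$kind == "isotropic") mat$E else mat$E_x
      df$E_y <- if (mat$kind == "isotropic") mat$E else mat$E_y
      recs[[length(recs) + 1L]] <- df
      G[i, j] <- rec$G
    }
  }
  records <- do.call(rbind, recs)
  argmin_eta <- etas[apply(G, 2, which.min)]
  names(argmin_eta) <- colnames(G)
  structure(list(records = records, G = G, etas = etas, alphas = alphas,
                 argmin_eta = argmin_eta, G_c = G_c, d_target = d_target),
            class = "orthotropy_table")
}

#' @export
print.orthotropy_table <- function(x, ...) {
  cat("<orthotropy_table> G [kJ/m^2], rows eta = E_x/E_y, cols chevron angle:\n")
  print(round(x$G / 1e3, 3))
  cat("argmin eta per angle:", paste(sprintf("%s: %g", names(x$argmin_eta), x$argmin_eta),
                                     collapse = ", "), "\n")
  invisible(x)
}

#' Compare incision shapes
#'
#' Percent change in energy release rate of the best chevron and the best
#' frown (restricted to central angles up to `beta_max`) relative to the
#' straight incision of the same length, computed as
#' `(G_straight - G_shape) / G_straight * 100` (positive = improvement).
#'
#' @param chevron A [sweep_chevron()] result (must include 180 degrees for
#'   the straight baseline, or supply `straight_G`).
#' @param frown A [sweep_frown()] result.
#' @param beta_max Frown angles above this are excluded from "best frown".
#' @param straight_G Optional straight-incision G, J/m^2; default is the
#'   180-degree chevron entry.
#' @return An object of class `shape_comparison`.
#' @export
compare_shapes <- function(chevron, frown, beta_max = 20, straight_G = NULL) {
  stopifnot(inherits(chevron, "incision_sweep"), inherits(frown, "incision_sweep"))
  if (is.null(straight_G)) {
    i180 <- which(chevron$records$angle == 180)
    if (!length(i180)) stop("chevron sweep lacks the 180-degree (straight) entry; supply straight_G")
    straight_G <- chevron$records$G[i180[1]]
  }
  ic <- which.min(chevron$records$G)
  fr <- frown$records[frown$records$angle <= beta_max, , drop = FALSE]
  if (!nrow(fr)) stop("no frown entries at or below beta_max")
  jf <- which.min(fr$G)
  pct <- function(G) (straight_G - G) / straight_G * 100
  structure(list(
    straight_G = straight_G,
    best_chevron = list(angle = chevron$records$angle[ic], G = chevron$records$G[ic],
                        improvement_pct = pct(chevron$records$G[ic])),
    best_frown = list(angle = fr$angle[jf], G = fr$G[jf],
                      improvement_pct = pct(fr$G[jf]), beta_max = beta_max)
  ), class = "shape_comparison")
}

#' @export
print.shape_comparison <- function(x, ...) {
  cat(sprintf("<shape_comparison> straight G = %.4g kJ/m^2\n", x$straight_G / 1e3))
  cat(sprintf("  best chevron: %g deg, G = %.4g kJ/m^2, improvement %+.2f%%\n",
              x$best_chevron$angle, x$best_chevron$G / 1e3, x$best_chevron$improvement_pct))
  cat(sprintf("  best frown (beta <= %g deg): %g deg, G = %.4g kJ/m^2, improvement %+.2f%%\n",
              x$best_frown$beta_max, x$best_frown$angle, x$best_frown$G / 1e3,
              x$best_frown$improvement_pct))
  invisible(x)
}
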