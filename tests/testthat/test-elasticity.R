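test_that("uncracked plate under equibiaxial tension reproduces the homogeneous state", {
  fx <- straight_fast()
  um <- merge_seam(fx$mesh)
  sigma0 <- 1e6; nu <- 0.49; E <- 9.82e6
  sol <- assemble_and_solve(um, material(E = E, nu = nu), load_case(sigma0))
  # exact solution u = sigma0 (1 - nu)/E * x up to the rigid-body gauge
  uex <- um$nodes * (sigma0 * (1 - nu) / E)
  fixn <- (sol$fixed_dofs[1] + 1) %/% 2
  shift <- sol$u[fixn, ] - uex[fixn, ]
  err <- max(abs(sweep(sol$u, 2, shift) - uex))
  expect_lt(err / max(abs(uex)), 1e-10)
  # constant stress field, von Mises = sigma0 for the equibiaxial state
  es <- sicsfract:::element_stress(um, sol)
  expect_lt(max(abs(es$sigma[, 1] - sigma0)) / sigma0, 1e-9)
  expect_lt(max(abs(es$sigma[, 2] - sigma0)) / sigma0, 1e-9)
  expect_lt(max(abs(es$sigma[, 3])) / sigma0, 1e-9)
  expect_lt(max(abs(es$von_mises - sigma0)) / sigma0, 1e-9)
})

test_that("solutions are linear in the load and energetically consistent", {
  fx <- straight_fast()
  sol1 <- fx$sol
  sol2 <- assemble_and_solve(fx$mesh, material(), load_case(2e6))
  expect_equal(sol2$u, 2 * sol1$u, tolerance = 1e-10)
  expect_lt(sol1$residual_rel, 1e-9)
  # total strain energy equals external work (1/2 t.u integrated on the edges)
  expect_equal(sol1$strain_energy, sol1$external_work, tolerance = 1e-9)
  expect_equal(sol2$strain_energy, 4 * sol1$strain_energy, tolerance = 1e-10)
})

test_that("straight-crack opening matches the infinite-plate closed form", {
  fx <- straight_fast()
  a <- 1.1e-3; E <- 9.82e6; sigma0 <- 1e6
  op <- fx$opening
  delta <- analytic_center_crack(sigma0, a, E)$opening
  # midpoint: delta(0) = 4 sigma0 a / E, within 2% (finite plate + mesh)
  expect_equal(op$midpoint, 4 * sigma0 * a / E, tolerance = 0.02)
  expect_equal(op$midpoint, op$max)
  # elliptical profile at stations away from the tips, within 3%
  for (sf in c(0, 0.15, 0.3, 0.45, 0.6)) {
    i <- which.min(abs(op$profile$s - sf * a))
    expect_equal(op$profile$opening[i], delta(op$profile$s[i]), tolerance = 0.03)
  }
  expect_false(op$interpenetration)
})

test_that("zero load opens nothing and compression is flagged as interpenetration", {
  fx <- straight_fast()
  sol0 <- assemble_and_solve(fx$mesh, material(), load_case(0))
  expect_lt(max(abs(sol0$u)), 1e-15)
  op0 <- crack_opening(sol0, fx$mesh)
  expect_equal(max(abs(op0$profile$opening)), 0)
  expect_false(op0$interpenetration)
  solc <- assemble_and_solve(fx$mesh, material(), load_case(-1e6))
  expect_true(crack_opening(solc, fx$mesh)$interpenetration)
})

test_that("displacement field has the mirror symmetry of the problem", {
  for (fx in list(straight_fast(), chevron150_fast())) {
    mesh <- fx$mesh; u <- fx$sol$u
    key <- function(x, y) paste(signif(x, 10), signif(y, 10))
    idx <- new.env()
    for (i in seq_len(nrow(mesh$nodes)))
      assign(key(mesh$nodes[i, 1], mesh$nodes[i, 2]), i, envir = idx)
    # sample off-seam nodes and compare with their mirror images
    samp <- seq(1, nrow(mesh$nodes), by = 23)
    seam_ids <- c(mesh$seam$up, mesh$seam$lo)
    samp <- setdiff(samp, seam_ids)
    uref <- max(abs(u))
    sx <- numeric(0); dy <- numeric(0)
    for (i in samp) {
      k <- key(-mesh$nodes[i, 1], mesh$nodes[i, 2])
      if (!exists(k, envir = idx)) next
      j <- get(k, envir = idx)
      if (j %in% seam_ids) next
      sx <- c(sx, u[j, 1] + u[i, 1])   # constant gauge shift under mirroring
      dy <- c(dy, u[j, 2] - u[i, 2])   # exactly zero for the symmetric field
    }
    expect_gt(length(sx), 20L)
    expect_lt(max(abs(sx - mean(sx))) / uref, 1e-6)
    expect_lt(max(abs(dy)) / uref, 1e-6)
  }
})

test_that("chevron opening profile is asymmetric about the arm midpoints", {
  fx <- chevron150_fast()
  pr <- fx$opening$profile
  a <- fx$mesh$a
  # compare stations symmetric about the right arm midpoint s = a/2
  i1 <- which.min(abs(pr$s - 0.25 * a))
  i2 <- which.min(abs(pr$s - 0.75 * a))
  asym <- abs(pr$opening[i1] - pr$opening[i2]) / max(pr$opening)
  expect_gt(asym, 0.01)
})

test_that("orthotropic materials are validated and reduce correctly", {
  expect_error(material("orthotropic", E_x = 1e6, E_y = 1e6, nu_xy = 1.1, G_xy = 4e5),
               "stability")
  m <- orthotropic_material(1)
  expect_identical(m$kind, "isotropic")
  m2 <- orthotropic_material(2, E = 9.82e6)
  expect_equal(m2$E_x / m2$E_y, 2)
  expect_equal(m2$E_x, 19.64e6)
  # isotropic D recovered from the orthotropic formula at eta = 1
  Diso <- sicsfract:::dmat_plane_stress(material())
  mo <- material("orthotropic", E_x = 9.82e6, E_y = 9.82e6, nu_xy = 0.49,
                 G_xy = 9.82e6 / (2 * 1.49))
  expect_equal(sicsfract:::dmat_plane_stress(mo), Diso, tolerance = 1e-12)
})

test_that("an unconstrained system is reported as singular", {
  fx <- straight_fast()
  expect_error(assemble_and_solve(fx$mesh, material(), load_case(1e6),
                                  fixed_dofs = integer(0)), "constraint")
})
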