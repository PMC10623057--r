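test_that("load calibration hits the target opening exactly and scales linearly", {
  sh <- incision_shape("straight")
  cal <- calibrate_load(sh, params = fast_params())
  # achieved opening from the confirming solve
  expect_equal(cal$achieved_opening, cal$d_target, tolerance = 1e-9)
  # sigma* ~ E d / (4 a) within 2% (finite plate + discretization)
  expect_equal(cal$sigma0_star, 9.82e6 * 1.73e-3 / (4 * 1.1e-3), tolerance = 0.02)
  rec1 <- incision_case(sh, params = fast_params(), d_target = 1.73e-3)
  rec2 <- incision_case(sh, params = fast_params(), d_target = 2 * 1.73e-3)
  expect_equal(rec2$sigma0, 2 * rec1$sigma0, tolerance = 1e-12)
  expect_equal(rec2$G, 4 * rec1$G, tolerance = 1e-12)
  expect_equal(rec1$opening_mid, 1.73e-3, tolerance = 1e-12)
})

test_that("a case at a prescribed load skips calibration and reports the verdict", {
  rec <- incision_case(incision_shape("chevron", angle = 150),
                       params = fast_params(), sigma0 = 3.95e6)
  expect_equal(rec$sigma0, 3.95e6)
  expect_equal(rec$G, max(rec$G_left, rec$G_right))
  expect_identical(rec$stable, rec$G <= rec$G_c)
  expect_true(rec$converged)
})

test_that("the 180-degree chevron sweep entry equals the straight incision", {
  rs <- incision_case(incision_shape("straight"), params = fast_params())
  rc <- incision_case(incision_shape("chevron", angle = 180), params = fast_params())
  expect_equal(rc$G, rs$G, tolerance = 1e-9)
  expect_equal(rc$sigma0, rs$sigma0, tolerance = 1e-9)
  # frown beta -> 0 converges to the straight entry
  rf <- incision_case(incision_shape("frown", angle = 1), params = fast_params())
  expect_equal(rf$G, rs$G, tolerance = 5e-3)
})

test_that("sweeps return ordered calibrated records with argmin and crossing", {
  sw <- sweep_chevron(c(150, 165, 180), params = fast_params(), refine = FALSE)
  expect_identical(nrow(sw$records), 3L)
  expect_true(all(diff(sw$records$angle) > 0))
  expect_equal(sw$G_min, min(sw$records$G))
  expect_identical(sw$argmin, sw$records$angle[which.min(sw$records$G)])
  expect_true(all(abs(sw$records$opening_mid - 1.73e-3) < 1e-12))
  # smoothness: G varies by < 5% between adjacent 1-degree points near 180
  sw1 <- sweep_chevron(c(177, 178, 179, 180), params = fast_params(), refine = FALSE)
  expect_true(all(abs(diff(sw1$records$G)) / sw1$records$G[-1] < 0.05))
  # crossing interpolation: exact on synthetic data
  expect_equal(sicsfract:::gc_crossing(c(160, 170, 180), c(5500, 5350, 5300), 5400),
               160 + 10 * (5500 - 5400) / (5500 - 5350))
  expect_true(is.na(sicsfract:::gc_crossing(c(170, 180), c(5500, 5600), 5400)))
})

test_that("frown sweep honours its angle domain", {
  expect_error(sweep_frown(c(10, 60), params = fast_params()), "betas")
  sw <- sweep_frown(c(10, 30), params = fast_params(), refine = FALSE)
  expect_identical(nrow(sw$records), 2L)
  expect_true(all(sw$records$converged))
})

test_that("critical incision length matches the closed-form straight prediction", {
  # G(2a) = pi E d^2 / (16 a) at calibrated opening => 2a* = pi E d^2 / (8 G_c)
  L_pred <- pi * 9.82e6 * (1.73e-3)^2 / (8 * 5400)
  expect_equal(L_pred, 2.1373e-3, tolerance = 1e-4)
  cl <- critical_length("straight", params = fast_params(),
                        bracket = c(1.8e-3, 2.6e-3))
  expect_equal(cl$length_crit, L_pred, tolerance = 0.03)
  # root invariants: G at the root equals G_c within 1%, and G decreases in a
  expect_lt(abs(cl$G_at_crit - cl$G_c) / cl$G_c, 0.01)
  rec_longer <- incision_case(incision_shape("straight", length = 1.1 * cl$length_crit),
                              params = fast_params())
  expect_lt(rec_longer$G, cl$G_c)
  expect_error(critical_length("straight", params = fast_params(),
                               bracket = c(2.4e-3, 2.6e-3)), "straddle")
})

test_that("orthotropy table reduces to the isotropic sweep at eta = 1 and is minimal there", {
  ot <- orthotropy_table(etas = c(1.5, 1, 0.75), alphas = c(170, 180),
                         params = fast_params())
  iso <- incision_case(incision_shape("chevron", angle = 170), params = fast_params())
  expect_equal(unname(ot$G["1", "170"]), iso$G, tolerance = 1e-9)
  for (al in c("170", "180")) {
    expect_identical(unname(ot$argmin_eta[al]), 1)
    expect_gt(ot$G["1.5", al], ot$G["1", al])
    expect_gt(ot$G["0.75", al], ot$G["1", al])
  }
  # eta < 1 mapping keeps the printed-modulus convention E_x = E
  r075 <- ot$records[ot$records$eta == 0.75, ][1, ]
  expect_equal(r075$E_x, 9.82e6)
  expect_equal(r075$E_y, 9.82e6 / 0.75)
})

test_that("shape comparison reports percent improvement relative to straight", {
  chev <- sweep_chevron(c(170, 180), params = fast_params(), refine = FALSE)
  fr <- sweep_frown(c(5, 10), params = fast_params(), refine = FALSE)
  cmp <- compare_shapes(chev, fr, beta_max = 20)
  i180 <- which(chev$records$angle == 180)
  expect_equal(cmp$straight_G, chev$records$G[i180])
  expect_equal(cmp$best_chevron$improvement_pct,
               (cmp$straight_G - cmp$best_chevron$G) / cmp$straight_G * 100)
  # identical shape compared with itself improves by exactly 0%
  chev180 <- sweep_chevron(c(180), params = fast_params(), refine = FALSE)
  cmp0 <- compare_shapes(chev180, fr, beta_max = 20)
  expect_equal(cmp0$best_chevron$improvement_pct, 0)
  expect_error(compare_shapes(chev180, fr, beta_max = 2), "beta_max")
})
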