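test_that("seamed meshes satisfy the structural invariants for all families", {
  for (fx in list(straight_fast(), chevron150_fast(), frown35_fast())) {
    mesh <- fx$mesh
    # seam pairs: distinct node ids, coincident reference coordinates
    expect_true(all(mesh$seam$up != mesh$seam$lo))
    expect_lt(max(abs(mesh$nodes[mesh$seam$up, ] - mesh$nodes[mesh$seam$lo, ])), 1e-12)
    # seam stations ordered along the incision, midpoint at s = 0
    expect_true(all(diff(mesh$seam$s) > 0))
    expect_lt(abs(mesh$seam$s[mesh$midpoint_pair]), 1e-12)
    # seam vertices lie exactly on the parametric path
    onpath <- sicsfract:::path_point(mesh$shape, mesh$seam$s)
    expect_lt(max(abs(mesh$nodes[mesh$seam$up, ] - onpath)), 1e-12)
    # all element Jacobians positive
    expect_gt(min(sicsfract:::element_corner_jacobians(mesh)), 0)
    # no element references both faces of a seam pair
    el <- mesh$elems
    for (i in seq_len(nrow(mesh$seam))) {
      rows <- which(rowSums(el == mesh$seam$up[i], na.rm = TRUE) > 0)
      expect_false(any(el[rows, ] == mesh$seam$lo[i], na.rm = TRUE))
    }
    areas <- element_areas(mesh)
    expect_true(all(areas > 0))
    for (nm in c("left", "right")) {
      tp <- mesh$tips[[nm]]
      # ring 1 is a fan: every element contains the tip node
      r1 <- el[tp$rings[[1]], , drop = FALSE]
      expect_true(all(apply(r1, 1, function(r) tp$node %in% r)))
      expect_true(all(is.na(r1[, 4])))  # triangles
      # rings are disjoint element sets with equal population
      ring_ids <- unlist(tp$rings)
      expect_identical(anyDuplicated(ring_ids), 0L)
      expect_equal(unname(lengths(tp$rings)), rep(mesh$params$n_spokes, mesh$params$n_rings))
      # quadrilateral annulus areas strictly increase outward (nesting);
      # the ring-1 fan is a disc, larger than the first annulus whenever
      # ring_growth < sqrt(2), so it is excluded from the monotonicity check
      ring_area <- vapply(tp$rings, function(ix) sum(areas[ix]), 0)
      expect_true(all(ring_area > 0))
      expect_true(all(diff(ring_area[-1]) > 0))
      # tip node coincides with the analytic tip
      expect_equal(unname(mesh$nodes[tp$node, ]), unname(tp$point), tolerance = 1e-12)
    }
  }
})

test_that("boundary edges tile the plate outline", {
  mesh <- straight_fast()$mesh
  W <- mesh$plate$width; H <- mesh$plate$height
  bd <- mesh$boundary
  xy1 <- mesh$nodes[bd$n1, , drop = FALSE]
  on_line <- function(v, target) all(abs(v - target) < 1e-12)
  expect_true(on_line(xy1[bd$side == "left", 1], -W / 2))
  expect_true(on_line(xy1[bd$side == "right", 1], W / 2))
  expect_true(on_line(xy1[bd$side == "bottom", 2], -H / 2))
  expect_true(on_line(xy1[bd$side == "top", 2], H / 2))
  L <- sqrt(rowSums((mesh$nodes[bd$n2, , drop = FALSE] - xy1)^2))
  expect_equal(sum(L), 2 * (W + H), tolerance = 1e-12)
})

test_that("infeasible ring systems and oversized incisions are rejected", {
  sh <- incision_shape("straight")
  path <- make_crack_path(sh)
  expect_error(build_mesh(path, params = mesh_params(r_inner = sh$a / 10)),
               "too large")
  expect_error(suppressWarnings(build_mesh(path, plate = plate_spec(0.0026, 0.0026))),
               "fit the plate")
  expect_warning(build_mesh(path, plate = plate_spec(0.010, 0.010),
                            params = fast_params()), "20%")
})

test_that("snapping is idempotent on a well-formed mesh", {
  fx <- frown35_fast()
  expect_identical(snap_seam_nodes(fx$mesh, fx$path), fx$mesh)
})

test_that("stray nodes near the path are projected onto it", {
  fx <- frown35_fast()
  mesh <- fx$mesh
  # displace an off-path node to 5e-9 m from the arc, between seam stations
  target_s <- 0.31 * mesh$a
  nrm <- sicsfract:::path_normal(mesh$shape, target_s)
  # base point on the snapping polyline itself (its chordal sagitta off the
  # true arc is larger than the displacement being tested)
  v0 <- fx$path$vertices
  k <- findInterval(target_s, fx$path$s)
  p_arc <- sicsfract:::path_point(mesh$shape, target_s)
  dseg <- v0[k + 1L, ] - v0[k, ]
  tt <- sum((p_arc - v0[k, ]) * dseg) / sum(dseg^2)
  p_on <- v0[k, ] + tt * dseg
  seam_ids <- c(mesh$seam$up, mesh$seam$lo, mesh$tips$left$node, mesh$tips$right$node)
  d2 <- rowSums((mesh$nodes - matrix(p_on, nrow(mesh$nodes), 2, byrow = TRUE))^2)
  d2[seam_ids] <- Inf
  id <- which.min(d2)
  mesh$nodes[id, ] <- p_on + 5e-9 * nrm
  snapped <- snap_seam_nodes(mesh, fx$path)
  # node now lies on the path polyline (within its chordal sagitta)
  v <- fx$path$vertices
  seg_d <- vapply(seq_len(nrow(v) - 1L), function(k) {
    a1 <- v[k, ]; dseg <- v[k + 1L, ] - a1
    t <- min(max(sum((snapped$nodes[id, ] - a1) * dseg) / sum(dseg^2), 0), 1)
    sqrt(sum((snapped$nodes[id, ] - a1 - t * dseg)^2))
  }, 0)
  expect_lt(min(seg_d), 1e-14)
})

test_that("near-coincident duplicate nodes are merged without losing elements", {
  fx <- straight_fast()
  mesh <- fx$mesh
  n0 <- nrow(mesh$nodes); e0 <- nrow(mesh$elems)
  # fabricate a generation artifact: duplicate one interior non-seam node and
  # re-point part of its element star to the duplicate
  seam_ids <- c(mesh$seam$up, mesh$seam$lo, mesh$tips$left$node, mesh$tips$right$node)
  cand <- setdiff(unique(as.vector(mesh$elems[mesh$ring_tag == 0, ])), seam_ids)
  cand <- cand[!is.na(cand)]
  id <- cand[100]
  dup <- n0 + 1L
  mesh$nodes <- rbind(mesh$nodes, mesh$nodes[id, , drop = FALSE])
  for (nm in c("left", "right"))
    mesh$tips[[nm]]$level <- c(mesh$tips[[nm]]$level, NA_integer_)
  star <- which(rowSums(mesh$elems == id, na.rm = TRUE) > 0)
  half <- star[seq_len(ceiling(length(star) / 2))]
  mesh$elems[half, ][mesh$elems[half, ] == id] <- dup
  merged <- snap_seam_nodes(mesh, fx$path)
  expect_equal(nrow(merged$nodes), n0)
  expect_equal(nrow(merged$elems), e0)
  expect_identical(merged$elems, fx$mesh$elems)
  # Euler characteristic restored to the original mesh's
  euler <- function(m) {
    el <- m$elems
    edges <- function(r) {
      r <- r[!is.na(r)]
      k <- length(r)
      t(vapply(seq_len(k), function(j) sort(c(r[j], r[j %% k + 1L])), integer(2)))
    }
    E <- unique(do.call(rbind, lapply(seq_len(nrow(el)), function(i) edges(el[i, ]))))
    nrow(m$nodes) - nrow(E) + nrow(el)
  }
  expect_identical(euler(merged), euler(fx$mesh))
})

test_that("merging the seam recovers the intact plate", {
  fx <- straight_fast()
  um <- merge_seam(fx$mesh)
  expect_identical(nrow(um$seam), 0L)
  expect_equal(nrow(um$nodes), nrow(fx$mesh$nodes) - nrow(fx$mesh$seam))
  expect_equal(nrow(um$elems), nrow(fx$mesh$elems))
  expect_gt(min(sicsfract:::element_corner_jacobians(um)), 0)
})
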