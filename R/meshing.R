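`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mesh generation parameters
#'
#' Controls the spider-web crack-tip discretization and the far-field grid.
#' Ring radii follow a geometric progression `r_k = r_inner * ring_growth^(k-1)`
#' for `k = 1..n_rings`; ring 1 is a triangle fan on the tip node, rings 2+
#' are quadrilateral annuli, and each ring doubles as one contour-integral
#' domain.
#'
#' @param n_rings Number of contour rings per tip (>= 10; rings 4--10 are the
#'   ones averaged for the reported energy release rate).
#' @param r_inner Radius of ring 1 in metres; `NULL` (default) resolves to
#'   `a/150` for incision half-length `a`.
#' @param ring_growth Geometric ratio of successive ring radii, in (1, 2].
#' @param n_spokes Circumferential element count per ring; a multiple of 8
#'   (the web is stitched to a square patch boundary).
#' @param far_field_size Target element size away from the incision in metres;
#'   `NULL` resolves to a tenth of the plate width.
#' @param grade_ratio Geometric growth ratio of element size from the incision
#'   region out to the far field.
#' @return An object of class `mesh_params`.
#' @export
mesh_params <- function(n_rings = 10L, r_inner = NULL, ring_growth = 1.30,
                        n_spokes = 24L, far_field_size = NULL, grade_ratio = 1.18) {
  n_rings <- as.integer(n_rings)
  n_spokes <- as.integer(n_spokes)
  if (n_rings < 10L) stop("n_rings must be >= 10 (rings 4-10 are averaged)")
  if (!(ring_growth > 1 && ring_growth <= 2)) stop("ring_growth must lie in (1, 2]")
  if (n_spokes < 8L || n_spokes %% 8L != 0L) stop("n_spokes must be a multiple of 8")
  if (!is.null(r_inner) && (!is.numeric(r_inner) || r_inner <= 0))
    stop("r_inner must be positive or NULL")
  if (!is.null(far_field_size) && (!is.numeric(far_field_size) || far_field_size <= 0))
    stop("far_field_size must be positive or NULL")
  if (!(grade_ratio > 1 && grade_ratio <= 2)) stop("grade_ratio must lie in (1, 2]")
  structure(list(n_rings = n_rings, r_inner = r_inner, ring_growth = ring_growth,
                 n_spokes = n_spokes, far_field_size = far_field_size,
                 grade_ratio = grade_ratio),
            class = "mesh_params")
}

# Monotone breakpoints from `from` to `to`, first interval ~ h0 growing by
# `ratio` up to `hmax`, rescaled so the last break lands exactly on `to`.
# Returns the interior breaks plus `to` (excludes `from`).
graded_breaks <- function(from, to, h0, ratio = 1.45, hmax = Inf) {
  L <- to - from
  stopifnot(L > 0, h0 > 0)
  h <- h0; pos <- 0; iv <- numeric(0)
  while (pos < L - 1e-15 * L) {
    iv <- c(iv, h); pos <- pos + h; h <- min(h * ratio, hmax)
  }
  iv <- iv * (L / sum(iv))
  out <- from + cumsum(iv)
  out[length(out)] <- to
  out
}

# Square-patch perimeter template for the web-to-grid transition: n_spokes+1
# points on the boundary of the square [-1,1]^2, counter-clockwise from
# (-1, 0) (the crack face behind the tip) back to (-1, 0); first and last
# entries are the lower/upper crack-face pair.
square_perimeter <- function(n_spokes) {
  m <- n_spokes / 8
  way <- rbind(c(-1, 0), c(-1, -1), c(1, -1), c(1, 1), c(-1, 1), c(-1, 0))
  counts <- c(m, 2 * m, 2 * m, 2 * m, m)
  pts <- way[1, , drop = FALSE]
  for (leg in seq_len(5)) {
    tloc <- seq_len(counts[leg]) / counts[leg]
    seg <- outer(1 - tloc, way[leg, ]) + outer(tloc, way[leg + 1, ])
    pts <- rbind(pts, seg)
  }
  pts
}

# cosine taper: 1 for v <= lo, 0 for v >= hi
taper <- function(v, lo, hi) {
  t <- pmin(pmax((v - lo) / (hi - lo), 0), 1)
  cos(pi * t / 2)^2
}

#' Build a seamed crack mesh with spider-web tip rings
#'
#' Generates a conforming plane mesh of the plate containing the incision as a
#' seam: node pairs along the crack path are duplicated (coincident in the
#' reference configuration) so the two faces can separate, with each tip kept
#' as a single node surrounded by `n_rings` nested contour rings (a triangle
#' fan, then quadrilateral annuli) stitched to a graded rectilinear far-field
#' grid.
#'
#' The mesh is first built for a straight reference incision and then carried
#' onto the chevron/frown path by a smooth in-plane map that is exact on the
#' seam (reference arclength stations land exactly on the parametric path)
#' and the identity near the plate boundary.
#'
#' @param path A [make_crack_path()] result.
#' @param plate A [plate_spec()].
#' @param params A [mesh_params()].
#' @return An object of class `crack_mesh` with fields `nodes` (n x 2 matrix,
#'   metres), `elems` (integer matrix, 4-node rows; triangles carry `NA` in
#'   column 4), `seam` (data frame: arclength `s`, `up`/`lo` node ids, local
#'   crack normal `nx`,`ny`), `midpoint_pair` (row index into `seam`), `tips`
#'   (per-tip node id, location, extension direction, ring element lists and
#'   node ring levels), `boundary` (outer edge node pairs with side tags),
#'   `ring_tag`/`tip_tag` per element, plus the generating `shape`, `plate`
#'   and `params`.
#' @export
build_mesh <- function(path, plate = plate_spec(), params = mesh_params()) {
  stopifnot(inherits(path, "crack_path"), inherits(plate, "plate_spec"),
            inherits(params, "mesh_params"))
  shape <- path$shape
  a <- shape$a
  W <- plate$width; H <- plate$height
  nr <- params$n_rings; ns <- params$n_spokes
  r_inner <- params$r_inner %||% (a / 150)
  rr <- r_inner * params$ring_growth^(0:(nr - 1L))
  r_out <- rr[nr]
  b <- 1.5 * r_out
  if (b > 0.7 * a)
    stop(sprintf(paste0("tip ring system too large for the incision: outer ring radius ",
                        "%.3g m (patch half-width %.3g m) vs half-length a = %.3g m; ",
                        "reduce r_inner, ring_growth or n_rings"), r_out, b, a))
  if (a + b > 0.45 * W || b > 0.45 * H)
    stop(sprintf("incision plus tip rings (extent %.3g x %.3g m) does not fit the plate %.3g x %.3g m",
                 2 * (a + b), 2 * b, W, H))
  if (chord_span(shape) / W >= 0.2)
    warning("incision chord exceeds 20% of the plate width; the large-plate assumption is degraded")
  ff <- params$far_field_size %||% (W / 10)
  tol <- 1e-9 * max(W, H)

  ## rectilinear grid lines (reference configuration: straight crack on y = 0)
  m <- ns %/% 8L                 # grid divisions per patch half-side
  h_patch <- b / m
  xpR <- a + seq(-b, b, length.out = 2L * m + 1L)
  inner_half <- a - b
  n_mid <- 2L * max(1L, ceiling(inner_half / h_patch))
  xmid <- seq(-inner_half, inner_half, length.out = n_mid + 1L)
  xout <- graded_breaks(a + b, W / 2, h0 = h_patch, ratio = params$grade_ratio, hmax = ff)
  xs <- sort(c(-rev(xpR), xpR, xmid[-c(1L, n_mid + 1L)], xout, -xout))
  yout <- graded_breaks(b, H / 2, h0 = h_patch, ratio = params$grade_ratio, hmax = ff)
  ys <- sort(c(seq(-b, b, length.out = 2L * m + 1L), yout, -yout))
  nx <- length(xs); ny <- length(ys)

  ## classify lattice points
  X <- matrix(xs, nx, ny); Y <- matrix(ys, nx, ny, byrow = TRUE)
  in_patch <- (abs(abs(X) - a) < b - tol) & (abs(Y) < b - tol)
  on_crack <- (abs(Y) < tol) & (abs(X) <= inner_half + tol)

  IDup <- matrix(NA_integer_, nx, ny)
  IDlo <- matrix(NA_integer_, nx, ny)
  norm_idx <- which(!in_patch & !on_crack)
  IDup[norm_idx] <- seq_along(norm_idx)
  IDlo[norm_idx] <- IDup[norm_idx]
  count <- length(norm_idx)
  crk <- which(on_crack & !in_patch)
  IDup[crk] <- count + seq_along(crk)
  IDlo[crk] <- count + length(crk) + seq_along(crk)
  count <- count + 2L * length(crk)

  node_xy <- matrix(NA_real_, count, 2L)
  node_xy[IDup[norm_idx], ] <- cbind(X[norm_idx], Y[norm_idx])
  node_xy[IDup[crk], ] <- cbind(X[crk], Y[crk])
  node_xy[IDlo[crk], ] <- cbind(X[crk], Y[crk])

  ## grid cells (skip the two tip patch squares)
  ii <- rep(seq_len(nx - 1L), ny - 1L)
  jj <- rep(seq_len(ny - 1L), each = nx - 1L)
  xc <- (xs[ii] + xs[ii + 1L]) / 2
  yc <- (ys[jj] + ys[jj + 1L]) / 2
  keep <- !((abs(abs(xc) - a) < b) & (abs(yc) < b))
  ii <- ii[keep]; jj <- jj[keep]
  grid_quads <- cbind(IDup[cbind(ii, jj)],
                      IDup[cbind(ii + 1L, jj)],
                      IDlo[cbind(ii + 1L, jj + 1L)],
                      IDlo[cbind(ii, jj + 1L)])
  stopifnot(!anyNA(grid_quads))

  elems <- list(grid_quads)
  tags_ring <- list(rep(0L, nrow(grid_quads)))
  tags_tip <- list(rep(0L, nrow(grid_quads)))

  ## tip patches
  qperim <- square_perimeter(ns)           # (ns+1) x 2, half-width 1
  dir <- qperim / sqrt(rowSums(qperim^2))  # spoke unit directions
  extra <- 2L * (1L + nr * (ns + 1L))      # tip node + ring nodes per tip
  node_xy <- rbind(node_xy, matrix(NA_real_, extra, 2L))
  tips <- list()
  seam_rows <- list(data.frame(s = X[crk], up = IDup[crk], lo = IDlo[crk]))

  for (side in c(-1, 1)) {
    tip_x <- side * a
    M <- c(side, 1)  # mirror in x for the left tip
    tip_id <- count + 1L
    node_xy[tip_id, ] <- c(tip_x, 0)
    count <- count + 1L
    Rid <- matrix(NA_integer_, nr, ns + 1L)
    for (k in seq_len(nr)) {
      Rid[k, ] <- count + seq_len(ns + 1L)
      node_xy[Rid[k, ], ] <- cbind(tip_x + rr[k] * M[1] * dir[, 1],
                                   rr[k] * M[2] * dir[, 2])
      count <- count + ns + 1L
    }
    ## square boundary node ids come from the grid
    gq <- cbind(tip_x + b * M[1] * qperim[, 1], b * M[2] * qperim[, 2])
    ixm <- vapply(gq[, 1], function(v) which.min(abs(xs - v)), integer(1))
    iym <- vapply(gq[, 2], function(v) which.min(abs(ys - v)), integer(1))
    stopifnot(all(abs(xs[ixm] - gq[, 1]) < tol), all(abs(ys[iym] - gq[, 2]) < tol))
    SQ <- IDup[cbind(ixm, iym)]
    SQ[1L] <- IDlo[ixm[1L], iym[1L]]          # lower crack face
    SQ[ns + 1L] <- IDup[ixm[ns + 1L], iym[ns + 1L]]  # upper crack face
    stopifnot(!anyNA(SQ))

    fan <- cbind(tip_id, Rid[1L, seq_len(ns)], Rid[1L, seq_len(ns) + 1L], NA_integer_)
    ring_quads <- vector("list", nr - 1L)
    for (k in 2:nr)
      ring_quads[[k - 1L]] <- cbind(Rid[k - 1L, seq_len(ns)], Rid[k, seq_len(ns)],
                                    Rid[k, seq_len(ns) + 1L], Rid[k - 1L, seq_len(ns) + 1L])
    trans <- cbind(Rid[nr, seq_len(ns)], SQ[seq_len(ns)],
                   SQ[seq_len(ns) + 1L], Rid[nr, seq_len(ns) + 1L])
    patch_el <- rbind(fan, do.call(rbind, ring_quads), trans)
    if (side < 0) {  # mirrored patch: restore counter-clockwise orientation
      patch_el <- cbind(patch_el[, 1L], patch_el[, 4L], patch_el[, 3L], patch_el[, 2L])
      tri <- is.na(patch_el[, 2L])
      patch_el[tri, 2L] <- patch_el[tri, 3L]
      patch_el[tri, 3L] <- patch_el[tri, 4L]
      patch_el[tri, 4L] <- NA_integer_
    }
    elems[[length(elems) + 1L]] <- patch_el
    tags_ring[[length(tags_ring) + 1L]] <-
      c(rep(1L, ns), rep(2:nr, each = ns), rep(nr + 1L, ns))
    tags_tip[[length(tags_tip) + 1L]] <- rep(if (side < 0) 1L else 2L, nrow(patch_el))

    ## crack-face seam pairs on the patch spokes (s measured pre-map = arclength)
    seam_rows[[length(seam_rows) + 1L]] <-
      data.frame(s = side * (a - rr), up = Rid[, ns + 1L], lo = Rid[, 1L])

    tips[[if (side < 0) "left" else "right"]] <-
      list(node = tip_id, Rid = Rid, nr = nr)
  }

  node_xy <- node_xy[seq_len(count), , drop = FALSE]
  elems <- do.call(rbind, elems)
  dimnames(elems) <- NULL
  ring_tag <- unlist(tags_ring)
  tip_tag <- unlist(tags_tip)

  ## per-tip ring element registry and node ring levels
  el_off <- 0L
  for (nm in c("left", "right")) {
    tt <- if (nm == "left") 1L else 2L
    idx <- which(tip_tag == tt)
    rings <- lapply(seq_len(nr), function(k) idx[ring_tag[idx] == k])
    level <- rep(NA_integer_, count)
    level[tips[[nm]]$node] <- 0L
    for (k in seq_len(nr)) level[tips[[nm]]$Rid[k, ]] <- k
    tips[[nm]]$rings <- rings
    tips[[nm]]$level <- level
    tips[[nm]]$Rid <- NULL
  }
  tips$left$point <- path$tip_left;  tips$left$tangent <- path$tip_tangents["left", ]
  tips$right$point <- path$tip_right; tips$right$tangent <- path$tip_tangents["right", ]

  ## seam table ordered by arclength
  seam <- do.call(rbind, seam_rows)
  seam <- seam[order(seam$s), , drop = FALSE]
  rownames(seam) <- NULL
  nrm <- path_normal(shape, seam$s)
  seam$nx <- nrm[, 1]; seam$ny <- nrm[, 2]
  midpoint_pair <- which.min(abs(seam$s))

  ## outer boundary edges (node pairs + side tag)
  boundary <- rbind(
    data.frame(n1 = IDup[cbind(1L, seq_len(ny - 1L))],
               n2 = IDup[cbind(1L, seq_len(ny - 1L) + 1L)], side = "left"),
    data.frame(n1 = IDup[cbind(nx, seq_len(ny - 1L))],
               n2 = IDup[cbind(nx, seq_len(ny - 1L) + 1L)], side = "right"),
    data.frame(n1 = IDup[cbind(seq_len(nx - 1L), 1L)],
               n2 = IDup[cbind(seq_len(nx - 1L) + 1L, 1L)], side = "bottom"),
    data.frame(n1 = IDup[cbind(seq_len(nx - 1L), ny)],
               n2 = IDup[cbind(seq_len(nx - 1L) + 1L, ny)], side = "top"))

  ## shape map: carry the straight reference mesh onto the chevron/frown path
  if (shape$family != "straight") {
    x0 <- a + 2 * b; x1 <- min(0.85 * W / 2, max(8 * a, 2.5 * x0))
    y0 <- 2 * b;     y1 <- min(0.85 * H / 2, max(8 * a, 5 * y0))
    w <- taper(abs(node_xy[, 1]), x0, x1) * taper(abs(node_xy[, 2]), y0, y1)
    D <- path_point_ext(shape, node_xy[, 1]) - cbind(node_xy[, 1], 0)
    node_xy <- node_xy + w * D
  }

  mesh <- structure(list(
    nodes = node_xy, elems = elems, ring_tag = ring_tag, tip_tag = tip_tag,
    seam = seam, midpoint_pair = midpoint_pair, tips = tips,
    boundary = boundary, shape = shape, plate = plate, params = params,
    a = a, b = b, ring_radii = rr
  ), class = "crack_mesh")

  bad <- count_nonpositive_jacobians(mesh)
  if (bad > 0L)
    stop(sprintf("mesh generation produced %d element(s) with non-positive Jacobian", bad))
  mesh
}

#' @export
print.crack_mesh <- function(x, ...) {
  cat(sprintf("<crack_mesh> %s 2a = %.4g mm: %d nodes, %d elements (%d tri), %d seam pairs, %d rings/tip\n",
              x$shape$family, 2 * x$a * 1e3, nrow(x$nodes), nrow(x$elems),
              sum(is.na(x$elems[, 4])), nrow(x$seam), x$params$n_rings))
  invisible(x)
}

# Signed corner areas: minimum cross product over element corners; used as
# the positive-Jacobian check (for bilinear quads positivity at all four
# corners implies positivity throughout).
element_corner_jacobians <- function(mesh) {
  el <- mesh$elems; xy <- mesh$nodes
  out <- numeric(nrow(el))
  tri <- is.na(el[, 4])
  if (any(tri)) {
    p1 <- xy[el[tri, 1], , drop = FALSE]
    p2 <- xy[el[tri, 2], , drop = FALSE]
    p3 <- xy[el[tri, 3], , drop = FALSE]
    out[tri] <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
                (p2[, 2] - p1[, 2]) * (p3[, 1] - p1[, 1])
  }
  if (any(!tri)) {
    q <- el[!tri, , drop = FALSE]
    cr <- matrix(Inf, nrow(q), 4)
    for (k in 1:4) {
      pk <- xy[q[, k], , drop = FALSE]
      pn <- xy[q[, k %% 4 + 1], , drop = FALSE]
      pp <- xy[q[, (k + 2) %% 4 + 1], , drop = FALSE]
      cr[, k] <- (pn[, 1] - pk[, 1]) * (pp[, 2] - pk[, 2]) -
                 (pn[, 2] - pk[, 2]) * (pp[, 1] - pk[, 1])
    }
    out[!tri] <- apply(cr, 1, min)
  }
  out
}

count_nonpositive_jacobians <- function(mesh) sum(element_corner_jacobians(mesh) <= 0)

#' Element areas
#'
#' Polygon (shoelace) area of every element, in square metres.
#'
#' @param mesh A [build_mesh()] result.
#' @return Numeric vector, one entry per element.
#' @export
element_areas <- function(mesh) {
  el <- mesh$elems; xy <- mesh$nodes
  area <- numeric(nrow(el))
  tri <- is.na(el[, 4])
  poly_area <- function(ids) {
    px <- matrix(xy[ids, 1], nrow(ids)); py <- matrix(xy[ids, 2], nrow(ids))
    n <- ncol(px); s <- 0
    for (k in seq_len(n)) {
      k2 <- k %% n + 1
      s <- s + px[, k] * py[, k2] - px[, k2] * py[, k]
    }
    s / 2
  }
  if (any(tri)) area[tri] <- poly_area(el[tri, 1:3, drop = FALSE])
  if (any(!tri)) area[!tri] <- poly_area(el[!tri, , drop = FALSE])
  area
}

# Renumber nodes after a merge: `map` is old id -> new (possibly shared) old
# id; compacts node storage and updates every id-bearing field.
renumber_mesh <- function(mesh, map) {
  keep <- sort(unique(map))
  newid <- integer(nrow(mesh$nodes))
  newid[keep] <- seq_along(keep)
  remap <- function(v) ifelse(is.na(v), NA_integer_, newid[map[v]])
  mesh$nodes <- mesh$nodes[keep, , drop = FALSE]
  mesh$elems <- matrix(remap(mesh$elems), ncol = 4)
  mesh$seam$up <- remap(mesh$seam$up); mesh$seam$lo <- remap(mesh$seam$lo)
  mesh$boundary$n1 <- remap(mesh$boundary$n1); mesh$boundary$n2 <- remap(mesh$boundary$n2)
  for (nm in c("left", "right")) {
    mesh$tips[[nm]]$node <- remap(mesh$tips[[nm]]$node)
    lv <- rep(NA_integer_, length(keep))
    old_lv <- mesh$tips[[nm]]$level
    src <- which(!is.na(old_lv))
    lv[newid[map[src]]] <- old_lv[src]
    mesh$tips[[nm]]$level <- lv
  }
  dup <- apply(mesh$elems, 1, function(r) anyDuplicated(r[!is.na(r)]) > 0)
  if (any(dup)) stop(sprintf("node merge collapsed %d element(s)", sum(dup)))
  mesh
}

#' Snap and de-duplicate mesh nodes near the crack path
#'
#' Housekeeping pass after mesh generation: nodes lying within `snap_tol` of
#' the incision path are projected onto it, and distinct non-seam nodes closer
#' than `merge_tol` are merged into one. A well-formed mesh is returned
#' unchanged (the operation is idempotent).
#'
#' @param mesh A [build_mesh()] result.
#' @param path The [make_crack_path()] the mesh was built for.
#' @param snap_tol Projection tolerance in metres.
#' @param merge_tol Merge tolerance in metres.
#' @return The cleaned `crack_mesh`.
#' @export
snap_seam_nodes <- function(mesh, path, snap_tol = 1e-8, merge_tol = 1e-10) {
  stopifnot(inherits(mesh, "crack_mesh"), inherits(path, "crack_path"))
  xy <- mesh$nodes
  seam_ids <- c(mesh$seam$up, mesh$seam$lo, mesh$tips$left$node, mesh$tips$right$node)

  ## project near-path stragglers onto the path polyline
  v <- path$vertices
  nseg <- nrow(v) - 1L
  cand <- setdiff(which(
    xy[, 1] >= min(v[, 1]) - snap_tol & xy[, 1] <= max(v[, 1]) + snap_tol &
    xy[, 2] >= min(v[, 2]) - snap_tol & xy[, 2] <= max(v[, 2]) + snap_tol), seam_ids)
  for (id in cand) {
    p <- xy[id, ]; best <- c(Inf, NA, NA)
    for (sg in seq_len(nseg)) {
      a1 <- v[sg, ]; d <- v[sg + 1L, ] - a1
      t <- sum((p - a1) * d) / sum(d * d)
      t <- min(max(t, 0), 1)
      q <- a1 + t * d
      dd <- sum((p - q)^2)
      if (dd < best[1]) best <- c(dd, q)
    }
    if (best[1] > 0 && sqrt(best[1]) <= snap_tol) xy[id, ] <- best[2:3]
  }
  mesh$nodes <- xy

  ## merge near-coincident non-seam nodes
  n <- nrow(xy)
  map <- seq_len(n)
  ord <- order(xy[, 1], xy[, 2])
  is_seam <- logical(n); is_seam[seam_ids] <- TRUE
  for (k in seq_len(n - 1L)) {
    i <- ord[k]; m <- k + 1L
    while (m <= n && xy[ord[m], 1] - xy[i, 1] <= merge_tol) {
      j <- ord[m]
      if (!(is_seam[i] && is_seam[j]) && map[i] != map[j] &&
          abs(xy[j, 2] - xy[i, 2]) <= merge_tol &&
          sqrt(sum((xy[j, ] - xy[i, ])^2)) <= merge_tol) {
        tgt <- min(map[i], map[j]); src <- max(map[i], map[j])
        map[map == src] <- tgt
      }
      m <- m + 1L
    }
  }
  if (all(map == seq_len(n))) return(mesh)
  renumber_mesh(mesh, map)
}

#' Merge the seam: the uncracked plate
#'
#' Collapses every seam node pair to a single node, producing the intact
#' (uncracked) plate on the same discretization; used for patch tests and as
#' the reference state.
#'
#' @param mesh A [build_mesh()] result.
#' @return A `crack_mesh` whose seam table is empty.
#' @export
merge_seam <- function(mesh) {
  stopifnot(inherits(mesh, "crack_mesh"))
  map <- seq_len(nrow(mesh$nodes))
  map[mesh$seam$lo] <- mesh$seam$up
  mesh <- renumber_mesh(mesh, map)
  mesh$seam <- mesh$seam[0, , drop = FALSE]
  mesh$midpoint_pair <- NA_integer_
  mesh
}
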