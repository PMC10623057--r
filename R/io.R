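# Config schema: nested key-value file with explicit units in the key names.
# Physical quantities are converted to SI on load; defaults are the corneal
# study constants (2a = 2.2 mm, d = 1.73 mm, E = 9.82 MPa, G_c = 5.40 kJ/m^2,
# 60 mm plate).
config_schema <- list(
  protocol = c("case", "calibrate", "sweep_chevron", "sweep_frown",
               "critical_length", "orthotropy_table", "compare"),
  plate = c("width_mm", "height_mm"),
  incision = c("family", "length_mm", "angle_deg"),
  material = c("E_MPa", "nu", "Gc_kJ_m2", "eta"),
  mesh = c("n_rings", "r_inner_mm", "ring_growth", "n_spokes",
           "far_field_mm", "grade_ratio"),
  load = c("d_target_mm", "sigma0_MPa"),
  sweep = c("alphas_deg", "betas_deg", "refine", "beta_max_deg"),
  orthotropy = c("etas", "alphas_deg"),
  output_dir = NULL, allow_unconverged = NULL, export = c("vtk", "figures"))

validate_config <- function(cfg) {
  bad <- setdiff(names(cfg), names(config_schema))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (sec in names(cfg)) {
    keys <- config_schema[[sec]]
    if (is.null(keys) || sec == "protocol") next
    if (!is.list(cfg[[sec]])) stop(sprintf("config section '%s' must be a mapping", sec))
    badk <- setdiff(names(cfg[[sec]]), keys)
    if (length(badk))
      stop(sprintf("unknown config key(s) under '%s': %s", sec, paste(badk, collapse = ", ")))
  }
  if (!is.null(cfg$protocol) && !cfg$protocol %in% config_schema$protocol)
    stop(sprintf("unknown protocol '%s' (expected one of: %s)", cfg$protocol,
                 paste(config_schema$protocol, collapse = ", ")))
  invisible(cfg)
}

#' Read a study configuration
#'
#' Loads and validates the key-value (YAML) configuration driving
#' [run_study()]. Unknown keys are rejected by name; quantities carry their
#' units in the key (`*_mm`, `*_MPa`, `Gc_kJ_m2`) and are converted to SI.
#'
#' @param path Path to the YAML config file.
#' @return An object of class `study_config`: the parsed SI-unit pieces
#'   (`plate`, `shape`, `mat`, `params`, `d_target`, `sigma0`, grids and
#'   output options).
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  g <- function(sec, key, default = NULL) {
    v <- cfg[[sec]][[key]]
    if (is.null(v)) default else v
  }
  plate <- plate_spec(width = g("plate", "width_mm", 60) * 1e-3,
                      height = g("plate", "height_mm", 60) * 1e-3)
  family <- g("incision", "family", "straight")
  shape <- incision_shape(family,
                          length = g("incision", "length_mm", 2.2) * 1e-3,
                          angle = g("incision", "angle_deg"))
  eta <- g("material", "eta", 1)
  E <- g("material", "E_MPa", 9.82) * 1e6
  nu <- g("material", "nu", 0.49)
  G_c <- g("material", "Gc_kJ_m2", 5.40) * 1e3
  mat <- orthotropic_material(eta, E = E, nu = nu, G_c = G_c)
  ri <- g("mesh", "r_inner_mm")
  ffs <- g("mesh", "far_field_mm")
  params <- mesh_params(n_rings = g("mesh", "n_rings", 10L),
                        r_inner = if (!is.null(ri)) ri * 1e-3,
                        ring_growth = g("mesh", "ring_growth", 1.30),
                        n_spokes = g("mesh", "n_spokes", 24L),
                        far_field_size = if (!is.null(ffs)) ffs * 1e-3,
                        grade_ratio = g("mesh", "grade_ratio", 1.18))
  sig <- g("load", "sigma0_MPa")
  structure(list(
    protocol = cfg$protocol %||% "case",
    plate = plate, shape = shape, mat = mat, params = params,
    E = E, nu = nu, G_c = G_c,
    d_target = g("load", "d_target_mm", 1.73) * 1e-3,
    sigma0 = if (!is.null(sig)) sig * 1e6,
    alphas = g("sweep", "alphas_deg", seq(120, 180, by = 5)),
    betas = g("sweep", "betas_deg", seq(5, 50, by = 5)),
    refine = isTRUE(g("sweep", "refine", TRUE)),
    beta_max = g("sweep", "beta_max_deg", 20),
    etas = g("orthotropy", "etas", c(2, 1.5, 1, 0.75, 0.5)),
    ortho_alphas = g("orthotropy", "alphas_deg", c(165, 170, 175, 180)),
    output_dir = cfg$output_dir %||% "incision-study-output",
    allow_unconverged = isTRUE(cfg$allow_unconverged),
    export_vtk = isTRUE(g("export", "vtk", FALSE)),
    export_figures = isTRUE(g("export", "figures", TRUE))
  ), class = "study_config")
}

write_csv_plain <- function(df, path) {
  utils::write.csv(format(df, digits = 12, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  path
}

#' Run a configured study
#'
#' Executes the protocol selected in a config file (single case, load
#' calibration, chevron/frown sweeps, critical-length inversion, orthotropy
#' table, or the three-way shape comparison), writing CSV tables, a JSON
#' summary, and a manifest with convergence diagnostics into the output
#' directory. The pipeline is fully deterministic: rerunning the same config
#' reproduces the outputs byte for byte.
#'
#' @param config Path to a YAML config file or a [read_study_config()] result.
#' @param output_dir Overrides the config's output directory.
#' @return The protocol result object, invisibly; artifacts on disk.
#' @export
run_study <- function(config, output_dir = NULL) {
  cf <- if (inherits(config, "study_config")) config else read_study_config(config)
  out <- output_dir %||% cf$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  summarise <- list(protocol = cf$protocol)
  res <- switch(cf$protocol,
    case = {
      rec <- incision_case(cf$shape, mat = cf$mat, plate = cf$plate, params = cf$params,
                           d_target = cf$d_target, sigma0 = cf$sigma0)
      write_csv_plain(as.data.frame(rec), file.path(out, "case.csv"))
      if (cf$export_vtk)
        export_vtk(rec$unit_case$mesh, rec$unit_case$sol, file.path(out, "case.vtk"))
      summarise$G_kJ_m2 <- rec$G / 1e3
      summarise$sigma0_MPa <- rec$sigma0 / 1e6
      summarise$stable <- rec$stable
      rec
    },
    calibrate = {
      cal <- calibrate_load(cf$shape, mat = cf$mat, plate = cf$plate,
                            params = cf$params, d_target = cf$d_target)
      summarise$sigma0_star_MPa <- cal$sigma0_star / 1e6
      cal
    },
    sweep_chevron = {
      sw <- sweep_chevron(cf$alphas, length = 2 * cf$shape$a, mat = cf$mat,
                          plate = cf$plate, params = cf$params,
                          d_target = cf$d_target, refine = cf$refine)
      write_csv_plain(sw$records, file.path(out, "sweep_chevron.csv"))
      if (cf$export_figures) sweep_figure(sw, file.path(out, "sweep_chevron.pdf"))
      summarise$argmin_deg <- sw$argmin
      summarise$G_min_kJ_m2 <- sw$G_min / 1e3
      summarise$crossing_deg <- sw$crossing
      sw
    },
    sweep_frown = {
      sw <- sweep_frown(cf$betas, length = 2 * cf$shape$a, mat = cf$mat,
                        plate = cf$plate, params = cf$params,
                        d_target = cf$d_target, refine = cf$refine)
      write_csv_plain(sw$records, file.path(out, "sweep_frown.csv"))
      if (cf$export_figures) sweep_figure(sw, file.path(out, "sweep_frown.pdf"))
      summarise$argmin_deg <- sw$argmin
      summarise$G_min_kJ_m2 <- sw$G_min / 1e3
      summarise$crossing_deg <- sw$crossing
      sw
    },
    critical_length = {
      cl <- critical_length(cf$shape$family, cf$shape$angle, mat = cf$mat,
                            plate = cf$plate, params = cf$params,
                            d_target = cf$d_target)
      summarise$length_crit_mm <- cl$length_crit * 1e3
      cl
    },
    orthotropy_table = {
      ot <- orthotropy_table(cf$etas, cf$ortho_alphas, length = 2 * cf$shape$a,
                             plate = cf$plate, params = cf$params,
                             d_target = cf$d_target, E = cf$E, nu = cf$nu,
                             G_c = cf$G_c)
      write_csv_plain(ot$records, file.path(out, "orthotropy_table.csv"))
      summarise$argmin_eta <- as.list(ot$argmin_eta)
      ot
    },
    compare = {
      chev <- sweep_chevron(cf$alphas, length = 2 * cf$shape$a, mat = cf$mat,
                            plate = cf$plate, params = cf$params,
                            d_target = cf$d_target, refine = cf$refine)
      fr <- sweep_frown(cf$betas, length = 2 * cf$shape$a, mat = cf$mat,
                        plate = cf$plate, params = cf$params,
                        d_target = cf$d_target, refine = cf$refine)
      cmp <- compare_shapes(chev, fr, beta_max = cf$beta_max)
      write_csv_plain(chev$records, file.path(out, "sweep_chevron.csv"))
      write_csv_plain(fr$records, file.path(out, "sweep_frown.csv"))
      summarise$chevron_improvement_pct <- cmp$best_chevron$improvement_pct
      summarise$frown_improvement_pct <- cmp$best_frown$improvement_pct
      summarise$straight_G_kJ_m2 <- cmp$straight_G / 1e3
      cmp
    })
  conv <- study_convergence(res)
  if (!is.null(conv$all_converged) && !conv$all_converged && !cf$allow_unconverged)
    stop("contour integrals failed the 2% ring-scatter convergence check; ",
         "set allow_unconverged to proceed")
  jsonlite::write_json(summarise, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  manifest <- list(package = "sicsfract",
                   version = as.character(utils::packageVersion("sicsfract")),
                   protocol = cf$protocol,
                   config_md5 = if (is.character(config)) unname(tools::md5sum(config)) else NA,
                   convergence = conv)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(res)
}

# convergence diagnostics of a protocol result, for the manifest
study_convergence <- function(res) {
  recs <- if (inherits(res, "incision_sweep") || inherits(res, "orthotropy_table"))
    res$records
  else if (inherits(res, "study_record")) as.data.frame(res)
  else NULL
  if (is.null(recs)) return(list(all_converged = NA))
  list(all_converged = all(recs$converged),
       max_ring_scatter = max(recs$scatter),
       n_cases = nrow(recs))
}

sweep_figure <- function(sw, path) {
  grDevices::pdf(path, width = 6, height = 4.5)
  on.exit(grDevices::dev.off())
  plot(sw)
  invisible(path)
}

#' Export mesh and solution as legacy VTK
#'
#' Writes an ASCII legacy-format VTK unstructured grid: node coordinates,
#' element connectivity, the displacement field as point vectors, and the
#' von Mises stress plus ring/tip tags as cell data — the inputs for the
#' usual crack-opening/stress-concentration visualisations.
#'
#' @param mesh A [build_mesh()] result.
#' @param sol The matching [assemble_and_solve()] solution (or `NULL` for
#'   geometry only).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_vtk <- function(mesh, sol, path) {
  stopifnot(inherits(mesh, "crack_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  n <- nrow(mesh$nodes)
  w("# vtk DataFile Version 3.0")
  w("sicsfract incision model")
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  w("POINTS %d double", n)
  writeLines(sprintf("%.17g %.17g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  el <- mesh$elems
  tri <- is.na(el[, 4])
  sizes <- ifelse(tri, 3L, 4L)
  w("CELLS %d %d", nrow(el), sum(sizes + 1L))
  cells <- character(nrow(el))
  cells[tri] <- sprintf("3 %d %d %d", el[tri, 1] - 1L, el[tri, 2] - 1L, el[tri, 3] - 1L)
  cells[!tri] <- sprintf("4 %d %d %d %d", el[!tri, 1] - 1L, el[!tri, 2] - 1L,
                         el[!tri, 3] - 1L, el[!tri, 4] - 1L)
  writeLines(cells, con)
  w("CELL_TYPES %d", nrow(el))
  writeLines(as.character(ifelse(tri, 5L, 9L)), con)
  if (!is.null(sol)) {
    stopifnot(inherits(sol, "plane_stress_solution"))
    w("POINT_DATA %d", n)
    w("VECTORS displacement double")
    writeLines(sprintf("%.17g %.17g 0", sol$u[, 1], sol$u[, 2]), con)
  }
  w("CELL_DATA %d", nrow(el))
  if (!is.null(sol)) {
    es <- element_stress(mesh, sol)
    w("SCALARS von_mises double 1")
    w("LOOKUP_TABLE default")
    writeLines(sprintf("%.17g", es$von_mises), con)
  }
  w("SCALARS ring_tag int 1")
  w("LOOKUP_TABLE default")
  writeLines(as.character(mesh$ring_tag), con)
  w("SCALARS tip_tag int 1")
  w("LOOKUP_TABLE default")
  writeLines(as.character(mesh$tip_tag), con)
  invisible(path)
}

#' Export an ERR result as CSV
#'
#' One row per contour ring plus a summary row with the averaged G and the
#' ring scatter.
#'
#' @param err An [err_at_tip()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_err_csv <- function(err, path) {
  stopifnot(inherits(err, "err_result"))
  df <- data.frame(ring = c(seq_along(err$per_ring_G), NA),
                   G = c(err$per_ring_G, err$G),
                   kind = c(rep("ring", length(err$per_ring_G)), "average_4_10"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
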