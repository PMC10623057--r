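# Shared fixtures: a coarse-but-valid mesh configuration for fast unit tests
# (the package defaults are reserved for the acceptance suite), and a lazy
# cache so expensive solves are shared across test files.

fast_params <- function(a = 1.1e-3)
  mesh_params(r_inner = a / 100, ring_growth = 1.35, n_spokes = 16,
              grade_ratio = 1.45)

.fixture_env <- new.env(parent = emptyenv())
fixture <- function(key, fun) {
  if (!exists(key, envir = .fixture_env)) assign(key, fun(), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

unit_solve <- function(family, angle = NULL, params = NULL, length = 2.2e-3,
                       sigma0 = 1e6, mat = material()) {
  sh <- incision_shape(family, length = length, angle = angle)
  path <- make_crack_path(sh)
  mesh <- build_mesh(path, params = params %||% fast_params(sh$a))
  sol <- assemble_and_solve(mesh, mat, load_case(sigma0))
  list(shape = sh, path = path, mesh = mesh, sol = sol,
       opening = crack_opening(sol, mesh))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

straight_fast <- function() fixture("straight_fast", function() unit_solve("straight"))
chevron150_fast <- function() fixture("chevron150_fast", function() unit_solve("chevron", 150))
frown35_fast <- function() fixture("frown35_fast", function() unit_solve("frown", 35))
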