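# Shared, lazily built model objects so expensive meshes/solves are reused
# across test files within one test run.

.oculoflow_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .oculoflow_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .oculoflow_cache)
  }
  get(name, envir = .oculoflow_cache, inherits = FALSE)
}

normal_mesh <- function() cached("mesh", generate_mesh(eye_geometry()))

coarse_mesh <- function() cached("coarse", make_fixture("coarse_eye"))

normal_params <- function() default_normal_eye()

normal_solution <- function() {
  cached("sol", solve_eye(normal_params(), normal_mesh()))
}

# production calibrated so the anterior-chamber probe reads 15 mmHg
calibrated_params <- function() {
  cached("pcal", calibrate_production(normal_params(), 15, normal_mesh()))
}

calibrated_solution <- function() {
  cached("solcal", solve_eye(calibrated_params(), normal_mesh()))
}

solve_scenario <- function(sc_name_or_obj, base = calibrated_params()) {
  sc <- if (inherits(sc_name_or_obj, "scenario")) sc_name_or_obj
        else get_scenario(sc_name_or_obj, base)
  solve_eye(apply_scenario(base, sc), normal_mesh())
}

# simple bracketing bisection, used as the independent root-finding oracle
bisect <- function(f, lo, hi, tol = 1e-10, n = 200L) {
  flo <- f(lo)
  for (i in seq_len(n)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(hi - lo) < tol) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}
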