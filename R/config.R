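#' Default run configuration
#'
#' The nominal forward-flight case: freestream 0.94 m/s, flapping
#' frequency 213 Hz, span 2.87 mm, air viscosity 1.56e-5 m^2/s, giving
#' Re = 173 and reduced frequency k = 0.65; standard kinematics
#' (amplitude 140 deg, feathering 60/-30 deg with a 0.22-cycle reversal
#' blend, stroke plane 20 deg, body incline 45 deg); standard wing
#' morphology (area 2.59 mm^2); odor released uniformly at the inlet
#' with C' = 1 and density 1.225 kg/m^3; desk-scale grid defaults.
#'
#' All physical quantities in the file carry explicit units, noted in
#' the key names (`_ms` m/s, `_hz` Hz, `_mm` mm, `_deg` degrees,
#' `_m2s` m^2/s, `_cm2s` cm^2/s, `_kgm3` kg/m^3); grid lengths are in
#' units of the span R.
#' @return nested named list (the configuration tree).
#' @export
default_config <- function() {
  list(
    flow = list(U_inf_ms = 0.94, nu_m2s = 1.56e-5, rho_kgm3 = 1.225),
    kinematics = list(Phi_deg = 140, f_hz = 213, theta_deg = 0,
                      alpha_up_deg = 60, alpha_down_deg = -30,
                      reversal_fraction = 0.22, beta_deg = 20,
                      chi_deg = 45),
    geometry = list(wing_area_mm2 = 2.59, span_mm = 2.87,
                    body_axes_mm = c(1.25, 0.42, 0.45),
                    clip_fraction = 0.193),
    grid = list(domain_R = c(-5, 9, -4.5, 5), box_delta_R = 0.03,
                stretch_ratio = 1.12),
    solver = list(cfl = 0.4, diffusion = "cn", poisson_tol = 1e-8,
                  n_cycles = 4),
    odor = list(C_in = 1, rho_odor_kgm3 = 1.225, diffusion = FALSE,
                D_cm2s = 0.1, probe_offset_R = 0.03),
    experiment = list(ks = c(0.33, 0.65, 1.30), scale = "desk"),
    output = list(dir = "flapflow_run", verbosity = 1)
  )
}

config_schema <- function() {
  # key -> c(type, min allowed) ; "num+" strictly positive, "num" any,
  # "numv" numeric vector, "bool", "chr"
  list(
    flow = list(U_inf_ms = "num+", nu_m2s = "num+", rho_kgm3 = "num+"),
    kinematics = list(Phi_deg = "num+", f_hz = "num+", theta_deg = "num",
                      alpha_up_deg = "num", alpha_down_deg = "num",
                      reversal_fraction = "num+", beta_deg = "num",
                      chi_deg = "num"),
    geometry = list(wing_area_mm2 = "num+", span_mm = "num+",
                    body_axes_mm = "numv", clip_fraction = "num"),
    grid = list(domain_R = "numv", box_delta_R = "num+",
                stretch_ratio = "num+"),
    solver = list(cfl = "num+", diffusion = "chr", poisson_tol = "num+",
                  n_cycles = "num+", dt = "num+"),
    odor = list(C_in = "num+", rho_odor_kgm3 = "num+", diffusion = "bool",
                D_cm2s = "num+", probe_offset_R = "num+"),
    experiment = list(ks = "numv", scale = "chr"),
    output = list(dir = "chr", verbosity = "num")
  )
}

#' Validate and normalize a run configuration
#'
#' Parses a JSON configuration (text, file path, or an already-parsed
#' list), checks every key against the schema (unknown keys are a hard
#' error, naming the offender), fills defaults for anything omitted, and
#' attaches the derived dimensionless groups.  An empty configuration
#' yields the nominal case (Re = 173, k = 0.65).
#'
#' @param raw path to a JSON file, a JSON string, or a list.
#' @return object of class `run_configuration`: the defaulted tree plus
#'   `$groups` ([dimensionless()] output).
#' @export
validate_config <- function(raw = NULL) {
  cfg <- if (is.null(raw)) {
    list()
  } else if (is.list(raw)) {
    raw
  } else if (file.exists(raw)) {
    txt <- paste(readLines(raw, warn = FALSE), collapse = "\n")
    if (!nzchar(trimws(txt))) list() else jsonlite::fromJSON(txt, simplifyVector = TRUE)
  } else {
    jsonlite::fromJSON(raw, simplifyVector = TRUE)
  }
  schema <- config_schema()
  defaults <- default_config()
  errors <- character()
  bad_block <- setdiff(names(cfg), names(schema))
  if (length(bad_block)) {
    errors <- c(errors, sprintf("unknown configuration block '%s'", bad_block))
  }
  out <- defaults
  for (blk in intersect(names(cfg), names(schema))) {
    bad_key <- setdiff(names(cfg[[blk]]), names(schema[[blk]]))
    if (length(bad_key)) {
      errors <- c(errors, sprintf("unknown key '%s' in block '%s'", bad_key, blk))
    }
    for (key in intersect(names(cfg[[blk]]), names(schema[[blk]]))) {
      val <- cfg[[blk]][[key]]
      ty <- schema[[blk]][[key]]
      ok <- switch(ty,
                   "num+" = is.numeric(val) && length(val) == 1L && is.finite(val) && val > 0,
                   "num" = is.numeric(val) && length(val) == 1L && is.finite(val),
                   "numv" = is.numeric(val) && all(is.finite(val)),
                   "bool" = is.logical(val) && length(val) == 1L,
                   "chr" = is.character(val) && length(val) == 1L)
      if (!ok) {
        errors <- c(errors, sprintf(
          "key '%s.%s' violates schema (expected %s%s)", blk, key,
          switch(ty, "num+" = "a positive number", "num" = "a number",
                 "numv" = "a numeric vector", "bool" = "a logical",
                 "chr" = "a string"),
          if (ty == "num+") ", got a non-positive or non-numeric value" else ""))
      } else {
        out[[blk]][[key]] <- val
      }
    }
  }
  if (length(errors)) {
    stop(paste(c("configuration schema violations:",
                 paste(" -", errors)), collapse = "\n"))
  }
  out$groups <- dimensionless(U_inf = out$flow$U_inf_ms,
                              R = out$geometry$span_mm * 1e-3,
                              nu = out$flow$nu_m2s,
                              f = out$kinematics$f_hz,
                              D = out$odor$D_cm2s)
  class(out) <- "run_configuration"
  out
}

#' @export
print.run_configuration <- function(x, ...) {
  cat(sprintf("<run_configuration> Re=%.0f, k=%.2f (U=%g m/s, f=%g Hz, R=%g mm)\n",
              x$groups$Re, x$groups$k, x$flow$U_inf_ms, x$kinematics$f_hz,
              x$geometry$span_mm))
  invisible(x)
}

#' Planform described by a configuration
#' @param config a `run_configuration`.
#' @param clipped use the trailing-edge-clipped wing.
#' @export
config_planform <- function(config, clipped = FALSE) {
  pf <- wing_planform(S = config$geometry$wing_area_mm2,
                      R = config$geometry$span_mm)
  if (clipped) {
    pf <- clip_trailing_edge(pf, default_clip_line(pf, config$geometry$clip_fraction))
  }
  pf
}

#' Kinematics described by a configuration (dimensional, seconds/Hz)
#' @param config a `run_configuration`.
#' @export
config_kinematics <- function(config) {
  kk <- config$kinematics
  wing_kinematics(Phi = kk$Phi_deg, f = kk$f_hz, theta0 = kk$theta_deg,
                  alpha_up = kk$alpha_up_deg, alpha_down = kk$alpha_down_deg,
                  reversal_fraction = kk$reversal_fraction,
                  beta = kk$beta_deg, chi = kk$chi_deg)
}
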