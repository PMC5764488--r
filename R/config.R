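# Flat "key = value" run-configuration files (with optional cosmetic
# [section] headers and '#' comments).  One dialect for every simulator so
# that runs are diffable and exactly reproducible.

config_schema <- list(
  common = c("model", "duration_ms", "seed", "provenance"),
  fre = c("tau_m", "tau_d", "J", "Theta", "Delta", "dt", "r0_hz", "v0",
          "s0_hz", "forcing_type", "forcing_base", "forcing_T"),
  qif_net = c("N", "tau_m", "tau_d", "J", "Theta", "Delta", "V_theta",
              "tau_s", "dt", "r0_hz", "v0", "s0_hz", "smoothing"),
  wb_net = c("N", "C_m", "g_L", "E_L", "g_Na", "E_Na", "g_K", "E_K", "phi",
             "I0", "I_bar", "sigma", "k", "tau_d", "tau_s", "dt",
             "v_center", "v_halfwidth", "sweep_tau_d", "sweep_k",
             "sweep_direction")
)

#' Load a run configuration
#'
#' Parses a flat `key = value` configuration file, validates every key
#' against the schema of the declared `model`
#' (`qif_fre`, `h_fre`, `slow_reduction`, `qif_net`, `wb_net`), resolves
#' defaults, and validates parameter invariants.  Unknown keys are an
#' error (listing the offenders), as are empty files and invalid
#' parameter values.
#'
#' @param path Path to the configuration file.
#' @return An object of class `run_config`: list with `model`, the
#'   resolved parameter object (`params`), initial conditions, duration,
#'   forcing, seed, and the full resolved key set (`resolved`) recorded
#'   for provenance.
#' @examples
#' cfg <- load_config(system.file("extdata", "fig3_fast.cfg",
#'                                package = "qiffre"))
#' cfg$params
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_user(sprintf("config file '%s' not found", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^\\[.*\\]$", lines)]  # section headers: cosmetic
  if (!length(lines)) stop_user(sprintf("config file '%s' is empty", path))
  bad <- !grepl("=", lines)
  if (any(bad))
    stop_user(paste("malformed config lines:", paste(lines[bad], collapse = "; ")))
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  if (anyDuplicated(keys))
    stop_user(paste("duplicate config keys:",
                    paste(unique(keys[duplicated(keys)]), collapse = ", ")))
  kv <- stats::setNames(as.list(vals), keys)

  model <- kv$model
  if (is.null(model)) stop_user("config must declare a 'model'")
  fam <- switch(model,
    qif_fre = , h_fre = , slow_reduction = "fre",
    qif_net = "qif_net", wb_net = "wb_net",
    stop_user(sprintf("unknown model '%s'", model)))
  allowed <- c(config_schema$common, config_schema[[fam]])
  unknown <- setdiff(keys, allowed)
  if (length(unknown))
    stop_user(paste("unknown config keys for model", model, ":",
                    paste(unknown, collapse = ", ")))

  num <- function(key, default = NULL) {
    if (is.null(kv[[key]])) return(default)
    x <- suppressWarnings(as.numeric(kv[[key]]))
    if (is.na(x)) stop_user(sprintf("config key '%s' must be numeric", key))
    x
  }
  numvec <- function(key, default = NULL) {
    if (is.null(kv[[key]])) return(default)
    x <- suppressWarnings(as.numeric(strsplit(kv[[key]], ",")[[1]]))
    if (anyNA(x)) stop_user(sprintf("config key '%s' must be a comma list", key))
    x
  }

  out <- list(model = model, seed = num("seed"),
              duration = num("duration_ms", 1000),
              provenance = kv$provenance, path = path)
  if (fam == "fre") {
    out$params <- fre_params(tau_m = num("tau_m", 10), tau_d = num("tau_d", 5),
                             J = num("J", 21), Theta = num("Theta", 4),
                             Delta = num("Delta", 0.3))
    out$dt <- num("dt", out$params$tau_m / 100)
    out$init <- list(r_hz = num("r0_hz", 5), v = num("v0", 0),
                     s_hz = num("s0_hz", 5))
    ft <- if (is.null(kv$forcing_type)) "constant" else kv$forcing_type
    out$forcing <- if (ft == "constant") NULL else
      forcing_spec(ft, base = num("forcing_base", 4),
                   T_theta = num("forcing_T"))
  } else if (fam == "qif_net") {
    tau_m <- num("tau_m", 10)
    out$params <- qif_net_params(N = num("N", 5000), tau_m = tau_m,
                                 J = num("J", 21), Theta = num("Theta", 4),
                                 Delta = num("Delta", 0.3),
                                 tau_d = num("tau_d", 5),
                                 V_theta = num("V_theta", 100),
                                 tau_s = num("tau_s", 1e-2 * tau_m),
                                 dt = num("dt", 1e-3 * tau_m))
    out$init <- list(r_hz = num("r0_hz", 5), v = num("v0", 0),
                     s_hz = num("s0_hz", 5))
    out$smoothing <- if (is.null(kv$smoothing)) "methods" else kv$smoothing
  } else {
    out$params <- wb_params(N = num("N", 1000), C_m = num("C_m", 1),
                            g_L = num("g_L", 0.1), E_L = num("E_L", -65),
                            g_Na = num("g_Na", 35), E_Na = num("E_Na", 55),
                            g_K = num("g_K", 9), E_K = num("E_K", -90),
                            phi = num("phi", 5), I0 = num("I0", 0.1601),
                            I_bar = num("I_bar", 0.5),
                            sigma = num("sigma", 0.01), k = num("k", 6),
                            tau_d = num("tau_d", 5), tau_s = num("tau_s", 0.01),
                            dt = num("dt", 0.001))
    out$init <- list(v_center = num("v_center", -62),
                     v_halfwidth = num("v_halfwidth", 5))
    out$sweep <- list(tau_d = numvec("sweep_tau_d"), k = numvec("sweep_k"),
                      direction = if (is.null(kv$sweep_direction))
                        "increasing" else kv$sweep_direction)
  }
  out$resolved <- kv
  structure(out, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("run config (%s): model %s, duration %g ms\n",
              x$path, x$model, x$duration))
  invisible(x)
}
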