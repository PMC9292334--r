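#' Load and validate a run configuration
#'
#' Reads a YAML configuration and fills every omitted entry with the package
#' defaults (including the standard element quota table). Unknown keys are
#' rejected at every level, and all values pass through the same validators
#' as the programmatic constructors.
#'
#' Recognized top-level sections: `seed`, `output_dir`,
#' `integrator` (`dt`, `save_every`), `elements` (per-element overrides),
#' `ecosystem` (parameter overrides), `scenario` (see [scenario_spec()]),
#' `attribution` (`threshold`, `grouping`).
#'
#' @param path path to a YAML file; an empty file yields the full-default
#'   configuration.
#' @return List of class `mn_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("seed", "output_dir", "integrator", "elements", "ecosystem",
             "scenario", "attribution")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  integ <- raw$integrator
  bad <- setdiff(names(integ), c("dt", "save_every"))
  if (length(bad)) {
    stop("unknown integrator key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dt <- if (is.null(integ$dt)) 0.25 else integ$dt
  save_every <- if (is.null(integ$save_every)) 30 else integ$save_every
  if (!is.numeric(dt) || dt <= 0) {
    stop("integrator.dt must be a positive number", call. = FALSE)
  }
  if (!is.numeric(save_every) || save_every < dt) {
    stop("integrator.save_every must be >= dt", call. = FALSE)
  }

  el_over <- raw$elements
  if (!is.null(el_over)) {
    el_over <- lapply(el_over, function(x) lapply(x, as.numeric))
  }
  elements <- tryCatch(element_params(el_over), error = function(e) {
    stop("elements: ", conditionMessage(e), call. = FALSE)
  })

  eco_over <- raw$ecosystem
  eco_defaults <- ecosystem_params(elements = elements)
  if (!is.null(eco_over)) {
    bad <- setdiff(names(eco_over), setdiff(names(eco_defaults), "elements"))
    if (length(bad)) {
      stop("unknown ecosystem key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    merged <- list()
    for (nm in names(eco_over)) {
      cur <- eco_defaults[[nm]]
      ov <- eco_over[[nm]]
      if (is.list(ov)) ov <- unlist(ov)
      if (is.matrix(cur)) {
        stop("ecosystem.", nm, " cannot be set from YAML; use the API",
             call. = FALSE)
      }
      if (!is.null(names(ov)) && length(cur) > 1) {
        bad <- setdiff(names(ov), names(cur))
        if (length(bad)) {
          stop("unknown ecosystem.", nm, " entry: ",
               paste(bad, collapse = ", "), call. = FALSE)
        }
        cur[names(ov)] <- ov
        merged[[nm]] <- cur
      } else {
        merged[[nm]] <- ov
      }
    }
    ecosystem <- tryCatch(
      do.call(ecosystem_params, c(merged, list(elements = elements))),
      error = function(e) stop("ecosystem: ", conditionMessage(e),
                               call. = FALSE))
  } else {
    ecosystem <- eco_defaults
  }

  sc <- raw$scenario
  bad <- setdiff(names(sc), names(formals(scenario_spec)))
  if (length(bad)) {
    stop("unknown scenario key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  scenario <- tryCatch(do.call(scenario_spec, if (is.null(sc)) list() else sc),
                       error = function(e) {
                         stop("scenario: ", conditionMessage(e),
                              call. = FALSE)
                       })

  at <- raw$attribution
  bad <- setdiff(names(at), c("threshold", "grouping"))
  if (length(bad)) {
    stop("unknown attribution key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  threshold <- if (is.null(at$threshold)) 0.5 else at$threshold
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    stop("attribution.threshold must be in [0, 1]", call. = FALSE)
  }
  grouping <- if (is.null(at$grouping)) {
    c("region", "element", "response_kind", "period")
  } else as.character(at$grouping)

  structure(list(
    seed = as.integer(if (is.null(raw$seed)) 1L else raw$seed),
    output_dir = if (is.null(raw$output_dir)) "mnrecycle-out" else
      raw$output_dir,
    integrator = list(dt = dt, save_every = save_every),
    elements = elements, ecosystem = ecosystem, scenario = scenario,
    attribution = list(threshold = threshold, grouping = grouping)
  ), class = "mn_config")
}

#' Save a configuration back to YAML
#'
#' Writes the fully resolved configuration so that loading the file again
#' reproduces it (round-trip identity).
#'
#' @param config an `mn_config` from [load_config()] (or built in code).
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "mn_config"))
  el <- config$elements
  el_list <- lapply(MN_ELEMENTS, function(e) {
    as.list(el[e, setdiff(names(el), "element")])
  })
  names(el_list) <- MN_ELEMENTS
  eco <- config$ecosystem
  eco_list <- list(
    mu_max = as.list(eco$mu_max), k_n = as.list(eco$k_n), q10 = eco$q10,
    t_ref = eco$t_ref, g_max = eco$g_max, k_g = eco$k_g,
    preference = as.list(eco$preference), ae_c = eco$ae_c,
    sigma_diss = eco$sigma_diss, m_z = eco$m_z, m_p = eco$m_p,
    lambda_sink = eco$lambda_sink, lambda_rem = eco$lambda_rem,
    kappa0 = eco$kappa0, n_deep = eco$n_deep,
    d_deep = as.list(eco$d_deep), source_n = eco$source_n,
    source_d = as.list(eco$source_d), fe_q_min = eco$fe_q_min)
  out <- list(
    seed = config$seed, output_dir = config$output_dir,
    integrator = config$integrator, elements = el_list,
    ecosystem = eco_list,
    scenario = unclass(config$scenario),
    attribution = list(threshold = config$attribution$threshold,
                       grouping = as.list(config$attribution$grouping)))
  yaml::write_yaml(out, path)
  invisible(path)
}

.fmt12 <- function(x) {
  if (is.numeric(x) && !is.integer(x)) {
    formatC(x, digits = 12, format = "g")
  } else x
}

#' Write a table as deterministic CSV
#'
#' Floating-point columns are written at 12 significant digits so that runs
#' with identical configuration and seed produce byte-identical files.
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  out <- as.data.frame(lapply(x, .fmt12), stringsAsFactors = FALSE)
  names(out) <- names(x)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a trajectory as tidy CSV
#'
#' One row per save time and variable (`time`, `year`, `variable`, `value`),
#' covering both the state vector and the flux diagnostics.
#'
#' @param traj an `mn_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  wide <- as.data.frame(traj)
  vars <- setdiff(names(wide), c("time", "year"))
  long <- data.frame(
    time = rep(wide$time, times = length(vars)),
    year = rep(wide$year, times = length(vars)),
    variable = rep(vars, each = nrow(wide)),
    value = unlist(wide[vars], use.names = FALSE))
  write_table_csv(long, path)
}

#' Read a driver panel CSV
#'
#' Checks the mandated attribution columns and fails naming any missing one.
#'
#' @param path CSV path.
#' @return data.frame panel.
#' @export
read_panel_csv <- function(path) {
  panel <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("response", MN_PREDICTORS)
  miss <- setdiff(need, names(panel))
  if (length(miss)) {
    stop("panel is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  panel
}

#' Write a run manifest
#'
#' Records the configuration echo, seeds, timestamps, stage status and the
#' md5 checksum of every output file.
#'
#' @param path output JSON path.
#' @param config the `mn_config` used (echoed).
#' @param outputs character vector of produced file paths.
#' @param seeds named list/vector of seeds used per stage.
#' @param status named character vector of per-stage status.
#' @param started POSIXct start time.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config, outputs, seeds, status,
                               started = Sys.time()) {
  files <- lapply(outputs, function(f) {
    list(path = f, md5 = unname(tools::md5sum(f)),
         bytes = file.info(f)$size)
  })
  manifest <- list(
    package = "mnrecycle",
    version = as.character(utils::packageVersion("mnrecycle")),
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = as.list(seeds), status = as.list(status),
    outputs = files,
    config = list(seed = config$seed,
                  integrator = config$integrator,
                  scenario = unclass(config$scenario),
                  attribution = config$attribution))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Built-in self check
#'
#' Runs a short closed-box conservation test and the LMG enumeration-oracle
#' equivalence on a fixed synthetic panel. Used by the command-line `check`
#' subcommand and handy after installation.
#'
#' @param years closed-box run length (model years).
#' @return Named list with `budget_residuals` (per element), `lmg_max_diff`
#'   and `ok`.
#' @export
self_check <- function(years = 5) {
  params <- ecosystem_params(source_d = c(Fe = 0, Zn = 0, Cu = 0, Co = 0,
                                          Mn = 0),
                             source_n = 0, lambda_sink = 0, kappa0 = 0)
  traj <- run_simulation(params,
                         forcing_constant(t_end = years * MN_YEAR_DAYS,
                                          kappa = 0),
                         t_end = years * MN_YEAR_DAYS)
  res <- budget_check(traj)
  gp <- generate_driver_panel(panel_spec(n = 400, seed = 42,
                                         default_cov = 0.5 +
                                           0.5 * diag(4)))
  a <- lmg_shares(gp$panel)
  b <- lmg_shares_bruteforce(gp$panel)
  dmax <- max(abs(a$shares - b$shares))
  list(budget_residuals = res, lmg_max_diff = dmax,
       ok = max(res) < 1e-8 && dmax < 1e-12)
}
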