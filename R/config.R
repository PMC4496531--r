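#' @title Run configuration and scenarios
#' @name config
#' @description
#' A declarative configuration layer: a run is a JSON-serializable list
#' naming the grid, kernel, gain, diffusion, smoothing kernel, horizon,
#' step, seed and initial condition.  [nf_config()] resolves the
#' declarative blocks into the package's objects; [run_scenario()]
#' bundles ready-made configurations used throughout the documentation
#' and tests.
NULL

#' Resolve a declarative kernel block
#'
#' @param spec list with \code{type} one of \code{"gaussian"},
#'   \code{"mexican_hat"}, \code{"exponential"}, \code{"zero"},
#'   \code{"counterexample"}, \code{"long_range"}, \code{"pva"}, plus
#'   type-specific parameters.
#' @param grid grid (needed for orientation-map-based kernels).
#' @return An \code{nf_kernel}.
#' @export
resolve_kernel <- function(spec, grid = NULL) {
  if (inherits(spec, "nf_kernel")) return(spec)
  switch(spec$type,
         gaussian = gaussian_kernel(K = spec$K %||% 1,
                                    beta = spec$beta %||% 1,
                                    N = spec$N %||% (grid$N %||% 1)),
         mexican_hat = mexican_hat_kernel(K1 = spec$K1 %||% 2,
                                          K2 = spec$K2 %||% 1,
                                          beta1 = spec$beta1 %||% 1,
                                          beta2 = spec$beta2 %||% 2,
                                          N = spec$N %||% (grid$N %||% 1)),
         exponential = exponential_kernel(beta = spec$beta %||% 1),
         zero = zero_kernel(),
         counterexample = counterexample_kernel(),
         long_range = {
           om <- orientation_map_synthetic(grid,
                                           n_modes = spec$n_modes %||% 8,
                                           seed = spec$map_seed %||% 1)
           long_range_kernel(eps_lr = spec$eps_lr %||% 0.1,
                             chi = spec$chi %||% 0,
                             beta_lr = spec$beta_lr %||% 2,
                             beta_theta = spec$beta_theta %||% (pi / 8),
                             theta_map = om)
         },
         pva = pva_kernel(resolve_kernel(spec$local, grid),
                          resolve_kernel(spec$longrange, grid)),
         stop(sprintf("unknown kernel type '%s'", spec$type)))
}

resolve_gain <- function(spec) {
  if (inherits(spec, "nf_gain")) return(spec)
  switch(spec$type,
         sigmoid = sigmoid_gain(),
         constant = constant_gain(spec$value %||% 0),
         stop(sprintf("unknown gain type '%s'", spec$type)))
}

resolve_diffusion <- function(spec) {
  if (inherits(spec, "nf_diffusion")) return(spec)
  switch(spec$type,
         linear = linear_diffusion(spec$lambda %||% 1),
         constant = constant_diffusion(spec$value %||% 1),
         tanh = tanh_diffusion(spec$c %||% 1),
         stop(sprintf("unknown diffusion type '%s'", spec$type)))
}

resolve_smoothing <- function(spec) {
  if (inherits(spec, "nf_smoothing")) return(spec)
  switch(spec$type,
         gaussian = smoothing_gaussian(beta = spec$beta %||% 1,
                                       amplitude = spec$amplitude %||% 1),
         indicator = smoothing_indicator(halfwidth = spec$halfwidth %||% 0.5,
                                         amplitude = spec$amplitude %||% 1),
         zero = smoothing_zero(),
         stop(sprintf("unknown smoothing type '%s'", spec$type)))
}

#' Build a run configuration
#'
#' Accepts either resolved package objects or declarative lists (as
#' read from JSON) for each ingredient, and returns a validated
#' \code{nf_config}.
#'
#' @param grid an \code{nf_grid} or list \code{(N, L, M)}.
#' @param kernel,gain,diffusion,phi objects or declarative blocks.
#' @param T time horizon; \code{dt} the uniform step.
#' @param dt time step.
#' @param seed integer seed.
#' @param y0 initial-condition spec (see [initial_condition()]).
#' @return An object of class \code{nf_config}.
#' @export
nf_config <- function(grid, kernel, gain = constant_gain(0),
                      diffusion = constant_diffusion(1),
                      phi = smoothing_gaussian(1),
                      T = 1, dt = 0.01, seed = 1,
                      y0 = list(type = "constant", value = 0)) {
  if (!inherits(grid, "nf_grid")) {
    grid <- grid_spec(N = grid$N %||% 1, L = grid$L %||% 10,
                      M = grid$M %||% 256)
  }
  cf <- structure(list(grid = grid,
                       kernel = resolve_kernel(kernel, grid),
                       gain = resolve_gain(gain),
                       diffusion = resolve_diffusion(diffusion),
                       phi = resolve_smoothing(phi),
                       T = T, dt = dt, seed = seed, y0 = y0),
                  class = "nf_config")
  if (cf$T < 0 || cf$dt <= 0) stop("need T >= 0 and dt > 0")
  cf
}

as_nf_config <- function(x) {
  if (inherits(x, "nf_config")) return(x)
  do.call(nf_config, x)
}

#' Read a configuration from JSON
#'
#' @param path JSON file with blocks \code{grid}, \code{kernel},
#'   \code{gain}, \code{diffusion}, \code{phi}, and scalars \code{T},
#'   \code{dt}, \code{seed}, \code{y0}.
#' @return An \code{nf_config}.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  nf_config(grid = raw$grid, kernel = raw$kernel,
            gain = raw$gain %||% list(type = "constant", value = 0),
            diffusion = raw$diffusion %||% list(type = "constant",
                                                value = 1),
            phi = raw$phi %||% list(type = "gaussian", beta = 1),
            T = raw$T %||% 1, dt = raw$dt %||% 0.01,
            seed = raw$seed %||% 1,
            y0 = as.list(raw$y0 %||% list(type = "constant", value = 0)))
}

#' Bundled scenarios
#'
#' Ready-made end-to-end runs writing their artifacts (JSON reports,
#' CSV tables) under \code{out_dir}:
#' \describe{
#'   \item{example_4_2}{exponential kernel, sigmoid gain, linear
#'     (multiplicative) diffusion: both well-posedness routes apply;
#'     runs the admissibility checks, a simulation, and moment
#'     diagnostics.}
#'   \item{mexican_hat_1d}{Mexican hat kernel with the Fourier weight:
#'     checks C1', the residual identity, and simulates.}
#'   \item{counterexample_c1}{the separable counterexample: C1 passes,
#'     C2' fails, and the simulator refuses to run without force.}
#' }
#'
#' @param name scenario name; unknown names raise an error listing the
#'   catalog.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @return Invisibly, a list of the computed reports; artifacts on
#'   disk.
#' @export
run_scenario <- function(name, out_dir = tempfile("scenario_"), seed = 1) {
  catalog <- c("example_4_2", "mexican_hat_1d", "counterexample_c1")
  if (!name %in% catalog) {
    stop(sprintf("unknown scenario '%s'; available: %s", name,
                 paste(catalog, collapse = ", ")))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- switch(
    name,
    example_4_2 = {
      kern <- exponential_kernel(beta = 1)
      cf <- nf_config(grid = grid_spec(1, 10, 128), kernel = kern,
                      gain = sigmoid_gain(),
                      diffusion = linear_diffusion(0.5),
                      phi = smoothing_gaussian(0.5), T = 2, dt = 0.02,
                      seed = seed,
                      y0 = list(type = "bump", height = 1, width = 2))
      c2 <- check_C2prime(kern)
      ens <- simulate_ensemble(cf, replicates = 120,
                               keep = seq(1, 101, by = 5))
      mom <- moment_diagnostics(ens)
      path <- simulate_field(cf)
      list(c2prime = c2, moments = mom, path = path)
    },
    mexican_hat_1d = {
      kern <- mexican_hat_kernel(2, 1, 1, 2)
      grid <- grid_spec(1, 20, 512)
      rho <- rho_fourier(kern, grid)
      resid <- verify_residual(rho, kern)
      c1p <- check_C1prime(kern, rho)
      cf <- nf_config(grid = grid, kernel = kern, gain = sigmoid_gain(),
                      diffusion = constant_diffusion(0.5),
                      phi = smoothing_gaussian(1), T = 1, dt = 0.02,
                      seed = seed)
      path <- simulate_field(cf)
      list(rho = rho, residual = resid, c1prime = c1p, path = path)
    },
    counterexample_c1 = {
      kern <- counterexample_kernel()
      c1 <- check_C1(kern)
      c2p <- check_C2prime(kern)
      cf <- nf_config(grid = grid_spec(1, 10, 128), kernel = kern,
                      gain = sigmoid_gain(),
                      diffusion = constant_diffusion(1),
                      phi = smoothing_gaussian(0.5), T = 0.2, dt = 0.02,
                      seed = seed)
      refused <- tryCatch({
        simulate_field(cf)
        FALSE
      }, error = function(e) TRUE)
      forced <- simulate_field(cf, force = TRUE)
      list(c1 = c1, c2prime = c2p, refused = refused, path = forced)
    })
  write_scenario_artifacts(name, res, out_dir)
  invisible(res)
}

write_scenario_artifacts <- function(name, res, out_dir) {
  summarize <- function(x) {
    if (inherits(x, "nf_condition_report")) {
      list(condition = x$condition_id, verdict = x$verdict,
           radii = x$truncation_radii, estimates = x$estimates,
           constants = x$constants)
    } else if (inherits(x, "nf_moment_report")) {
      list(growth_exponent = x$growth_exponent, se = x$growth_se,
           verdict = x$verdict, replicates = x$replicates)
    } else if (inherits(x, "nf_path")) {
      list(scheme = x$scheme, times = range(x$times),
           nodes = ncol(x$values),
           final_l2 = grid_l2_norm(x$grid, x$values[nrow(x$values), ]))
    } else if (inherits(x, "nf_weight")) {
      list(construction = x$construction, Lambda = x$Lambda,
           l1_norm = x$l1_norm)
    } else x
  }
  report <- lapply(res, summarize)
  jsonlite::write_json(report, file.path(out_dir,
                                         paste0(name, "_report.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(res$path)) {
    utils::write.csv(
      data.frame(time = res$path$times,
                 l2_norm = apply(res$path$values, 1, grid_l2_norm,
                                 grid = res$path$grid)),
      file.path(out_dir, paste0(name, "_l2.csv")), row.names = FALSE)
  }
  invisible(NULL)
}

#' Command-line dispatcher
#'
#' Thin shell interface over the package functions, used by the
#' \code{exec/nf} script:
#' \preformatted{
#'   nf simulate --config cfg.json --out-dir DIR
#'   nf check-conditions --config cfg.json --out-dir DIR
#'   nf build-weight --config cfg.json --out-dir DIR
#'   nf scenario NAME --out-dir DIR [--seed S]
#' }
#' Exit codes (returned, so the script can pass them to \code{quit}):
#' 0 ok, 2 contract-check failure, 3 configuration error.
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit status, invisibly.
#' @export
nf_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    cat("usage: nf <simulate|check-conditions|build-weight|scenario>",
        "[--config cfg.json] [--out-dir DIR] [--seed S] [--force]\n")
  }
  if (length(args) < 1) { usage(); return(invisible(3L)) }
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  out_dir <- opt("--out-dir", ".")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(opt("--seed", "1"))
  status <- tryCatch({
    switch(cmd,
           simulate = {
             cf <- read_config(opt("--config"))
             path <- simulate_field(cf, force = "--force" %in% args)
             utils::write.csv(
               data.frame(time = path$times,
                          l2_norm = apply(path$values, 1, grid_l2_norm,
                                          grid = path$grid)),
               file.path(out_dir, "path_l2.csv"), row.names = FALSE)
             utils::write.csv(as.data.frame(path$values),
                              file.path(out_dir, "path_values.csv"),
                              row.names = FALSE)
             0L
           },
           `check-conditions` = {
             cf <- read_config(opt("--config"))
             reps <- list(C1 = check_C1(cf$kernel),
                          C2 = check_C2(cf$kernel),
                          `C2prime` = check_C2prime(cf$kernel))
             out <- lapply(reps, function(r) {
               list(verdict = r$verdict, radii = r$truncation_radii,
                    estimates = r$estimates, constants = r$constants)
             })
             jsonlite::write_json(out,
                                  file.path(out_dir, "conditions.json"),
                                  auto_unbox = TRUE, digits = NA,
                                  pretty = TRUE)
             if (all(vapply(reps, function(r) r$verdict != "fail",
                            logical(1)))) 0L else 2L
           },
           `build-weight` = {
             cf <- read_config(opt("--config"))
             rho <- rho_fourier(cf$kernel, cf$grid)
             utils::write.csv(data.frame(x = cf$grid$axis,
                                         rho = rho$values),
                              file.path(out_dir, "weight.csv"),
                              row.names = FALSE)
             jsonlite::write_json(list(Lambda = rho$Lambda,
                                       l1_norm = rho$l1_norm,
                                       residual = verify_residual(rho,
                                                                  cf$kernel)),
                                  file.path(out_dir, "weight_meta.json"),
                                  auto_unbox = TRUE, digits = NA)
             0L
           },
           scenario = {
             if (length(args) < 2) stop("scenario name required")
             run_scenario(args[2], out_dir = out_dir, seed = seed)
             0L
           },
           { usage(); 3L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("C2'|unknown|required|must", conditionMessage(e))) 3L else 2L
  })
  invisible(as.integer(status))
}
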