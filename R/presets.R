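# Parameter presets for the worked scenarios: each returns a complete,
# runnable configuration (stimulus angles, amplitudes, switching rates and
# time-scale ratios of the standard examples analyzed in the vignette).

.preset_registry <- function() {
  fig1 <- function(tau_ratio) list(
    kind = "stochastic",
    stimuli = list(c(cos(0.3926), sin(0.3926)), c(sin(0.3926), cos(0.3926))),
    probs = c(0.5, 0.5),
    tau_w = 25, tau_theta = 25 * tau_ratio,
    process = list(rate = 5),
    init = list(draw = "uniform", min = 0, max = 0.3),
    T = 5000)
  mf2 <- function(rho, x2, tau_ratio) list(
    kind = "meanfield2",
    stimuli = list(c(1, 0), x2),
    probs = c(rho, 1 - rho),
    tau_w = 2, tau_theta = 2 * tau_ratio,
    init = list(state = c(0.1, 0, 0)),
    T = 400)
  net <- function(gamma, tau_ratio, start) list(
    kind = "network",
    stimuli = list(c(1, 0), c(cos(0.7709), sin(0.7709))),
    probs = c(0.5, 0.5),
    gamma = gamma,
    tau_w = 1, tau_theta = tau_ratio,
    init = list(state = start),
    T = 2000)
  sym0 <- c(2, 0, 2, 2, 0, 2) + c(0.13, 0.07, -0.05, -0.11, 0.05, 0.08)
  anti0 <- c(2, 0, 2, 0, 2, 2) + c(0.13, 0.07, -0.05, -0.11, 0.05, 0.08)
  list(
    fig1b = fig1(0.25),
    fig1c = fig1(1.7),
    fig1d = fig1(2.5),
    sim_a = mf2(0.5, c(0, 1), 1.1),
    sim_b = mf2(0.5, c(cos(1), sin(1)), 1.5),
    sim_c = mf2(0.7, c(cos(1), sin(1)), 1.5),
    sim_d = mf2(0.5, 1.5 * c(cos(1), sin(1)), 0.8),
    fig4a = c(mf2(0.5, c(cos(1), sin(1)), 1.5),
              list(analysis = list(type = "tau_sweep", range = c(1.3, 3.3)))),
    fig4c = c(mf2(0.5, 1.5 * c(cos(1), sin(1)), 1.6),
              list(analysis = list(type = "tau_sweep", range = c(0.4, 2.1)))),
    fig5 = list(kind = "reduced3", alpha = 0.92, beta = 2.5, C = 1,
                tau_w = 1, tau_theta = 1.6,
                init = list(state = c(1.05, 0.95, 0.9)), T = 600,
                analysis = list(type = "C_sweep", range = c(-4, 5))),
    fig6 = list(kind = "reduced3", alpha = 0.92, beta = 2.5, C = 0.18,
                tau_w = 1, tau_theta = 1.8,
                init = list(state = c(1.05, 0.95, 0.9)), T = 2000,
                analysis = list(type = "poincare", coordinate = 2, value = 2,
                                C_range = c(0, 0.25))),
    fig7a = c(net(0.2, 1.2, sym0),
              list(analysis = list(type = "tau_sweep", range = c(0.8, 3)))),
    fig7c = c(net(0.4, 1.2, sym0),
              list(analysis = list(type = "tau_sweep", range = c(0.5, 3)))),
    fig9a = net(0.2, 2.65, sym0),
    fig9b = net(0.2, 3, sym0),
    fig10a = c(net(0.25, 1.3, anti0),
               list(analysis = list(type = "tau_sweep", range = c(1.1, 2.6))))
  )
}

#' Named parameter presets
#'
#' `preset_names()` lists the registry; [load_preset()] returns one
#' complete run configuration.
#'
#' @return Character vector of preset names.
#' @export
preset_names <- function() names(.preset_registry())

#' Load a preset run configuration
#'
#' @param name one of [preset_names()].
#' @param seed integer seed stored into the configuration (used for the
#'   switching process and for drawn initial conditions).
#' @return A validated configuration of class `"bcm_config"`.
#' @export
load_preset <- function(name, seed = 1L) {
  reg <- .preset_registry()
  if (!name %in% names(reg))
    stop("unknown preset '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  cfg <- reg[[name]]
  cfg$name <- name
  cfg$seed <- as.integer(seed)
  validate_config(cfg)
}

.config_keys <- c("kind", "stimuli", "probs", "tau_w", "tau_theta",
                  "process", "init", "T", "analysis", "gamma",
                  "alpha", "beta", "C", "name", "seed")

#' Validate a run configuration
#'
#' Checks the schema: known keys only, a known model kind, probabilities
#' summing to 1, positive time scales, and kind-specific requirements.
#'
#' @param cfg a named list.
#' @return The configuration, classed `"bcm_config"`.
#' @export
validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  kinds <- c("stochastic", "meanfield2", "reduced3", "network")
  if (is.null(cfg$kind) || !cfg$kind %in% kinds)
    stop("kind must be one of: ", paste(kinds, collapse = ", "))
  if (!is.null(cfg$probs)) {
    if (any(cfg$probs <= 0) || abs(sum(cfg$probs) - 1) > 1e-8)
      stop("probs must be positive and sum to 1")
  }
  if (is.null(cfg$tau_w) || is.null(cfg$tau_theta) ||
      cfg$tau_w <= 0 || cfg$tau_theta <= 0)
    stop("tau_w and tau_theta must be positive")
  if (cfg$kind == "stochastic" &&
      (is.null(cfg$process) || is.null(cfg$process$rate) ||
       cfg$process$rate <= 0))
    stop("stochastic runs need process$rate > 0")
  if (cfg$kind == "reduced3" &&
      (is.null(cfg$alpha) || is.null(cfg$beta) || is.null(cfg$C)))
    stop("reduced3 runs need alpha, beta and C")
  if (cfg$kind == "network" && (is.null(cfg$gamma)))
    stop("network runs need gamma")
  if (is.null(cfg$T) || cfg$T <= 0) stop("T must be positive")
  structure(cfg, class = "bcm_config")
}

#' Read and write run configurations
#'
#' Plain-YAML serialization of a configuration; `read_config` validates on
#' load, so a round trip through disk returns an equivalent object.
#'
#' @param cfg a `bcm_config` (or plain list for `write_config`).
#' @param path file path.
#' @return `read_config` returns a `bcm_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$stimuli)) cfg$stimuli <- lapply(cfg$stimuli, as.numeric)
  if (!is.null(cfg$probs)) cfg$probs <- as.numeric(cfg$probs)
  if (!is.null(cfg$init$state)) cfg$init$state <- as.numeric(cfg$init$state)
  validate_config(cfg)
}

# materialize the initial state of a config (drawn inits use the run seed)
.config_init <- function(cfg, dim) {
  if (!is.null(cfg$init$state)) return(as.numeric(cfg$init$state))
  if (identical(cfg$init$draw, "uniform")) {
    return(stats::runif(dim, cfg$init$min, cfg$init$max))
  }
  stop("config has no usable initial condition")
}

#' Execute a run configuration
#'
#' Runs the configured model and writes `trajectory.csv` (header
#' `t,v1..,theta[,stimulus_index]`) plus `metadata.json` (seed, package
#' version, tolerances) into `out_dir`. Outputs are deterministic given the
#' configuration seed.
#'
#' @param cfg a `bcm_config`, e.g. from [load_preset()].
#' @param out_dir output directory, created if needed.
#' @param dt output/recording step for the deterministic kinds.
#' @return Invisibly, a list with the trajectory object and the file paths.
#' @export
run_bcm <- function(cfg, out_dir, dt = 0.1) {
  cfg <- validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(cfg$seed)) 1L else cfg$seed
  set.seed(seed)
  rule <- bcm_rule(cfg$tau_w, cfg$tau_theta)
  meta <- list(package = "bcmdyn",
               version = as.character(utils::packageVersion("bcmdyn")),
               config = cfg$name, kind = cfg$kind, seed = seed,
               rtol = 1e-8, atol = 1e-10)
  if (cfg$kind == "stochastic") {
    ens <- stimulus_ensemble(cfg$stimuli, cfg$probs)
    w0 <- .config_init(cfg, ens$n)
    theta0 <- if (!is.null(cfg$init$draw))
      stats::runif(1, cfg$init$min, cfg$init$max) else 0.1
    proc <- switching_process(cfg$process$rate, seed = seed)
    tr <- simulate_switching(ens, rule, proc, w0, theta0, cfg$T)
    df <- data.frame(t = tr$t)
    for (k in seq_len(ens$m)) df[[paste0("v", k)]] <- tr$v[, k]
    df$theta <- tr$theta
    df$stimulus_index <- tr$stimulus
    meta$initial <- c(w0, theta0)
  } else {
    sys <- switch(cfg$kind,
      meanfield2 = bcm_meanfield(stimulus_ensemble(cfg$stimuli, cfg$probs),
                                 rule),
      reduced3 = reduce_three_stimuli(cfg$alpha, cfg$beta, cfg$C,
                                      tau = cfg$tau_theta / cfg$tau_w),
      network = bcm_network(network_params(
        cfg$gamma, stimulus_ensemble(cfg$stimuli, cfg$probs), rule)))
    y0 <- .config_init(cfg, sys$dim)
    tr <- integrate_system(sys, y0, cfg$T, dt = dt)
    df <- as.data.frame(tr)
    names(df) <- sub("^v_", "v", names(df))   # stable wire format
    meta$initial <- y0
    meta$unbounded <- isTRUE(attr(tr, "unbounded"))
  }
  traj_path <- file.path(out_dir, "trajectory.csv")
  meta_path <- file.path(out_dir, "metadata.json")
  utils::write.csv(df, traj_path, row.names = FALSE)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(list(trajectory = tr, files = c(traj_path, meta_path)))
}
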