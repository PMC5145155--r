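# Protocol configs (YAML), result serialization, and deterministic fixtures.

protocol_kinds <- c("trace", "async", "sweep", "fi", "classify", "bt",
                    "cusp", "nullclines", "population", "etoh", "reward")

protocol_schema <- list(
  kind = protocol_kinds,
  top = c("kind", "seed", "params", "variant", "syn", "i_app", "duration",
          "transient", "dt", "sweep", "fi", "classify", "bt", "cusp",
          "nullclines", "async", "population", "reward", "label")
)

validate_protocol <- function(cfg) {
  if (is.null(cfg$kind) || !cfg$kind %in% protocol_schema$kind) {
    stop("config field 'kind' must be one of: ",
         paste(protocol_schema$kind, collapse = ", "))
  }
  unknown <- setdiff(names(cfg), protocol_schema$top)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(cfg$params)) {
    g <- intersect(names(cfg$params),
                   c("gbar_ca", "gbar_kca", "gbar_k", "gbar_sna", "gbar_na",
                     "gbar_dr", "g_l", "g_h"))
    if (any(unlist(cfg$params[g]) < 0)) {
      stop("config params: conductances must be >= 0")
    }
  }
  if (!is.null(cfg$syn) &&
      any(unlist(cfg$syn[intersect(names(cfg$syn),
                                   c("g_nmda", "g_ampa", "g_gaba"))]) < 0)) {
    stop("config syn: conductances must be >= 0")
  }
  invisible(cfg)
}

cfg_params <- function(cfg) {
  if (is.null(cfg$params)) da_params() else do.call(da_params, cfg$params)
}

cfg_variant <- function(cfg) {
  if (is.null(cfg$variant)) model_variant() else
    do.call(model_variant, cfg$variant)
}

cfg_syn <- function(cfg) {
  if (is.null(cfg$syn)) syn_drive() else do.call(syn_drive, cfg$syn)
}

#' Run a protocol configuration
#'
#' Executes one of the shipped (or user-written) YAML protocols and writes
#' its results to disk: CSV tables (traces, F-I curves, heat maps, diagram
#' branches, rasters as `neuron,time_ms`) plus a JSON manifest with the
#' verdicts, seed, runtime and package version.  Unknown config keys are
#' rejected; a negative conductance fails validation before anything runs.
#'
#' Shipped configurations live under
#' `system.file("protocols", package = "daneuron")` and reproduce the
#' package's reference analyses (balanced trace, conductance-plane maps,
#' excitability classification, the Bogdanov-Takens boundary, the Ih cusp,
#' and the population protocols).
#'
#' @param config path to a YAML protocol file.
#' @param out_dir output directory (created if missing).
#' @param seed overrides the config seed.
#' @return (invisibly) the list of result objects, with the manifest as
#'   attribute.
#' @export
run_protocol <- function(config, out_dir = tempfile("daneuron-"),
                         seed = NULL) {
  cfg <- yaml_fix_yn(yaml::read_yaml(config))
  validate_protocol(cfg)
  if (!is.null(seed)) cfg$seed <- seed
  if (is.null(cfg$seed)) cfg$seed <- 1
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  params <- cfg_params(cfg)
  variant <- cfg_variant(cfg)
  syn <- cfg_syn(cfg)
  res <- list()
  info <- list(kind = cfg$kind, seed = cfg$seed,
               label = if (is.null(cfg$label)) cfg$kind else cfg$label)

  num <- function(x) if (is.null(x)) NULL else as.numeric(unlist(x))
  grid_of <- function(g) {
    if (!is.null(g$values)) return(num(g$values))
    seq(g$from, g$to, length.out = g$n)
  }

  if (cfg$kind == "trace") {
    sim <- integrate_da(params, variant, syn,
                        i_app = if (is.null(cfg$i_app)) 0 else cfg$i_app,
                        duration = cfg$duration %||% 12000,
                        dt = cfg$dt %||% 0.025,
                        record_every = 20,
                        transient = cfg$transient %||% 2000)
    write.csv(data.frame(time_ms = sim$time, v_mv = sim$v, ca_um = sim$ca),
              file.path(out_dir, "trace.csv"), row.names = FALSE)
    write.csv(data.frame(spike_ms = sim$spikes),
              file.path(out_dir, "spikes.csv"), row.names = FALSE)
    st <- firing_stats(sim$spikes, sim$transient)
    info$rate_hz <- st$rate
    info$cv <- st$cv
    res$sim <- sim
  } else if (cfg$kind == "async") {
    dur <- cfg$duration %||% 12000
    dt <- cfg$dt %||% 0.025
    s <- asynchronous_drive(cfg$async$g_nmda %||% 10,
                            cfg$async$g_gaba %||% 4,
                            duration = dur, dt = dt, seed = cfg$seed)
    sim <- integrate_da(params, variant, s, duration = dur, dt = dt,
                        record_every = 40,
                        transient = cfg$transient %||% 2000)
    write.csv(data.frame(time_ms = sim$time, v_mv = sim$v),
              file.path(out_dir, "trace.csv"), row.names = FALSE)
    st <- firing_stats(sim$spikes, sim$transient)
    info$rate_hz <- st$rate
    info$cv <- st$cv
    info$mean_gates <- as.list(attr(s, "mean_gates"))
    res$sim <- sim
  } else if (cfg$kind == "nullclines") {
    nc <- nullclines(params, syn,
                     i_app = if (is.null(cfg$i_app)) 0 else cfg$i_app,
                     v_range = num(cfg$nullclines$v_range) %||% c(-90, -20),
                     variant = reduced_variant())
    write.csv(nc, file.path(out_dir, "nullclines.csv"), row.names = FALSE)
    eq <- find_equilibria(params, reduced_variant(), syn,
                          if (is.null(cfg$i_app)) 0 else cfg$i_app)
    write.csv(as.data.frame(eq), file.path(out_dir, "equilibria.csv"),
              row.names = FALSE)
    res$nullclines <- nc
    res$equilibria <- eq
  } else if (cfg$kind == "sweep") {
    map <- conductance_plane_sweep(
      params, variant,
      x = list(param = cfg$sweep$x$param, values = grid_of(cfg$sweep$x)),
      y = list(param = cfg$sweep$y$param, values = grid_of(cfg$sweep$y)),
      syn = syn,
      duration = cfg$duration %||% 10000,
      transient = cfg$transient %||% 2000,
      dt = cfg$dt %||% 0.025)
    tidy <- expand.grid(x = map$x_values, y = map$y_values)
    names(tidy) <- c(map$x_param, map$y_param)
    tidy$rate_hz <- as.vector(map$rate)
    tidy$cv <- as.vector(map$cv)
    tidy$block <- as.vector(map$block)
    write.csv(tidy, file.path(out_dir, "heatmap.csv"), row.names = FALSE)
    if (!is.null(cfg$sweep$balance_band)) {
      bl <- balance_line(map, num(cfg$sweep$balance_band))
      info$balance_slope <- bl$slope
      info$balance_intercept <- bl$intercept
    }
    res$map <- map
  } else if (cfg$kind == "fi") {
    fi <- fi_curve(params, variant, cfg$fi$param, grid_of(cfg$fi),
                   syn = syn, e_eff = cfg$fi$e_eff %||% -90,
                   duration = cfg$duration %||% 10000,
                   transient = cfg$transient %||% 2000,
                   dt = cfg$dt %||% 0.025)
    write.csv(fi, file.path(out_dir, "fi_curve.csv"), row.names = FALSE)
    vd <- tryCatch(excitability_type(fi), error = function(e) NULL)
    if (!is.null(vd)) {
      info$excitability_type <- vd$type
      info$onset_rate_hz <- vd$onset_rate
    }
    res$fi <- fi
  } else if (cfg$kind == "classify") {
    bp <- classify_transition(params, variant, cfg$classify$param,
                              grid_of(cfg$classify), syn = syn,
                              e_eff = cfg$classify$e_eff %||% -90,
                              dt = cfg$dt %||% 0.05)
    info$bifurcation <- bp$type
    info$value <- bp$value
    info$onset_rate_hz <- bp$onset_rate
    res$bifurcation <- bp
  } else if (cfg$kind == "bt") {
    bt <- bt_boundary(params, variant, syn,
                      e_range = num(cfg$bt$e_range) %||% c(-90, -60),
                      g_max = cfg$bt$g_max %||% 3)
    info$e_bt_mv <- bt$e_bt
    res$bt <- bt
  } else if (cfg$kind == "cusp") {
    cr <- critical_gh_fold(params, variant, syn,
                           gh_range = num(cfg$cusp$gh_range) %||% c(0, 10))
    info$gh_crit <- cr$gh_crit
    res$cusp <- cr
  } else if (cfg$kind %in% c("population", "etoh")) {
    spec <- population_spec(
      n_neurons = cfg$population$n_neurons %||% 50,
      ou = ou_spec(mu = cfg$population$mu %||% 1.5,
                   sigma = cfg$population$sigma %||% 0.5,
                   c = cfg$population$c %||% 0.5,
                   tau = cfg$population$tau %||% 5,
                   seed = cfg$seed),
      params = params, seed = cfg$seed)
    cmp <- if (cfg$kind == "population") {
      tonic_tone_protocol(spec, duration = cfg$duration %||% 14000)
    } else {
      etoh_protocol(spec, duration = cfg$duration %||% 14000)
    }
    write.csv(cmp$control$raster, file.path(out_dir, "raster_control.csv"),
              row.names = FALSE)
    write.csv(cmp$tone$raster, file.path(out_dir, "raster_tone.csv"),
              row.names = FALSE)
    write.csv(data.frame(time_ms = cmp$tone$da$time,
                         da_control_um = cmp$control$da$da,
                         da_tone_um = cmp$tone$da$da),
              file.path(out_dir, "da_traces.csv"), row.names = FALSE)
    info$sync_control <- cmp$sync_control
    info$sync_tone <- cmp$sync_tone
    info$da_control <- cmp$da_control
    info$da_tone <- cmp$da_tone
    res$comparison <- cmp
  } else if (cfg$kind == "reward") {
    rw <- reward_coding_protocol(
      reward_values = num(cfg$reward$values) %||% seq(0, 1, 0.1),
      type = cfg$reward$type %||% "I", params = params)
    write.csv(rw, file.path(out_dir, "reward_response.csv"),
              row.names = FALSE)
    res$reward <- rw
  }

  info$runtime_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  info$package_version <- as.character(utils::packageVersion("daneuron"))
  jsonlite::write_json(info, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  attr(res, "manifest") <- info
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# YAML 1.1 parses bare `y`/`n` mapping keys as TRUE/FALSE; map them back
yaml_fix_yn <- function(x) {
  if (!is.list(x)) return(x)
  nm <- names(x)
  if (!is.null(nm)) {
    nm[nm == "TRUE"] <- "y"
    nm[nm == "FALSE"] <- "n"
    names(x) <- nm
  }
  lapply(x, yaml_fix_yn)
}

#' Theta-model F-I oracle
#'
#' The theta model `dtheta/dt = I - cos(theta)` is the normal form of a
#' SNIC bifurcation: quiescent for I < 1, firing for I > 1 with the
#' closed-form rate `sqrt(I^2 - 1)/(2 pi)` (kHz when time is in ms), which
#' scales as the square root of the distance to threshold.  Used as the
#' independent fixture against which the SNIC certificates are checked.
#'
#' @param i_values drive values.
#' @param dt integration step (ms); `NULL` returns the closed form only.
#' @param duration simulated time per point (ms).
#' @return data.frame with `value`, `rate` (Hz, simulated; 0 when
#'   quiescent) and `rate_exact` (Hz, closed form).
#' @export
theta_model_fi <- function(i_values, dt = 0.001, duration = 500) {
  exact <- ifelse(i_values > 1,
                  1000 * sqrt(pmax(i_values^2 - 1, 0)) / (2 * pi), 0)
  rate <- rep(0, length(i_values))
  if (!is.null(dt)) {
    for (k in seq_along(i_values)) {
      i0 <- i_values[k]
      if (i0 <= 1) next
      theta <- -pi / 2
      crossings <- 0
      n <- round(duration / dt)
      for (s in seq_len(n)) {
        theta <- theta + dt * (i0 - cos(theta))
        if (theta >= pi) {
          theta <- theta - 2 * pi
          crossings <- crossings + 1
        }
      }
      rate[k] <- crossings / duration * 1000
    }
  }
  data.frame(value = i_values, rate = rate, rate_exact = exact)
}

#' Deterministic test fixtures
#'
#' Regenerates the small canned inputs used by the unit tests: a 1-second
#' Poisson spike-train set, an OU conductance trace, the theta-model F-I
#' table, and a hard-coded bistable F-I pair with a known hysteresis
#' width.  Regeneration is idempotent under a fixed seed.
#'
#' @param seed RNG seed.
#' @param dir output directory (`NULL` returns the fixtures without
#'   writing).
#' @return (invisibly) a named list of fixtures.
#' @export
make_fixtures <- function(seed = 1, dir = NULL) {
  trains <- poisson_glu_trains(n = 10, rate = 10, duration = 1000,
                               seed = seed)
  ou <- ou_trace(ou_spec(mu = 1.5, sigma = 0.5, c = 0, tau = 5,
                         seed = seed),
                 duration = 1000, dt = 0.1)
  theta <- theta_model_fi(c(0.5, 0.9, 1.0005, 1.002, 1.01, 1.05, 1.2))
  bistable <- list(
    rising = structure(data.frame(value = seq(-2, 0, 0.25),
                                  rate = c(0, 0, 0, 0, 0, 3, 4, 5, 6)),
                       class = c("fi_curve", "data.frame"),
                       param = "i_app", direction = "rising"),
    falling = structure(data.frame(value = seq(0, -2, -0.25),
                                   rate = c(6, 5, 4, 3, 2.5, 2, 0, 0, 0)),
                        class = c("fi_curve", "data.frame"),
                        param = "i_app", direction = "falling"),
    width = 0.5)
  fx <- list(trains = trains, ou = ou, theta = theta, bistable = bistable)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(data.frame(train = rep(seq_along(trains$trains),
                                     lengths(trains$trains)),
                         time_ms = unlist(trains$trains)),
              file.path(dir, "glu_trains.csv"), row.names = FALSE)
    write.csv(data.frame(time_ms = seq(0, by = 0.1,
                                       length.out = nrow(ou)),
                         g = ou[, 1]),
              file.path(dir, "ou_trace.csv"), row.names = FALSE)
    write.csv(theta, file.path(dir, "theta_fi.csv"), row.names = FALSE)
  }
  invisible(fx)
}
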