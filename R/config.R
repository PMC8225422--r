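# YAML configuration: load, validate (unknown keys rejected), save.

.CONFIG_SCHEMA <- list(
  # the neuron count is spelled "n_neurons": a bare "N" key is a boolean
  # token in YAML 1.1 and would not survive parsing
  top = c("n_neurons", "t_end", "t_couple", "output_dt", "seed",
          "mask_structural", "update_mode", "hh", "plasticity",
          "structural", "integrator", "init"),
  hh = c("gNa", "gK", "gL", "CM", "ENa", "EK", "EL", "Iext", "Vrest"),
  plasticity = c("gamma", "R", "epsilon", "update_period"),
  structural = c("type", "global_L", "overlap_fraction"),
  integrator = c("method", "rtol", "atol"),
  init = c("mode", "V_min", "V_max", "jitter_frac", "Iext_jitter")
)

.check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("unknown configuration key(s) in %s: %s", where,
                 paste(bad, collapse = ", ")))
}

#' Load a simulation configuration from a YAML file
#'
#' Any key left out falls back to the reference defaults (the Table-style
#' constants: gNa = 120, gK = 36, gL = 0.3, CM = 1, ENa = 55, EK = -72,
#' EL = -49.4, 64 neurons, R = 25, epsilon = 18.82, gamma = 6e-7, L = 100,
#' d = 2); an empty file therefore yields the full default scenario.
#' Unknown keys are rejected with an error naming them.  The neuron count
#' is spelled `n_neurons` (a bare `N` is a boolean token in YAML 1.1).
#'
#' @param path Path to a YAML file (may be empty).
#' @return A [simulation_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must contain a YAML mapping")
  .check_keys(raw, .CONFIG_SCHEMA$top, "top level")
  for (sec in c("hh", "plasticity", "structural", "integrator", "init")) {
    if (!is.null(raw[[sec]]))
      .check_keys(raw[[sec]], .CONFIG_SCHEMA[[sec]], sec)
  }
  gv <- function(sec, key, default) {
    v <- raw[[sec]][[key]]
    if (is.null(v)) default else v
  }
  hh <- hh_params(
    gNa = gv("hh", "gNa", 120), gK = gv("hh", "gK", 36),
    gL = gv("hh", "gL", 0.3), CM = gv("hh", "CM", 1),
    ENa = gv("hh", "ENa", 55), EK = gv("hh", "EK", -72),
    EL = gv("hh", "EL", -49.4), Iext = gv("hh", "Iext", 10),
    Vrest = gv("hh", "Vrest", -60))
  pl <- plasticity_params(
    gamma = gv("plasticity", "gamma", 6e-7),
    R = gv("plasticity", "R", 25),
    epsilon = gv("plasticity", "epsilon", 18.82),
    update_period = gv("plasticity", "update_period", 1))
  stype <- gv("structural", "type", "lattice")
  if (!identical(stype, "lattice"))
    stop(sprintf("unsupported structural network type '%s'", stype))
  method <- gv("integrator", "method", "rk45dp7")
  if (!identical(method, "rk45dp7"))
    stop(sprintf("unsupported integrator method '%s'", method))
  simulation_config(
    N = raw$n_neurons %||% 64,
    t_end = raw$t_end %||% 3000,
    t_couple = raw$t_couple %||% 400,
    output_dt = raw$output_dt %||% 0.1,
    hh = hh, plasticity = pl,
    global_L = gv("structural", "global_L", 100),
    overlap_fraction = gv("structural", "overlap_fraction", 0.25),
    rtol = gv("integrator", "rtol", 1e-6),
    atol = gv("integrator", "atol", 1e-8),
    seed = raw$seed %||% 1L,
    mask_structural = raw$mask_structural %||% TRUE,
    update_mode = raw$update_mode %||% "pairwise",
    init_mode = gv("init", "mode", "limit_cycle"),
    V_init = c(gv("init", "V_min", -70), gv("init", "V_max", -50)),
    jitter_frac = gv("init", "jitter_frac", 1),
    Iext_jitter = gv("init", "Iext_jitter", 0))
}

#' Save a simulation configuration to a YAML file
#'
#' Writes every tunable field, so `load_config(save_config(cfg, f))`
#' round-trips to an identical configuration.
#'
#' @param config A [simulation_config()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  if (!identical(attr(config$network, "type"), "lattice"))
    stop("only lattice structural networks are serializable to YAML; ",
         "use write_structural_network() for custom domain geometries")
  hh <- config$hh; pl <- config$plasticity
  x <- list(
    n_neurons = config$N, t_end = config$t_end, t_couple = config$t_couple,
    output_dt = config$output_dt, seed = config$seed,
    mask_structural = config$mask_structural,
    update_mode = config$update_mode,
    hh = list(gNa = hh$gNa, gK = hh$gK, gL = hh$gL, CM = hh$CM,
              ENa = hh$ENa, EK = hh$EK, EL = hh$EL, Iext = hh$Iext,
              Vrest = hh$Vrest),
    plasticity = list(gamma = pl$gamma, R = pl$R, epsilon = pl$epsilon,
                      update_period = pl$update_period),
    structural = list(type = "lattice", global_L = config$network$global_L,
                      overlap_fraction = attr(config$network,
                                              "overlap_fraction") %||%
                        0.25),
    integrator = list(method = "rk45dp7", rtol = config$rtol,
                      atol = config$atol),
    init = list(mode = config$init_mode,
                V_min = config$V_init[1], V_max = config$V_init[2],
                jitter_frac = config$jitter_frac,
                Iext_jitter = config$Iext_jitter))
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}
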