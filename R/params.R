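#' Default simulation parameters
#'
#' Returns the full default parameter set for the myotube simulation. All
#' values are overridable through [simulation_params()] or a `key: value`
#' config file read by [load_params()]. Units follow the pN/um/s convention
#' used throughout the package.
#'
#' Defaults of note: thermal energy `temperature_kT = 0.0042` pN·um (~300 K),
#' homogeneous cytoplasmic `viscosity = 1` pN·s/um^2, nucleus radius 4 um,
#' MT flexural rigidity 20 pN·um^2, unloaded growth speed 0.2 um/s, shrinkage
#' 0.4 um/s, growth-force sensitivity 1.5 pN, a fixed tubulin pool of 500 um
#' polymer equivalent per myotube, mean catastrophe time 600 s at free growth
#' and 30 s at stall, at most 20 MTs nucleated per nucleus, 50 dynein plus
#' 50 Kif5b motors per nuclear surface, and 200 passive (MAP4-like) plus 200
#' motile (MAP7-Kif5b-like) cytoplasmic crosslinkers per myotube.
#'
#' @return Named list of parameters.
#' @seealso [simulation_params()], [load_params()]
#' @export
#' @examples
#' p <- default_params()
#' p$force_sensitivity_fg
default_params <- function() {
  list(
    # integration
    dt                  = 0.01,   # s
    duration            = 600,    # s
    temperature_kT      = 0.0042, # pN um
    viscosity           = 1,      # pN s / um^2
    # geometry / bodies
    nucleus_count       = 5,
    nucleus_radius      = 4,      # um
    centrosome_radius   = 0.5,    # um
    # microtubules
    mt_rigidity         = 20,     # pN um^2 flexural rigidity
    mt_segment_length   = 2,      # um discretization target
    mt_stretch_k        = 100,    # pN/um inextensibility penalty per segment
    mt_drag_per_length  = 2,      # pN s/um^2 (drag per unit fiber length)
    v_grow0             = 0.2,    # um/s unloaded growth speed
    v_shrink            = 0.4,    # um/s
    force_sensitivity_fg = 1.5,   # pN
    tubulin_pool_Lmax   = 500,    # um polymer equivalent
    cat_time_free       = 600,    # s mean catastrophe time at free growth
    cat_time_stalled    = 30,     # s mean catastrophe time at stall
    nucleation_rate     = 0.02,   # 1/s per free nucleation site
    nucleation_angle_sd = 0.17,   # rad; near-horizontal nucleation spread
    max_mts_per_nucleus = 20,
    anchor_k            = 100,    # pN/um minus-end anchoring spring
    # connector populations
    n_dynein_per_nucleus = 50,
    n_kif5b_per_nucleus  = 50,
    n_map4               = 200,
    n_map7kif5b          = 200,
    crosslinker_radius   = 0.05,  # um (bead radius of a free crosslinker)
    crosslinker_diffusion = 1,    # um^2/s free-diffusion coefficient
                                  # (small proteins see water-like microviscosity,
                                  #  unlike organelle-scale drag)
    # motor species: dynein (minus-directed), kif5b (plus-directed)
    dynein_v0            = 1.0,   # um/s
    dynein_f_stall       = 5,     # pN
    dynein_k_on          = 5,     # 1/s
    dynein_k_off         = 0.5,   # 1/s
    dynein_capture_radius = 0.05, # um
    dynein_spring_k      = 100,   # pN/um
    dynein_f_unbind      = 3,     # pN; load-accelerated unbinding (Inf = off)
    kif5b_v0             = 0.8,
    kif5b_f_stall        = 5,
    kif5b_k_on           = 5,
    kif5b_k_off          = 0.5,
    kif5b_capture_radius = 0.05,
    kif5b_spring_k       = 100,
    kif5b_f_unbind       = 3,
    map4_k_on            = 5,
    map4_k_off           = 0.5,
    map4_capture_radius  = 0.05,
    map4_spring_k        = 100,
    map4_f_unbind        = 3,
    map7kif5b_v0         = 0.8,
    map7kif5b_f_stall    = 5,
    map7kif5b_k_on       = 5,
    map7kif5b_k_off      = 0.5,
    map7kif5b_capture_radius = 0.05,
    map7kif5b_spring_k   = 100,
    map7kif5b_f_unbind   = 3,
    # environment
    confinement_k        = 100,   # pN/um
    steric_k             = 100,   # pN/um
    centrosomes_per_nucleus = 1,
    dynein_retained      = TRUE,  # keep NE dynein in all conditions
    external_fx          = 0,     # pN uniform force on bodies (diagnostic)
    external_fy          = 0,
    seed                 = 1
  )
}

# keys that must be non-negative
.nonneg_keys <- function() {
  c("temperature_kT", "viscosity", "mt_rigidity", "mt_segment_length",
    "mt_stretch_k", "mt_drag_per_length", "v_grow0", "v_shrink",
    "tubulin_pool_Lmax", "nucleation_rate", "nucleation_angle_sd", "anchor_k",
    "n_dynein_per_nucleus", "n_kif5b_per_nucleus", "n_map4", "n_map7kif5b",
    "crosslinker_radius", "crosslinker_diffusion",
    "dynein_v0", "dynein_f_stall", "dynein_k_on", "dynein_k_off",
    "dynein_capture_radius", "dynein_spring_k", "dynein_f_unbind",
    "kif5b_v0", "kif5b_f_stall", "kif5b_k_on", "kif5b_k_off",
    "kif5b_capture_radius", "kif5b_spring_k", "kif5b_f_unbind",
    "map4_k_on", "map4_k_off", "map4_capture_radius", "map4_spring_k",
    "map4_f_unbind", "map7kif5b_f_unbind",
    "map7kif5b_v0", "map7kif5b_f_stall", "map7kif5b_k_on", "map7kif5b_k_off",
    "map7kif5b_capture_radius", "map7kif5b_spring_k",
    "confinement_k", "steric_k", "centrosomes_per_nucleus", "duration")
}

#' Build a validated simulation parameter set
#'
#' Starts from [default_params()] and overrides the named values given.
#' Unknown keys and invalid values (negative rates, non-positive `dt`, ...)
#' raise an error naming the offending key.
#'
#' @param ... Named parameter overrides.
#' @param .overrides Optionally, a named list of overrides (merged after
#'   `...`).
#' @return A named list of class `simulation_params` with attribute
#'   `"provenance"` marking each key `"default"` or `"user"`.
#' @export
#' @examples
#' p <- simulation_params(nucleus_count = 7, duration = 60)
simulation_params <- function(..., .overrides = list()) {
  user <- c(list(...), .overrides)
  defaults <- default_params()
  if (length(user)) {
    if (is.null(names(user)) || any(names(user) == ""))
      stop("all parameter overrides must be named")
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown))
      stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  }
  p <- modifyList(defaults, user)
  validate_params(p)
  attr(p, "provenance") <- ifelse(names(p) %in% names(user), "user", "default")
  names(attr(p, "provenance")) <- names(p)
  class(p) <- c("simulation_params", "list")
  p
}

validate_params <- function(p) {
  num_keys <- setdiff(names(default_params()), "dynein_retained")
  for (k in num_keys) {
    v <- p[[k]]
    ok <- is.numeric(v) && length(v) == 1L &&
      (is.finite(v) || (grepl("_f_unbind$", k) && is.infinite(v) && v > 0))
    if (!ok)
      stop("parameter '", k, "' must be a finite numeric scalar")
  }
  if (p$dt <= 0) stop("parameter 'dt' must be > 0")
  if (p$force_sensitivity_fg <= 0)
    stop("parameter 'force_sensitivity_fg' must be > 0")
  if (p$nucleus_radius <= 0) stop("parameter 'nucleus_radius' must be > 0")
  if (p$centrosome_radius <= 0) stop("parameter 'centrosome_radius' must be > 0")
  if (p$max_mts_per_nucleus < 1) stop("parameter 'max_mts_per_nucleus' must be >= 1")
  if (p$nucleus_count < 2) stop("parameter 'nucleus_count' must be >= 2")
  if (p$cat_time_stalled <= 0) stop("parameter 'cat_time_stalled' must be > 0")
  if (p$cat_time_free < p$cat_time_stalled)
    stop("parameter 'cat_time_free' must be >= 'cat_time_stalled'")
  for (k in .nonneg_keys()) {
    if (p[[k]] < 0) stop("parameter '", k, "' must be >= 0")
  }
  if (!is.logical(p$dynein_retained) || length(p$dynein_retained) != 1L)
    stop("parameter 'dynein_retained' must be TRUE or FALSE")
  invisible(p)
}

#' Read simulation parameters from a config file or text
#'
#' The config format is flat `key: value` (YAML scalar mapping). Absent keys
#' take their defaults; unknown keys or invalid values are rejected with an
#' error naming the key. The resolved set records, per key, whether the value
#' came from the file or from the defaults.
#'
#' @param config Path to a config file, or a character string of `key: value`
#'   lines (used when `is_text = TRUE` or when `config` contains a newline).
#' @param is_text Force interpretation of `config` as literal text.
#' @param quiet Suppress the resolved-parameter log.
#' @return A `simulation_params` list (see [simulation_params()]).
#' @export
#' @examples
#' p <- load_params("force_sensitivity_fg: 1.5", is_text = TRUE, quiet = TRUE)
#' p$force_sensitivity_fg
load_params <- function(config = NULL, is_text = FALSE, quiet = FALSE) {
  user <- list()
  if (!is.null(config)) {
    txt_mode <- is_text || (is.character(config) && any(grepl("\n", config))) ||
      (is.character(config) && grepl(":", config) && !file.exists(config))
    parsed <- if (txt_mode) yaml::yaml.load(paste(config, collapse = "\n"))
              else yaml::read_yaml(config)
    if (!is.null(parsed)) {
      if (!is.list(parsed)) stop("config must be a flat key: value mapping")
      user <- parsed
    }
  }
  p <- simulation_params(.overrides = user)
  if (!quiet) {
    prov <- attr(p, "provenance")
    msg <- paste0(names(p), " = ", vapply(p, format, ""), " [", prov, "]")
    message("resolved parameters:\n  ", paste(msg, collapse = "\n  "))
  }
  p
}

#' Serialize simulation parameters
#'
#' Writes a `simulation_params` list as flat `key: value` YAML, the format
#' read back by [load_params()]. `load_params(dump_params(p), is_text = TRUE)`
#' round-trips.
#'
#' @param params A `simulation_params` list.
#' @param file Optional path; when `NULL` the text is returned invisibly.
#' @return The YAML text, invisibly.
#' @export
dump_params <- function(params, file = NULL) {
  validate_params(params)
  txt <- yaml::as.yaml(unclass(params)[names(default_params())])
  if (!is.null(file)) writeLines(txt, file)
  invisible(txt)
}

#' @export
print.simulation_params <- function(x, ...) {
  prov <- attr(x, "provenance")
  n_user <- sum(prov == "user")
  cat("<simulation_params> ", length(x), " parameters (",
      n_user, " user-set)\n", sep = "")
  show <- c("dt", "duration", "nucleus_count", "temperature_kT", "viscosity",
            "v_grow0", "v_shrink", "force_sensitivity_fg",
            "tubulin_pool_Lmax", "nucleation_rate", "max_mts_per_nucleus")
  for (k in show)
    cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}
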