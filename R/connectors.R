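#' Linear force-velocity relation of a molecular motor
#'
#' A motor walks at `v0` when unloaded and slows linearly with opposing
#' load, stalling at `f_stall`: `v = v0 * (1 - f_opposing / f_stall)`,
#' clamped to `[0, v0]` (no walking backward under super-stall load, no
#' super-velocity under assisting load).
#'
#' @param f_opposing Load component opposing motion, pN (assisting loads
#'   enter as 0 or negative values and are clamped).
#' @param v0 Unloaded speed, um/s.
#' @param f_stall Stall force, pN (> 0).
#' @return Speed along the filament, um/s.
#' @export
#' @examples
#' motor_velocity(0, 0.8, 5)      # unloaded
#' motor_velocity(2.5, 0.8, 5)    # half speed
#' motor_velocity(5, 0.8, 5)      # stalled
motor_velocity <- function(f_opposing, v0, f_stall) {
  if (f_stall <= 0) stop("f_stall must be > 0")
  stopifnot(v0 >= 0)
  cpp_motor_velocity(f_opposing, v0, f_stall)
}

#' Hookean force pair of a connector
#'
#' A connector (motor or passive crosslinker) exerts a zero-rest-length
#' Hookean spring force between its two attachment points, equal and
#' opposite on the two ends.
#'
#' @param p1,p2 Numeric (x, y) attachment points, um.
#' @param k Spring stiffness, pN/um.
#' @return List with `f1` and `f2`, the pN force vectors on each end
#'   (`f1 == -f2`; `f1` pulls end 1 toward end 2).
#' @export
#' @examples
#' connector_forces(c(0, 0), c(0.1, 0), 100)  # 10 pN pair
connector_forces <- function(p1, p2, k) {
  stopifnot(k >= 0, length(p1) == 2, length(p2) == 2)
  d <- c(p2[1] - p1[1], p2[2] - p1[2])
  f1 <- k * d
  list(f1 = f1, f2 = -f1)
}

#' Connector species table
#'
#' The four connector species and their architecture: NE-anchored dynein
#' (minus-end-directed motor head), NE-anchored Kif5b (plus-end-directed
#' motor head), cytoplasmic MAP4 (two passive MT-binding heads), and the
#' cytoplasmic MAP7-Kif5b complex (one passive MAP7 head, one plus-directed
#' Kif5b motor head). Head directionality is +1 toward the MT plus end, -1
#' toward the minus end, 0 passive.
#'
#' @param params A parameter set from [simulation_params()].
#' @return A data.frame, one row per species.
#' @export
connector_species <- function(params = default_params()) {
  data.frame(
    name = c("dynein", "kif5b", "map4", "map7kif5b"),
    anchored = c(TRUE, TRUE, FALSE, FALSE),
    head1 = c("body-anchor", "body-anchor", "passive", "passive"),
    head2 = c("motor", "motor", "passive", "motor"),
    direction = c(-1, 1, 0, 1),
    v0 = c(params$dynein_v0, params$kif5b_v0, 0, params$map7kif5b_v0),
    f_stall = c(params$dynein_f_stall, params$kif5b_f_stall, NA,
                params$map7kif5b_f_stall),
    k_on = c(params$dynein_k_on, params$kif5b_k_on, params$map4_k_on,
             params$map7kif5b_k_on),
    k_off = c(params$dynein_k_off, params$kif5b_k_off, params$map4_k_off,
              params$map7kif5b_k_off),
    capture_radius = c(params$dynein_capture_radius,
                       params$kif5b_capture_radius,
                       params$map4_capture_radius,
                       params$map7kif5b_capture_radius),
    spring_k = c(params$dynein_spring_k, params$kif5b_spring_k,
                 params$map4_spring_k, params$map7kif5b_spring_k),
    stringsAsFactors = FALSE)
}
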