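#' Microtubule growth speed under load and tubulin depletion
#'
#' The plus-end growth speed is the unloaded speed scaled by the free
#' tubulin fraction and attenuated exponentially by antagonistic force:
#' \deqn{v = v_0 (1 - L_{poly}/L_{max}) e^{-f/f_g}}
#' with growth-force sensitivity \eqn{f_g} (default 1.5 pN). Only the force
#' component opposing growth counts; `f_antagonistic` is clamped at 0 from
#' below, so the result always lies in `[0, v0]`.
#'
#' @param v0 Unloaded growth speed, um/s.
#' @param f_antagonistic Magnitude of the force component opposing growth, pN.
#' @param fg Growth-force sensitivity, pN (> 0).
#' @param L_polymerized,L_max Current and maximal polymerized tubulin, um.
#' @return Growth speed, um/s.
#' @export
#' @examples
#' growth_speed(0.2, 0, 1.5, 0, 500)           # unloaded: v0
#' growth_speed(0.2, 1.5, 1.5, 0, 500)         # v0 / e
growth_speed <- function(v0, f_antagonistic, fg, L_polymerized, L_max) {
  stopifnot(v0 >= 0, fg > 0, L_max > 0, L_polymerized >= 0,
            L_polymerized <= L_max)
  cpp_growth_speed(v0, f_antagonistic, fg, L_polymerized, L_max)
}

#' Growth-rate-dependent catastrophe rate
#'
#' The mean catastrophe time interpolates linearly in normalized growth
#' speed between the stalled and free-growth limits, as observed in vitro:
#' `rate = 1 / (t_stalled + (t_free - t_stalled) * v / v0)`. The rate is
#' monotonically non-increasing in `v`: slow (stalled) ends catastrophize
#' sooner.
#'
#' @param v Current growth speed, um/s (in `[0, v0]`).
#' @param v0 Unloaded growth speed, um/s.
#' @param t_free Mean catastrophe time at free growth, s.
#' @param t_stalled Mean catastrophe time at stall, s (`0 < t_stalled <= t_free`).
#' @return Catastrophe rate, 1/s.
#' @export
#' @examples
#' catastrophe_rate(0.2, 0.2, 600, 30)  # 1/600 at free growth
#' catastrophe_rate(0, 0.2, 600, 30)    # 1/30 at stall
catastrophe_rate <- function(v, v0, t_free, t_stalled) {
  if (t_stalled <= 0) stop("t_stalled must be > 0")
  if (t_free < t_stalled) stop("t_free must be >= t_stalled")
  stopifnot(v >= 0, v <= v0 + 1e-12)
  cpp_catastrophe_rate(v, v0, t_free, t_stalled)
}
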