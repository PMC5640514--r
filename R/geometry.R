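#' Construct the elliptical myotube domain
#'
#' Myotubes are modelled as 2D ellipses whose full width is 14 um and whose
#' full length grows with the number of nuclei: 95 x 14 um for five nuclei,
#' 114 x 14 for six, 133 x 14 for seven, 152 x 14 for eight and 171 x 14 for
#' nine, i.e. 19 um of length per nucleus. Outside the 5-9 range the same
#' 19 um-per-nucleus rule is extrapolated (and flagged).
#'
#' @param nucleus_count Integer number of nuclei (>= 2).
#' @return An object of class `myotube_domain`: list with semi-axes `a`
#'   (half length, along +x) and `b` (half width), `nucleus_count`, and
#'   `extrapolated` flag.
#' @export
#' @examples
#' d <- make_domain(5)
#' c(length = 2 * d$a, width = 2 * d$b)
make_domain <- function(nucleus_count) {
  if (!is.numeric(nucleus_count) || length(nucleus_count) != 1L ||
      !is.finite(nucleus_count) || nucleus_count != round(nucleus_count))
    stop("nucleus_count must be a single integer")
  if (nucleus_count < 2) stop("nucleus_count must be >= 2")
  extra <- !(nucleus_count %in% 5:9)
  if (extra)
    message("nucleus_count ", nucleus_count,
            " outside the tabulated 5-9 range; length extrapolated as 19 um per nucleus")
  d <- structure(
    list(a = 19 * nucleus_count / 2, b = 7,
         nucleus_count = as.integer(nucleus_count),
         extrapolated = extra),
    class = "myotube_domain")
  d
}

#' @export
print.myotube_domain <- function(x, ...) {
  cat(sprintf("<myotube_domain> %g x %g um ellipse (%d nuclei%s)\n",
              2 * x$a, 2 * x$b, x$nucleus_count,
              if (x$extrapolated) ", extrapolated" else ""))
  invisible(x)
}

as_domain <- function(domain) {
  if (inherits(domain, "myotube_domain")) return(domain)
  if (is.list(domain) && all(c("a", "b") %in% names(domain))) return(domain)
  stop("domain must be a myotube_domain or a list with elements a, b")
}

#' Nearest point on an ellipse boundary
#'
#' Finds the boundary point of the axis-aligned ellipse with semi-axes
#' `a`, `b` closest to `point`, by a bounded 1D root find on the boundary
#' parameter (tolerance 1e-9 um).
#'
#' @param point Numeric length-2 vector (x, y) in um.
#' @param a,b Semi-axes (um), `a >= b > 0`.
#' @return Numeric length-2 vector: the closest boundary point.
#' @export
ellipse_nearest_point <- function(point, a, b) {
  stopifnot(is.numeric(point), length(point) == 2, a > 0, b > 0)
  cpp_ellipse_nearest_point(point[1], point[2], a, b)
}

#' Soft confinement force of the elliptical boundary
#'
#' Zero for points inside the ellipse; outside, a linear restoring force of
#' magnitude `k` times the penetration depth, directed toward the nearest
#' boundary point. For a finite-size body pass its `radius` to confine it to
#' the correspondingly reduced ellipse.
#'
#' @param point Numeric (x, y) position, um.
#' @param domain A [make_domain()] object (or list with `a`, `b`).
#' @param k Confinement stiffness, pN/um (>= 0).
#' @param radius Body radius, um (0 for a point such as an MT vertex).
#' @return Numeric length-2 force vector, pN.
#' @export
#' @examples
#' d <- make_domain(5)
#' confinement_force(c(0, 0), d, 100)        # zero at the center
#' confinement_force(c(d$a + 1, 0), d, 100)  # ~ -k * 1 along x
confinement_force <- function(point, domain, k, radius = 0) {
  d <- as_domain(domain)
  stopifnot(k >= 0, radius >= 0, radius < d$b)
  cpp_confinement_force(point[1], point[2], d$a, d$b, k, radius)
}

#' Soft excluded-volume force between two circular bodies
#'
#' Zero when the centers are at least `rA + rB` apart; otherwise an
#' equal-and-opposite repulsion of magnitude `k * overlap` along the center
#' line. Coincident centers fall back to the +x axis deterministically.
#'
#' @param posA,posB Numeric (x, y) centers, um.
#' @param rA,rB Radii, um.
#' @param k Steric stiffness, pN/um.
#' @return List with `fA` and `fB`, the force vectors (pN) on each body
#'   (`fA == -fB`).
#' @export
steric_force <- function(posA, rA, posB, rB, k) {
  stopifnot(k >= 0, rA >= 0, rB >= 0)
  f <- cpp_steric_force(posA[1], posA[2], rA, posB[1], posB[2], rB, k)
  list(fA = f[1:2], fB = f[3:4])
}
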