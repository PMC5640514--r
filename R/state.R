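# State assembly: bodies, nucleation sites, NE motor anchors, cytoplasmic
# crosslinkers. Everything downstream (the compiled engine) consumes the
# plain-list layout produced here, so tests can also build custom states.

runif_in_ellipse <- function(n, a, b) {
  # rejection sampling from the bounding box
  xs <- numeric(n); ys <- numeric(n); got <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 16L)
    x <- runif(m, -a, a); y <- runif(m, -b, b)
    ok <- (x / a)^2 + (y / b)^2 <= 1
    take <- min(sum(ok), n - got)
    if (take > 0) {
      idx <- which(ok)[seq_len(take)]
      xs[got + seq_len(take)] <- x[idx]
      ys[got + seq_len(take)] <- y[idx]
      got <- got + take
    }
  }
  cbind(x = xs, y = ys)
}

# deterministic overdamped relaxation of body overlaps inside the reduced
# ellipse; returns updated positions or errors out
relax_bodies <- function(x, y, radius, domain, k = 100, max_iter = 5000,
                         tol = 1e-6) {
  n <- length(x)
  for (iter in seq_len(max_iter)) {
    fx <- numeric(n); fy <- numeric(n)
    worst <- 0
    if (n > 1) {
      for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
        dx <- x[j] - x[i]; dy <- y[j] - y[i]
        d <- sqrt(dx^2 + dy^2); rr <- radius[i] + radius[j]
        if (d < rr) {
          ov <- rr - d
          worst <- max(worst, ov)
          if (d < 1e-12) { dx <- 1; dy <- 0; d <- 1 }
          ux <- dx / d; uy <- dy / d
          fx[i] <- fx[i] - k * ov * ux; fy[i] <- fy[i] - k * ov * uy
          fx[j] <- fx[j] + k * ov * ux; fy[j] <- fy[j] + k * ov * uy
        }
      }
    }
    for (i in seq_len(n)) {
      f <- cpp_confinement_force(x[i], y[i], domain$a, domain$b, k, radius[i])
      fx[i] <- fx[i] + f[1]; fy[i] <- fy[i] + f[2]
      pen <- sqrt(sum(f^2)) / k
      worst <- max(worst, pen)
    }
    if (worst < tol) return(cbind(x = x, y = y))
    # displacement 0.2 * overlap per iteration (stable relaxation)
    x <- x + 0.2 * fx / k
    y <- y + 0.2 * fy / k
  }
  stop("cannot place bodies without overlap after ", max_iter,
       " relaxation iterations")
}

#' Initialize a simulation state
#'
#' Builds the complete initial state for one simulated myotube: `n` nuclei
#' clustered around the domain center (made overlap-free by deterministic
#' steric relaxation), centrosome-like bodies (when NE nucleation is off)
#' placed uniformly at random, nucleation sites and motor anchors sampled
#' uniformly on body surfaces, cytoplasmic crosslinkers scattered uniformly,
#' and no microtubules at `t = 0`. All randomness is drawn from R's RNG, so
#' `set.seed()` (or the `seed` argument) makes the state reproducible
#' bit-for-bit.
#'
#' @param condition A [make_condition()] object or condition name.
#' @param params A [simulation_params()] list.
#' @param seed Optional integer; when given, `set.seed(seed)` is called
#'   first.
#' @return An object of class `simulation_state`: a plain list with elements
#'   `domain`, `condition`, `params`, `bodies`, `sites`, `anchors`, `links`,
#'   `mts`, `pool`, `time`.
#' @export
#' @examples
#' st <- initialize_state("control", simulation_params(nucleus_count = 5), seed = 1)
#' table(st$bodies$kind)
initialize_state <- function(condition = "control",
                             params = simulation_params(),
                             seed = NULL) {
  if (is.character(condition)) condition <- make_condition(condition)
  stopifnot(inherits(condition, "condition_spec"))
  validate_params(params)
  if (!is.null(seed)) set.seed(seed)
  n <- params$nucleus_count
  domain <- make_domain(n)
  if (params$nucleus_radius >= domain$b)
    stop("nucleus_radius must be smaller than the domain half-width")

  # nuclei: tight overlapping cluster at the center, then relaxed
  x0 <- (seq_len(n) - (n + 1) / 2) * (0.5 * params$nucleus_radius)
  y0 <- runif(n, -0.5, 0.5)
  pos <- relax_bodies(x0, y0, rep(params$nucleus_radius, n), domain,
                      k = max(params$steric_k, 1))
  gamma_nuc <- 6 * pi * params$viscosity * params$nucleus_radius
  bodies <- data.frame(
    kind = rep("nucleus", n), x = pos[, "x"], y = pos[, "y"],
    radius = params$nucleus_radius, drag = gamma_nuc,
    nucleates = condition$ne_nucleation,
    stringsAsFactors = FALSE)

  n_cen <- if (condition$ne_nucleation) 0L
           else as.integer(round(condition$centrosomes_per_nucleus * n))
  if (n_cen > 0) {
    cp <- runif_in_ellipse(n_cen, domain$a - params$centrosome_radius,
                           domain$b - params$centrosome_radius)
    bodies <- rbind(bodies, data.frame(
      kind = rep("centrosome", n_cen), x = cp[, "x"], y = cp[, "y"],
      radius = params$centrosome_radius,
      drag = 6 * pi * params$viscosity * params$centrosome_radius,
      nucleates = TRUE, stringsAsFactors = FALSE))
  }
  rownames(bodies) <- NULL

  # nucleation sites: fixed surface points, uniform angles; the per-body site
  # count enforces the MT cap
  nsite <- params$max_mts_per_nucleus
  site_body <- integer(0); site_angle <- numeric(0); site_active <- logical(0)
  for (i in seq_len(nrow(bodies))) {
    site_body <- c(site_body, rep(i, nsite))
    site_angle <- c(site_angle, runif(nsite, 0, 2 * pi))
    site_active <- c(site_active, rep(bodies$nucleates[i], nsite))
  }
  sites <- data.frame(body = site_body, angle = site_angle,
                      active = site_active)

  # NE motor anchors, uniform on each nuclear surface
  anc_body <- integer(0); anc_angle <- numeric(0); anc_species <- character(0)
  for (i in seq_len(n)) {
    if (isTRUE(params$dynein_retained)) {
      anc_body <- c(anc_body, rep(i, params$n_dynein_per_nucleus))
      anc_angle <- c(anc_angle, runif(params$n_dynein_per_nucleus, 0, 2 * pi))
      anc_species <- c(anc_species, rep("dynein", params$n_dynein_per_nucleus))
    }
    if (condition$ne_kif5b) {
      anc_body <- c(anc_body, rep(i, params$n_kif5b_per_nucleus))
      anc_angle <- c(anc_angle, runif(params$n_kif5b_per_nucleus, 0, 2 * pi))
      anc_species <- c(anc_species, rep("kif5b", params$n_kif5b_per_nucleus))
    }
  }
  anchors <- data.frame(body = anc_body, angle = anc_angle,
                        species = anc_species, stringsAsFactors = FALSE)

  # cytoplasmic crosslinkers, uniform in the cell
  nl <- params$n_map4 + params$n_map7kif5b
  lp <- if (nl > 0) runif_in_ellipse(nl, domain$a, domain$b) else
    cbind(x = numeric(0), y = numeric(0))
  links <- data.frame(
    species = c(rep("map4", params$n_map4),
                rep("map7kif5b", params$n_map7kif5b)),
    x = lp[, "x"], y = lp[, "y"], stringsAsFactors = FALSE)

  mts <- data.frame(site = integer(0), x = numeric(0), y = numeric(0),
                    dir_x = numeric(0), dir_y = numeric(0),
                    length = numeric(0), state = character(0),
                    stringsAsFactors = FALSE)

  structure(
    list(domain = domain, condition = condition, params = params,
         bodies = bodies, sites = sites, anchors = anchors, links = links,
         mts = mts,
         pool = list(L_max = params$tubulin_pool_Lmax, L_polymerized = 0),
         time = 0),
    class = "simulation_state")
}

#' @export
print.simulation_state <- function(x, ...) {
  cat(sprintf("<simulation_state> t = %g s, %s, %d bodies (%d nuclei), %d sites, %d anchors, %d crosslinkers, %d MTs\n",
              x$time, x$condition$name, nrow(x$bodies),
              sum(x$bodies$kind == "nucleus"), nrow(x$sites),
              nrow(x$anchors), nrow(x$links), nrow(x$mts)))
  invisible(x)
}
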