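# Event-loop driver. The per-step order inside the compiled engine is fixed:
# force accumulation -> Langevin motion -> MT plus-end dynamics ->
# connector kinetics (walk, detach, attach) -> nucleation.

.species_code <- c(dynein = 0L, kif5b = 1L, map4 = 2L, map7kif5b = 3L)

state_for_engine <- function(state) {
  stopifnot(inherits(state, "simulation_state"))
  p <- state$params
  kind <- match(state$bodies$kind, c("nucleus", "centrosome")) - 1L
  mt_state <- if (nrow(state$mts)) ifelse(state$mts$state == "growing", 1L, -1L)
              else integer(0)
  list(
    a = state$domain$a, b = state$domain$b,
    params = lapply(unclass(p)[setdiff(names(p), "dynein_retained")], as.numeric),
    body_kind = kind,
    body_x = as.numeric(state$bodies$x), body_y = as.numeric(state$bodies$y),
    body_radius = as.numeric(state$bodies$radius),
    body_drag = as.numeric(state$bodies$drag),
    body_nucleates = as.integer(state$bodies$nucleates),
    site_body = as.integer(state$sites$body) - 1L,
    site_angle = as.numeric(state$sites$angle),
    site_active = as.integer(state$sites$active),
    anchor_body = as.integer(state$anchors$body) - 1L,
    anchor_angle = as.numeric(state$anchors$angle),
    anchor_species = unname(.species_code[state$anchors$species]),
    link_species = unname(.species_code[state$links$species]),
    link_x = as.numeric(state$links$x), link_y = as.numeric(state$links$y),
    mt_site = as.integer(state$mts$site) - 1L,  # -1 for unanchored (site 0)
    mt_x = as.numeric(state$mts$x), mt_y = as.numeric(state$mts$y),
    mt_dir_x = as.numeric(state$mts$dir_x),
    mt_dir_y = as.numeric(state$mts$dir_y),
    mt_length = as.numeric(state$mts$length),
    mt_state = mt_state,
    pool_Lmax = state$pool$L_max,
    pool_Lpoly = state$pool$L_polymerized,
    time = state$time)
}

#' Run a simulation
#'
#' Integrates a [initialize_state()] state forward by `duration` seconds with
#' the compiled Langevin engine, recording body positions every
#' `frame_stride` steps. The run is a pure function of (state, duration,
#' RNG state): seeding the RNG identically reproduces it exactly.
#'
#' @param state A `simulation_state`.
#' @param duration Simulated time, s (>= 0; 0 records the initial frame only).
#' @param frame_stride Record a trajectory frame every this many steps
#'   (default 100, i.e. 1 s at the default `dt`).
#' @param seed Optional integer passed to `set.seed()` before running.
#' @return An object of class `simulation_result`: list with `nuclei` (final
#'   nuclear positions, data.frame), `bodies`, `frames` (matrix: time then
#'   x,y per body), `mts` (final fiber polylines and states), `events`
#'   (counts of nucleations, catastrophes, removals, attachments, ...),
#'   `pool`, `diagnostics` (conservation error, internal-force balance,
#'   max step displacement), `sf` (spreading factor of the final nuclei),
#'   `condition` and `domain`.
#' @export
#' @examples
#' p <- simulation_params(duration = 1)
#' st <- initialize_state("control", p, seed = 1)
#' res <- run_simulation(st, duration = 1)
#' res$sf
run_simulation <- function(state, duration = state$params$duration,
                           frame_stride = 100, seed = NULL) {
  stopifnot(inherits(state, "simulation_state"), duration >= 0,
            frame_stride >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- engine_run(state_for_engine(state), as.numeric(duration),
                    as.integer(frame_stride))
  nuc <- which(state$bodies$kind == "nucleus")
  L <- 2 * state$domain$a
  nuclei <- data.frame(
    nucleus_index = seq_along(nuc),
    x_um = out$body_x[nuc] + state$domain$a,  # axial position in [0, L]
    y_um = out$body_y[nuc])
  sfv <- if (length(nuc) >= 3) spreading_factor(nuclei$x_um, L) else NA_real_
  bodies <- state$bodies
  bodies$x <- out$body_x; bodies$y <- out$body_y
  structure(
    list(nuclei = nuclei, bodies = bodies, frames = out$frames,
         mts = list(x = out$mt_x, y = out$mt_y, length = out$mt_length,
                    state = c("shrinking", "", "growing")[out$mt_state + 2L],
                    site = out$mt_site + 1L),
         events = out$events, pool = out$pool,
         diagnostics = out$diagnostics,
         connectors = out$connectors,
         connectors_detail = list(anchor_mt = out$anchor_mt),
         sf = sfv, myotube_length_um = L,
         condition = state$condition, domain = state$domain,
         params = state$params, duration = duration),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %s, %g s, %d nuclei, SF = %.3f\n",
              x$condition$name, x$duration, nrow(x$nuclei), x$sf))
  cat(sprintf("  events: %d nucleations, %d catastrophes, %d removals\n",
              x$events[["nucleations"]], x$events[["catastrophes"]],
              x$events[["removals"]]))
  invisible(x)
}

#' Simulate one myotube end to end
#'
#' Convenience wrapper: seeds the RNG, builds the initial state for a
#' condition and runs it.
#'
#' @inheritParams initialize_state
#' @inheritParams run_simulation
#' @param nucleus_count Number of nuclei (overrides `params$nucleus_count`).
#' @return A `simulation_result` (see [run_simulation()]).
#' @export
simulate_myotube <- function(condition = "control",
                             nucleus_count = NULL,
                             params = simulation_params(),
                             duration = params$duration,
                             seed = params$seed,
                             frame_stride = 100) {
  if (!is.null(nucleus_count))
    params <- simulation_params(.overrides = utils::modifyList(
      unclass(params)[names(default_params())],
      list(nucleus_count = nucleus_count)))
  set.seed(seed)
  st <- initialize_state(condition, params)
  run_simulation(st, duration = duration, frame_stride = frame_stride)
}

#' Run a seeded ensemble across conditions
#'
#' Runs `n_replicates` independent simulations per condition, cycling the
#' nucleus count round-robin through `nucleus_counts` (5-9 by default, the
#' tabulated geometries). Replicate `r` uses its own RNG stream seeded as
#' `seed + r` in every condition, so each replicate is individually
#' reproducible, results are independent of execution order, and the
#' conditions are compared on matched initial configurations.
#'
#' @param conditions Character vector of condition names (see
#'   [make_condition()]).
#' @param n_replicates Replicates per condition (>= 1).
#' @param nucleus_counts Integer vector cycled across replicates.
#' @param params Base [simulation_params()] (its `nucleus_count` is
#'   overridden per replicate).
#' @param seed Base seed.
#' @param duration Simulated seconds per replicate.
#' @return An object of class `ensemble_result`: list with `sf` (one row per
#'   replicate: condition, replicate, seed, nucleus_count,
#'   myotube_length_um, sf) and `positions` (one row per nucleus:
#'   replicate, condition, myotube_length_um, nucleus_index, x_um).
#' @export
#' @examples
#' \donttest{
#' ens <- run_ensemble(c("control", "no_ne_nucleation"), n_replicates = 2,
#'                     params = simulation_params(duration = 5), seed = 1)
#' ens$sf
#' }
run_ensemble <- function(conditions = c("control", "no_ne_nucleation",
                                        "no_ne_nucleation_no_kif5b"),
                         n_replicates = 20,
                         nucleus_counts = 5:9,
                         params = simulation_params(),
                         seed = params$seed,
                         duration = params$duration) {
  stopifnot(n_replicates >= 1, length(nucleus_counts) >= 1)
  sf_rows <- list(); pos_rows <- list(); k <- 0L
  base <- unclass(params)[names(default_params())]
  for (cond in conditions) {
    for (r in seq_len(n_replicates)) {
      k <- k + 1L
      nn <- nucleus_counts[((r - 1L) %% length(nucleus_counts)) + 1L]
      p_r <- simulation_params(.overrides = utils::modifyList(
        base, list(nucleus_count = as.numeric(nn))))
      res <- simulate_myotube(cond, params = p_r, duration = duration,
                              seed = seed + r, frame_stride = 10000L)
      sf_rows[[k]] <- data.frame(
        condition = cond, replicate = r, seed = seed + r,
        nucleus_count = nn, myotube_length_um = res$myotube_length_um,
        sf = res$sf, stringsAsFactors = FALSE)
      pos_rows[[k]] <- data.frame(
        replicate = r, condition = cond,
        myotube_length_um = res$myotube_length_um,
        nucleus_index = res$nuclei$nucleus_index,
        x_um = res$nuclei$x_um, stringsAsFactors = FALSE)
    }
  }
  structure(list(sf = do.call(rbind, sf_rows),
                 positions = do.call(rbind, pos_rows),
                 seed = seed, duration = duration),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat("<ensemble_result> ", nrow(x$sf), " replicates, ",
      length(unique(x$sf$condition)), " condition(s), duration ",
      x$duration, " s\n", sep = "")
  agg <- aggregate(sf ~ condition, x$sf, function(v) round(mean(v), 3))
  print(agg, row.names = FALSE)
  invisible(x)
}
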