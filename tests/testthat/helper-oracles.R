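# Independent oracles used across tests. These deliberately avoid the
# package's own implementation paths.

# exact two-sided Mann-Whitney p by enumeration of all group-A index
# choices from the pooled sample (no ties assumed)
mw_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  nA <- length(a)
  idx <- utils::combn(length(pooled), nA)
  u_of <- function(ii) {
    av <- pooled[ii]; bv <- pooled[-ii]
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  }
  u_all <- apply(idx, 2, u_of)
  u_obs <- u_of(seq_len(nA))
  mu <- nA * (length(pooled) - nA) / 2
  # two-sided: as or more extreme in distance from the mean
  p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
  list(U = u_obs, p = p)
}

# brute-force mean all-pairs distance
mean_pair_dist_oracle <- function(x) {
  s <- 0; n <- length(x); np <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    s <- s + abs(x[i] - x[j]); np <- np + 1
  }
  s / np
}

# event-driven two-state (grow -> catastrophe -> shrink -> gone) fiber life
# with renucleation delay; returns lengths of live fibers at sample times
renewal_lengths_oracle <- function(v_grow, v_shrink, cat_rate, nuc_rate,
                                   t_end, sample_times) {
  t <- 0; len <- NA  # NA = site empty
  state <- "empty"
  t_next <- stats::rexp(1, nuc_rate)
  out <- numeric(0)
  si <- 1
  repeat {
    t_evt <- t + t_next
    while (si <= length(sample_times) && sample_times[si] < t_evt) {
      dt <- sample_times[si] - t
      out <- c(out, switch(state,
        empty = NA_real_,
        growing = len + v_grow * dt,
        shrinking = max(len - v_shrink * dt, NA)))
      si <- si + 1
    }
    if (si > length(sample_times) || t_evt > t_end) break
    if (state == "empty") {
      t <- t_evt; len <- 0; state <- "growing"
      t_next <- stats::rexp(1, cat_rate)
    } else if (state == "growing") {
      len <- len + v_grow * t_next
      t <- t_evt; state <- "shrinking"
      t_next <- len / v_shrink
    } else {
      t <- t_evt; len <- NA; state <- "empty"
      t_next <- stats::rexp(1, nuc_rate)
    }
  }
  out
}

# default small parameter set for fast engine tests
fast_params <- function(...) {
  simulation_params(.overrides = utils::modifyList(
    list(duration = 10), list(...)))
}
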