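#' Scheduled multiplicative perturbation of a base-production term
#'
#' Represents an in-silico intervention: at `time`, the base-production entry
#' `J[node]` is multiplied by `factor` (e.g. `factor = 0.5` halves the node's
#' constitutive drive, emulating a drug that blocks its upstream input). The
#' switch takes effect before the integration step leaving `time`; events
#' scheduled at the same instant are applied in the order given.
#'
#' @param time Event time, inside the simulation window.
#' @param node Node label (or 1-based index) whose `J` entry is switched.
#' @param factor Strictly positive multiplicative factor.
#' @param parameter Which constant is switched; only `"J"` is supported.
#' @return An object of class `perturbation_event`.
#' @export
#' @examples
#' perturbation_event(50, "AR", 0.5)  # androgen ablation
perturbation_event <- function(time, node, factor, parameter = "J") {
  if (!identical(parameter, "J"))
    stopf("only perturbations of J are supported (got parameter = '%s')",
          parameter)
  if (!is.finite(factor) || factor <= 0)
    stopf("perturbation factor must be finite and > 0 (got %s)",
          format(factor))
  if (!is.finite(time)) stopf("perturbation time must be finite")
  structure(list(time = as.numeric(time), node = node,
                 factor = as.numeric(factor), parameter = "J"),
            class = "perturbation_event")
}

# Normalise events (a perturbation_event, a list of them, or a data.frame
# with columns time/node/factor) to a validated data.frame with node indices.
resolve_events <- function(events, model, t_start, t_end) {
  if (is.null(events)) {
    return(data.frame(time = numeric(), node = character(),
                      index = integer(), factor = numeric()))
  }
  if (inherits(events, "perturbation_event")) events <- list(events)
  if (is.data.frame(events)) {
    events <- lapply(seq_len(nrow(events)), function(i)
      perturbation_event(events$time[i], events$node[i], events$factor[i]))
  }
  idx <- vapply(events, function(e) {
    if (is.character(e$node)) {
      i <- match(e$node, model$labels)
      if (is.na(i)) stopf("perturbation references unknown node '%s'", e$node)
      i
    } else {
      i <- as.integer(e$node)
      if (i < 1L || i > model$n)
        stopf("perturbation node index %d outside 1..%d", i, model$n)
      i
    }
  }, integer(1))
  tm <- vapply(events, `[[`, numeric(1), "time")
  if (any(tm < t_start | tm > t_end))
    stopf("perturbation times must lie within [%g, %g]", t_start, t_end)
  out <- data.frame(time = tm, node = model$labels[idx], index = idx,
                    factor = vapply(events, `[[`, numeric(1), "factor"))
  # stable sort: ties at equal time keep schedule order
  out[order(out$time), , drop = FALSE]
}

#' One positivity-clamped explicit Euler step
#'
#' Advances the state by
#' `max(0, x + dt * (J - d * x + A %*% x + sigma))`, the component-wise clamp
#' at zero implementing the positivity boundary condition: a node whose
#' unclamped update would turn negative is held at exactly zero until its net
#' production becomes positive again.
#'
#' @param x Current nonnegative activity vector.
#' @param model A [network_model()].
#' @param dt Time increment, > 0.
#' @param sigma Noise/forcing vector added to the rate (recycled; default 0).
#' @return The next activity vector (named by node).
#' @export
step_euler <- function(x, model, dt, sigma = 0) {
  stopifnot(inherits(model, "network_model"))
  x <- as.numeric(x)
  if (length(x) != model$n)
    stopf("state has length %d but the model has %d nodes", length(x), model$n)
  if (!all(is.finite(x))) {
    bad <- model$labels[!is.finite(x)]
    stopf("non-finite state for node(s): %s", paste(bad, collapse = ", "))
  }
  if (dt <= 0) stopf("dt must be > 0")
  rate <- model$J - model$d * x + drop(model$A %*% x) + sigma
  stats::setNames(pmax(0, x + dt * rate), model$labels)
}

#' Integrate a network model forward in time
#'
#' Fixed-step explicit (Newton-forward) Euler integration of the
#' almost-linear dynamics, with the state clamped at zero after every step,
#' optional uniform stochastic forcing, and scheduled multiplicative switches
#' of base-production terms. An event at time `t` takes effect before the
#' step from `t` to `t + dt`.
#'
#' Noise, when `noise_amplitude > 0`, is redrawn independently for every node
#' at every step from `uniform(-noise_amplitude, +noise_amplitude)`. With a
#' non-NULL `seed` the trajectory is fully reproducible and the caller's RNG
#' state is left untouched.
#'
#' @param model A [network_model()].
#' @param x0 Initial activity vector (nonnegative), length `model$n`.
#' @param t_end End of the simulation window.
#' @param t_start Start of the window (default 0).
#' @param dt Time increment (default 0.001).
#' @param noise_amplitude Half-width of the uniform noise term added to each
#'   rate (activity per unit time); 0 disables noise.
#' @param seed Integer RNG seed, or NULL to use the current RNG stream.
#' @param events Perturbation schedule: a [perturbation_event()], a list of
#'   them, or a data.frame with columns `time`, `node`, `factor`.
#' @param output_stride Store every k-th step (default 100, i.e. every 0.1
#'   time units at `dt = 0.001`); use 1 for full resolution.
#' @return An object of class `network_trajectory`: `times` (stored time
#'   stamps), `states` (matrix, rows = time points, columns = nodes, all
#'   entries >= 0), `labels`, `events_applied` (data.frame of time, node, old
#'   and new `J` value), plus `dt`, `seed` and `noise_amplitude` metadata.
#' @export
#' @examples
#' tr <- simulate_network(ar_nfkb_model(), x0 = c(1, 1.2, 1.4, 1.6, 1.8, 2),
#'                        t_end = 5, dt = 0.01, output_stride = 10)
#' tail(as.data.frame(tr), 2)
simulate_network <- function(model, x0, t_end, t_start = 0, dt = 0.001,
                             noise_amplitude = 0, seed = NULL, events = NULL,
                             output_stride = 100) {
  stopifnot(inherits(model, "network_model"))
  if (dt <= 0) stopf("dt must be > 0")
  if (t_end <= t_start) stopf("t_end must exceed t_start")
  if (noise_amplitude < 0) stopf("noise_amplitude must be >= 0")
  output_stride <- as.integer(output_stride)
  if (output_stride < 1L) stopf("output_stride must be >= 1")
  x0 <- as.numeric(x0)
  if (length(x0) != model$n)
    stopf("x0 has length %d but the model has %d nodes", length(x0), model$n)
  if (!all(is.finite(x0)) || any(x0 < 0))
    stopf("x0 must be finite and nonnegative")

  nsteps <- as.integer(round((t_end - t_start) / dt))
  if (nsteps < 1L) stopf("window shorter than one step")
  ev <- resolve_events(events, model, t_start, t_end)
  ev_step <- as.integer(round((ev$time - t_start) / dt))

  noise <- NULL
  if (noise_amplitude > 0) {
    # row k = the per-node draws for step k; row-major fill reproduces
    # per-step, per-node sequential draws
    noise <- with_seed_or_global(seed, matrix(
      stats::runif(nsteps * model$n, -noise_amplitude, noise_amplitude),
      nrow = nsteps, ncol = model$n, byrow = TRUE))
  }

  B <- model$A - diag(model$d, model$n)
  Jc <- unname(model$J)
  x <- x0

  keep <- seq.int(0L, nsteps, by = output_stride)
  states <- matrix(NA_real_, length(keep), model$n,
                   dimnames = list(NULL, model$labels))
  states[1L, ] <- x
  out_row <- 1L

  applied <- ev[0, c("time", "node")]
  applied$old <- numeric(0); applied$new <- numeric(0)
  next_ev <- 1L

  for (k in seq_len(nsteps)) {
    while (next_ev <= nrow(ev) && ev_step[next_ev] == k - 1L) {
      i <- ev$index[next_ev]
      old <- Jc[i]
      Jc[i] <- old * ev$factor[next_ev]
      applied <- rbind(applied, data.frame(
        time = ev$time[next_ev], node = ev$node[next_ev],
        old = old, new = Jc[i]))
      next_ev <- next_ev + 1L
    }
    rate <- Jc + drop(B %*% x)
    if (!is.null(noise)) rate <- rate + noise[k, ]
    x <- x + dt * rate
    x[x < 0] <- 0
    if (!all(is.finite(x)))
      stopf("integration diverged (non-finite state) at t = %g",
            t_start + k * dt)
    if (k %% output_stride == 0L) {
      out_row <- out_row + 1L
      states[out_row, ] <- x
    }
  }

  structure(
    list(times = t_start + keep * dt, states = states, labels = model$labels,
         events_applied = applied, dt = dt, seed = seed,
         noise_amplitude = noise_amplitude),
    class = "network_trajectory")
}

#' @export
print.network_trajectory <- function(x, ...) {
  cat(sprintf("<network_trajectory> %d stored points, t in [%g, %g], dt = %g\n",
              length(x$times), x$times[1], x$times[length(x$times)], x$dt))
  if (nrow(x$events_applied))
    cat(sprintf("  %d perturbation(s) applied\n", nrow(x$events_applied)))
  cat("final state:\n")
  print(round(x$states[nrow(x$states), ], 4))
  invisible(x)
}

#' @export
as.data.frame.network_trajectory <- function(x, ...) {
  cbind(data.frame(time = x$times), as.data.frame(x$states))
}

#' Per-node mean activity over time windows
#'
#' Summarises a trajectory into regime averages: for each half-open window
#' `[t_lo, t_hi)` the arithmetic mean of the stored states per node.
#'
#' @param traj A [simulate_network()] trajectory.
#' @param windows A list of `c(t_lo, t_hi)` pairs or a 2-column matrix, all
#'   within the stored time range.
#' @return Matrix, rows = windows (named `[lo,hi)`), columns = nodes.
#' @export
phase_summary <- function(traj, windows) {
  stopifnot(inherits(traj, "network_trajectory"))
  if (is.matrix(windows))
    windows <- lapply(seq_len(nrow(windows)), function(i) windows[i, ])
  out <- vapply(windows, function(w) {
    if (length(w) != 2L || w[2] <= w[1])
      stopf("each window must be c(t_lo, t_hi) with t_hi > t_lo")
    sel <- traj$times >= w[1] & traj$times < w[2]
    if (!any(sel))
      stopf("window [%g, %g) contains no stored time points", w[1], w[2])
    colMeans(traj$states[sel, , drop = FALSE])
  }, numeric(length(traj$labels)))
  out <- t(out)
  rownames(out) <- vapply(windows, function(w)
    sprintf("[%g,%g)", w[1], w[2]), character(1))
  out
}
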