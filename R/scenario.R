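#' Three-phase in-silico drug scenario on the AR/NF-kB network
#'
#' Runs the canonical perturbation experiment on [ar_nfkb_model()]: starting
#' from `x(0) = (1, 1.2, 1.4, 1.6, 1.8, 2)`, the system relaxes to its fixed
#' point, then three treatments are applied in sequence, each halving one
#' base-production term:
#'
#' * `t = 50`: androgen ablation — `J[AR]` switched from 1.5 to 0.75;
#' * `t = 100`: NF-kB inhibition — `J[p65]` switched from 2 to 1;
#' * `t = 150`: PI3K inhibition — `J[PI3K]` switched from 2 to 1.
#'
#' Each regime is summarised by its late-window mean (the final 40% of the
#' regime, excluding the post-switch transient): `[80, 100)`, `[130, 150)`
#' and the final 40% of `[150, t_end]`. The pre-treatment baseline is the
#' mean over `[40, 50)`, which for a converged system equals the fixed point.
#'
#' @param seed RNG seed for the noise term, or NULL.
#' @param t_end Simulation horizon, must exceed 150 so the third regime is
#'   observable (default 200, giving every regime 50 time units).
#' @param noise_amplitude Uniform noise half-width (default 0: deterministic).
#' @param dt Integration step (default 0.001).
#' @return An object of class `scenario_report`: `trajectory`, `baseline`
#'   (per-node), `regime_means` (3 x nodes matrix, late windows), `windows`,
#'   and `directions` (per-node sign of change across each transition at the
#'   default 1% relative tolerance).
#' @seealso [direction_check()] for the named directional claims.
#' @export
#' @examples
#' rep <- ablation_scenario(t_end = 200)
#' round(rep$regime_means[, c("p65", "cMyc")], 3)
ablation_scenario <- function(seed = NULL, t_end = 200, noise_amplitude = 0,
                              dt = 0.001) {
  if (t_end <= 150) stopf("t_end must exceed 150 (third regime starts there)")
  model <- ar_nfkb_model()
  events <- list(perturbation_event(50, "AR", 0.5),
                 perturbation_event(100, "p65", 0.5),
                 perturbation_event(150, "PI3K", 0.5))
  traj <- simulate_network(model, x0 = c(1, 1.2, 1.4, 1.6, 1.8, 2),
                           t_end = t_end, dt = dt,
                           noise_amplitude = noise_amplitude, seed = seed,
                           events = events)
  regimes <- rbind(c(50, 100), c(100, 150), c(150, t_end))
  late <- t(apply(regimes, 1, function(r) c(r[2] - 0.4 * (r[2] - r[1]), r[2])))
  baseline_w <- c(40, 50)
  means <- phase_summary(traj, rbind(baseline_w, late))
  baseline <- means[1, ]
  regime_means <- means[-1, , drop = FALSE]
  rownames(regime_means) <- c("post_AR_ablation", "post_NFkB_inhibition",
                              "post_PI3K_inhibition")
  report <- structure(
    list(trajectory = traj, baseline = baseline, regime_means = regime_means,
         windows = list(baseline = baseline_w, late = late),
         directions = NULL),
    class = "scenario_report")
  report$directions <- transition_directions(report, tolerance = 0.01)
  report
}

# Sign of change (up/down/flat) per node across baseline -> regime 1 ->
# regime 2 -> regime 3, "flat" when the relative change is within tolerance.
transition_directions <- function(report, tolerance) {
  lv <- rbind(report$baseline, report$regime_means)
  out <- matrix("flat", nrow(lv) - 1L, ncol(lv),
                dimnames = list(
                  paste(rownames(report$regime_means)),
                  colnames(lv)))
  for (i in seq_len(nrow(lv) - 1L)) {
    ref <- lv[i, ]
    delta <- lv[i + 1L, ] - ref
    thresh <- tolerance * pmax(abs(ref), .Machine$double.eps)
    out[i, delta > thresh] <- "up"
    out[i, delta < -thresh] <- "down"
  }
  out
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("<scenario_report>\n")
  cat("baseline [40,50):\n"); print(round(x$baseline, 4))
  cat("late-window regime means:\n"); print(round(x$regime_means, 4))
  invisible(x)
}

#' Evaluate the model's directional treatment-response claims
#'
#' Checks the four qualitative predictions of the three-phase scenario
#' against a [ablation_scenario()] report, using a relative tolerance to
#' separate genuine movement from numerical/stochastic flutter:
#'
#' * `nfkb_up_after_ar_ablation`: p65 rises above baseline after androgen
#'   ablation (and so does c-Myc: `cmyc_up_after_ar_ablation`) — AR blockade
#'   de-represses NF-kB and with it the oncogene;
#' * `cmyc_below_baseline_after_nfkb_inhibition`: after NF-kB inhibition
#'   c-Myc falls below its pre-ablation baseline;
#' * `cmyc_falls_further_after_pi3k_inhibition` and
#'   `nfkb_falls_further_after_pi3k_inhibition`: adding PI3K inhibition pushes
#'   c-Myc and p65 below their previous-regime levels.
#'
#' A comparison only counts as "up"/"down" when it exceeds
#' `tolerance * |reference|`; at `tolerance = 1` every comparison is flat and
#' every claim fails.
#'
#' @param report A `scenario_report`.
#' @param tolerance Relative tolerance for calling a change (default 0.01,
#'   matched to the default noise amplitude on O(1) activities).
#' @return A data.frame with columns `claim`, `node`, `comparison`, `pass`.
#' @export
#' @examples
#' direction_check(ablation_scenario())
direction_check <- function(report, tolerance = 0.01) {
  stopifnot(inherits(report, "scenario_report"))
  if (nrow(report$regime_means) < 3L)
    stopf("report is missing regimes: need all three post-treatment regimes")
  m <- report$regime_means
  b <- report$baseline
  cmp <- function(a, ref, dir) {
    thr <- tolerance * max(abs(ref), .Machine$double.eps)
    if (dir == "up") a - ref > thr else ref - a > thr
  }
  data.frame(
    claim = c("nfkb_up_after_ar_ablation",
              "cmyc_up_after_ar_ablation",
              "cmyc_below_baseline_after_nfkb_inhibition",
              "cmyc_falls_further_after_pi3k_inhibition",
              "nfkb_falls_further_after_pi3k_inhibition"),
    node = c("p65", "cMyc", "cMyc", "cMyc", "p65"),
    comparison = c("regime1 > baseline", "regime1 > baseline",
                   "regime2 < baseline", "regime3 < regime2",
                   "regime3 < regime2"),
    pass = c(cmp(m[1, "p65"], b["p65"], "up"),
             cmp(m[1, "cMyc"], b["cMyc"], "up"),
             cmp(m[2, "cMyc"], b["cMyc"], "down"),
             cmp(m[3, "cMyc"], m[2, "cMyc"], "down"),
             cmp(m[3, "p65"], m[2, "p65"], "down")),
    row.names = NULL)
}
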