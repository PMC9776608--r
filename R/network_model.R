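#' Construct a dynamic network model
#'
#' A network model is the tuple `(labels, J, d, A)` defining the almost-linear
#' system
#' \deqn{\frac{d}{dt} x_i = J_i - d_i x_i + \sum_j A_{ij} x_j + \sigma_i,}
#' where `J` is the base production of each node (activity per unit time), `d`
#' the first-order decay rate, and `A` the interaction matrix with `A[i, j]`
#' the per-unit effect of source node `j` on the rate of change of target node
#' `i`. The dynamics are "almost" linear because states are additionally
#' clamped at zero during integration (see [simulate_network()]).
#'
#' @param labels Character vector of unique node names.
#' @param J Numeric base-production vector, one entry per node. Entries may be
#'   negative (constitutive drain).
#' @param d Numeric decay-rate vector, strictly positive, one entry per node.
#' @param A Numeric n x n interaction matrix, row = target, column = source.
#' @return An object of class `network_model` with elements `labels`, `J`,
#'   `d`, `A` and `n`.
#' @seealso [ar_nfkb_model()] for the built-in six-node prostate-cancer model.
#' @export
#' @examples
#' m <- network_model(c("a", "b"), J = c(1, 2), d = c(1, 1),
#'                    A = matrix(0, 2, 2))
#' fixed_point(m)$x_star  # decoupled: x* = J / d
network_model <- function(labels, J, d, A) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n < 1L) stopf("a network model needs at least one node")
  if (anyDuplicated(labels))
    stopf("duplicate node labels: %s",
          paste(unique(labels[duplicated(labels)]), collapse = ", "))
  J <- as.numeric(J); d <- as.numeric(d)
  if (length(J) != n)
    stopf("length(J) is %d but there are %d labels", length(J), n)
  if (length(d) != n)
    stopf("length(d) is %d but there are %d labels", length(d), n)
  if (!all(is.finite(J))) stopf("J contains non-finite entries")
  if (!all(is.finite(d)) || any(d <= 0))
    stopf("all decay rates d must be finite and > 0")
  A <- as.matrix(A)
  if (!is.numeric(A) || nrow(A) != n || ncol(A) != n)
    stopf("A must be a numeric %dx%d matrix (got %dx%d)",
          n, n, nrow(A), ncol(A))
  if (!all(is.finite(A))) stopf("A contains non-finite entries")
  dimnames(A) <- list(labels, labels)
  structure(
    list(labels = labels, J = stats::setNames(J, labels),
         d = stats::setNames(d, labels), A = A, n = n),
    class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("<network_model> %d nodes: %s\n", x$n,
              paste(x$labels, collapse = ", ")))
  cat("J:", format(unname(x$J)), "\n")
  cat("d:", format(unname(x$d)), "\n")
  cat("A (row = target, column = source):\n")
  print(x$A, ...)
  invisible(x)
}

#' The six-node AR/PI3K/PTEN/NF-kB/IkB/c-Myc model
#'
#' Returns the hand-parameterised model of transcription-factor crosstalk in
#' prostate cancer cells: nodes AR, PI3K, PTEN, p65 (NF-kB), IkB and c-Myc,
#' with base production `J = (1.5, 2, -0.1, 2, -0.1, 0.8)`, a common decay
#' rate of 1 for all nodes, and an interaction matrix encoding (among others)
#' PTEN inhibition of PI3K, mutual p65/IkB negative feedback (p65 induces IkB,
#' IkB inhibits p65), AR repression of p65, and induction of c-Myc by PI3K and
#' p65. The interaction matrix is read row = target, column = source.
#'
#' The unperturbed system is stable (all eigenvalues of `A - diag(d)` have
#' negative real part) and has a strictly positive fixed point, so the
#' positivity clamp never engages at steady state.
#'
#' @return A [network_model()] with 6 nodes.
#' @export
#' @examples
#' m <- ar_nfkb_model()
#' fp <- fixed_point(m)
#' fp$stable && fp$feasible
ar_nfkb_model <- function() {
  labels <- c("AR", "PI3K", "PTEN", "p65", "IkB", "cMyc")
  A <- rbind(
    c(   0, -1.0, 0, 0.5,  0,  0.7),  # AR   <- PI3K (-), p65 (+), c-Myc (+)
    c(   0,  0.0, -2, 1.0,  0, -0.5), # PI3K <- PTEN (-), p65 (+), c-Myc (-)
    c(   0,  2.0,  0, 0.0,  0,  0.0), # PTEN <- PI3K (+)
    c(-0.9,  1.5,  0, 0.0, -3,  0.5), # p65  <- AR (-), PI3K (+), IkB (-), c-Myc (+)
    c(   0,  0.0,  0, 3.0,  0,  0.0), # IkB  <- p65 (+)  [negative feedback loop]
    c(   0,  0.5,  0, 1.0,  0,  0.0)) # cMyc <- PI3K (+), p65 (+)
  network_model(labels,
                J = c(1.5, 2, -0.1, 2, -0.1, 0.8),
                d = rep(1, 6),
                A = A)
}

#' Fixed point and linear stability of a network model
#'
#' Solves the steady state of the noise-free dynamics,
#' `(diag(d) - A) x* = J`, and reports the spectrum of the system matrix
#' `A - diag(d)`. The fixed point is `stable` when every eigenvalue has
#' strictly negative real part and `feasible` when every component of `x*` is
#' strictly positive (so the positivity clamp is inactive at equilibrium and
#' the linear analysis applies).
#'
#' @param model A [network_model()].
#' @param cond_limit Maximum acceptable condition number (kappa, 2-norm
#'   estimate) of `diag(d) - A`; beyond it the system is treated as having no
#'   unique fixed point. Default `1e12`.
#' @return An object of class `fixed_point` with `x_star` (named numeric),
#'   `eigenvalues` (complex), `stable`, `feasible`, and `condition_number`.
#' @export
#' @examples
#' fixed_point(ar_nfkb_model())
fixed_point <- function(model, cond_limit = 1e12) {
  stopifnot(inherits(model, "network_model"))
  M <- diag(model$d, model$n) - model$A
  rc <- rcond(M)
  kappa <- if (rc > 0) 1 / rc else Inf
  if (!is.finite(kappa) || kappa > cond_limit)
    stopf("no unique fixed point: diag(d) - A has condition number %.3g (limit %.3g)",
          kappa, cond_limit)
  x_star <- drop(solve(M, model$J))
  names(x_star) <- model$labels
  ev <- eigen(model$A - diag(model$d, model$n), only.values = TRUE)$values
  structure(
    list(x_star = x_star,
         eigenvalues = ev,
         stable = all(Re(ev) < 0),
         feasible = min(x_star) > 0,
         condition_number = kappa),
    class = "fixed_point")
}

#' @export
print.fixed_point <- function(x, ...) {
  cat("<fixed_point>\n")
  print(round(x$x_star, 6))
  cat("eigenvalue real parts:", format(Re(x$eigenvalues), digits = 4), "\n")
  cat(sprintf("stable: %s   feasible (all x* > 0): %s\n",
              x$stable, x$feasible))
  invisible(x)
}

#' Rescale the activity units of a network model
#'
#' Applies the per-node change of units `y_i(t) = lam_i * x_i(t)`. For the
#' scaled trajectory to satisfy the same form of dynamics, the parameters must
#' transform as `J'_i = lam_i J_i`, `A'_ij = lam_i A_ij / lam_j`, and
#' `d'_i = d_i`: substituting `x_i = y_i / lam_i` into the rate equation
#' leaves the decay term `-d_i y_i` unchanged, so decay rates are invariant
#' under node-wise rescaling (they are in units of inverse time, not
#' activity). Diagonal interaction entries are likewise invariant.
#'
#' @param model A [network_model()].
#' @param lam Strictly positive numeric vector of per-node scale factors
#'   (dimensionless), length `model$n`.
#' @return The rescaled `network_model`.
#' @export
#' @examples
#' m <- ar_nfkb_model()
#' scale_model(m, rep(1, 6))  # identity
scale_model <- function(model, lam) {
  stopifnot(inherits(model, "network_model"))
  lam <- as.numeric(lam)
  if (length(lam) != model$n)
    stopf("lam has length %d but the model has %d nodes", length(lam), model$n)
  if (!all(is.finite(lam)) || any(lam <= 0))
    stopf("all scale factors must be finite and > 0")
  network_model(model$labels,
                J = lam * model$J,
                d = model$d,
                A = model$A * outer(lam, 1 / lam))
}
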