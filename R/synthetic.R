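#' Declare a planted gene set for the synthetic generator
#'
#' @param set A [gene_set()].
#' @param delta Expression shift (in expression units, i.e. multiples of
#'   `base_sd` when `base_sd = 1`) applied to the set's genes in group B.
#' @param direction `"up"` (group B higher) or `"down"`.
#' @return A list of class `planted_set`.
#' @export
planted_set <- function(set, delta, direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(inherits(set, "gene_set"))
  if (!is.finite(delta) || delta < 0) stopf("delta must be finite and >= 0")
  structure(list(set = set, delta = as.numeric(delta), direction = direction),
            class = "planted_set")
}

#' Specification of a synthetic two-group expression experiment
#'
#' Defines a gene universe and a two-group design (A = control, B = treated)
#' with independent Gaussian expression
#' `Normal(base_mean + delta_g * [sample in B], base_sd)`, where `delta_g` is
#' the signed shift of any planted gene set containing gene `g` (zero
#' elsewhere). This emulates the structure of a castration-vs-sham or
#' treated-vs-control comparison with a known enriched pathway, giving every
#' enrichment-stage operation a ground truth to recover.
#'
#' The default spec plants a single 50-gene upregulated set with shift 2 in a
#' 2000-gene universe, 10 samples per group.
#'
#' @param n_genes Universe size (default 2000).
#' @param n_per_group Samples per condition, at least 2 (default 10).
#' @param planted_sets List of [planted_set()] declarations; members must lie
#'   in the universe. Overlapping sets must agree in direction (their shifts
#'   add); conflicting overlaps are rejected. NULL plants the default set.
#' @param base_mean Background mean expression, log2-scale-like (default 7).
#' @param base_sd Background standard deviation, > 0 (default 1).
#' @param seed Integer seed (default 1).
#' @return A list of class `synthetic_spec` (fields as above plus `genes`,
#'   the universe identifiers).
#' @export
#' @examples
#' sp <- synthetic_spec()
#' sp$planted_sets[[1]]$set
synthetic_spec <- function(n_genes = 2000, n_per_group = 10,
                           planted_sets = NULL, base_mean = 7, base_sd = 1,
                           seed = 1) {
  if (n_genes < 2) stopf("n_genes must be at least 2")
  if (n_per_group < 2) stopf("n_per_group must be at least 2")
  if (base_sd <= 0) stopf("base_sd must be > 0")
  genes <- sprintf("g%05d", seq_len(n_genes))
  if (is.null(planted_sets)) {
    planted_sets <- list(planted_set(
      gene_set("planted_up", genes[seq_len(min(50, n_genes %/% 2))],
               "synthetic planted upregulated set"),
      delta = 2, direction = "up"))
  }
  for (ps in planted_sets) {
    if (!inherits(ps, "planted_set"))
      stopf("planted_sets must be a list of planted_set() objects")
    outside <- setdiff(ps$set$members, genes)
    if (length(outside))
      stopf("planted set '%s' has members outside the universe: %s",
            ps$set$name, paste(utils::head(outside, 5), collapse = ", "))
  }
  # conflicting-direction overlap is an error; same-direction shifts add
  if (length(planted_sets) > 1) {
    for (i in seq_along(planted_sets)) for (j in seq_len(i - 1)) {
      ov <- intersect(planted_sets[[i]]$set$members,
                      planted_sets[[j]]$set$members)
      if (length(ov) &&
          planted_sets[[i]]$direction != planted_sets[[j]]$direction)
        stopf("planted sets '%s' and '%s' overlap with conflicting directions",
              planted_sets[[i]]$set$name, planted_sets[[j]]$set$name)
    }
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_per_group = as.integer(n_per_group),
                 planted_sets = planted_sets, base_mean = base_mean,
                 base_sd = base_sd, seed = seed, genes = genes),
            class = "synthetic_spec")
}

# signed per-gene shift implied by the planted sets
planted_delta <- function(spec) {
  delta <- stats::setNames(numeric(spec$n_genes), spec$genes)
  for (ps in spec$planted_sets) {
    s <- if (ps$direction == "up") ps$delta else -ps$delta
    delta[ps$set$members] <- delta[ps$set$members] + s
  }
  delta
}

#' Draw a synthetic two-group expression matrix
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `expr` (genes x samples matrix, rownames = genes,
#'   colnames `A1..An, B1..Bn`), `groups` (factor of `"A"`/`"B"` per
#'   sample), and `truth` (data.frame of planted genes and their signed
#'   shifts). Deterministic under the spec's seed; the caller's RNG state is
#'   not disturbed.
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  delta <- planted_delta(spec)
  n_s <- 2L * spec$n_per_group
  groups <- factor(rep(c("A", "B"), each = spec$n_per_group))
  shift <- outer(delta, as.integer(groups == "B"))
  expr <- spec$base_mean + shift + with_seed_or_global(spec$seed,
    matrix(stats::rnorm(spec$n_genes * n_s, 0, spec$base_sd),
           spec$n_genes, n_s))
  dimnames(expr) <- list(spec$genes,
                         paste0(rep(c("A", "B"), each = spec$n_per_group),
                                seq_len(spec$n_per_group)))
  truth <- data.frame(gene = names(delta)[delta != 0],
                      delta = unname(delta[delta != 0]),
                      stringsAsFactors = FALSE)
  list(expr = expr, groups = groups, truth = truth)
}

#' Per-gene Welch t-test table from a synthetic draw
#'
#' Generates an expression matrix from the spec and performs a per-gene
#' two-sided Welch (unequal-variance) t-test of group B against group A.
#' The reported `log2fc` is `mean(B) - mean(A)` (the values are already on a
#' log-like scale), and `adj_p` is the BH adjustment of the raw p-values.
#'
#' @param spec A [synthetic_spec()].
#' @return A [de_table()] with attribute `truth` (the planted genes and
#'   shifts).
#' @export
generate_de_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dr <- generate_expression(spec)
  a <- dr$expr[, dr$groups == "A", drop = FALSE]
  b <- dr$expr[, dr$groups == "B", drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p <- pmax(p, .Machine$double.xmin)  # never emit p = 0
  out <- de_table(rownames(dr$expr), log2fc = mb - ma, p = p,
                  adj_p = pmax(bh_adjust(p), p))
  attr(out, "truth") <- dr$truth
  out
}

#' Group-wise gene-set activity scores from a synthetic draw
#'
#' Draws an expression matrix, computes [set_activity_scores()] for a
#' planted set, and splits the per-sample scores by group — the synthetic
#' analogue of comparing pathway-activity violin plots between castrated and
#' sham-operated animals.
#'
#' @param spec A [synthetic_spec()].
#' @param set A [gene_set()] that is planted in `spec` (matched by name).
#' @return A list with numeric score vectors `a` and `b`.
#' @export
generate_activity_groups <- function(spec, set) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(set, "gene_set"))
  planted_names <- vapply(spec$planted_sets, function(ps) ps$set$name,
                          character(1))
  if (!set$name %in% planted_names)
    stopf("gene set '%s' is not planted in this spec (planted: %s)",
          set$name, paste(planted_names, collapse = ", "))
  dr <- generate_expression(spec)
  sc <- set_activity_scores(dr$expr, set)
  list(a = sc[dr$groups == "A"], b = sc[dr$groups == "B"])
}
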