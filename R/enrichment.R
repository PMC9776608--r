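#' Gene set container
#'
#' @param name Set name (scalar character).
#' @param members Character vector of gene identifiers; duplicates are
#'   removed with a warning. Identifiers are opaque, case-sensitive strings.
#' @param description Free-text description (default empty).
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, members, description = "") {
  members <- as.character(members)
  if (length(members) == 0L) stopf("gene set '%s' has no members", name)
  if (anyDuplicated(members)) {
    warnf("gene set '%s': removed %d duplicate member(s)",
          name, sum(duplicated(members)))
    members <- unique(members)
  }
  structure(list(name = as.character(name),
                 description = as.character(description),
                 members = members),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s (%d members)\n", x$name, length(x$members)))
  invisible(x)
}

#' Differential-expression table
#'
#' Builds and validates the per-gene record feeding the ranking, filtering
#' and enrichment stages: gene identifier, log2 fold-change, raw p-value in
#' (0, 1], and optionally a BH-adjusted p-value (which can never fall below
#' the raw p). p-values of exactly 0 are rejected rather than clamped.
#'
#' @param gene Character vector of unique gene identifiers.
#' @param log2fc Numeric log2 fold-changes.
#' @param p Raw p-values in (0, 1].
#' @param adj_p Optional adjusted p-values; `NA` marks "not yet adjusted".
#' @return A data.frame of class `de_table` with those four columns.
#' @seealso [bh_adjust()], [deg_filter()], [build_ranked_list()]
#' @export
de_table <- function(gene, log2fc, p, adj_p = NULL) {
  gene <- as.character(gene)
  if (anyDuplicated(gene))
    stopf("duplicate gene identifiers: %s",
          paste(utils::head(unique(gene[duplicated(gene)]), 5), collapse = ", "))
  log2fc <- as.numeric(log2fc); p <- as.numeric(p)
  if (length(log2fc) != length(gene) || length(p) != length(gene))
    stopf("gene, log2fc and p must have equal length")
  if (!all(is.finite(log2fc))) stopf("log2fc contains non-finite values")
  check_p(p)
  if (is.null(adj_p)) adj_p <- rep(NA_real_, length(gene))
  adj_p <- as.numeric(adj_p)
  set <- !is.na(adj_p)
  if (any(set & (adj_p < p - 1e-12 | adj_p > 1)))
    stopf("adjusted p-values must satisfy p <= adj_p <= 1")
  structure(data.frame(gene = gene, log2fc = log2fc, p = p, adj_p = adj_p,
                       stringsAsFactors = FALSE),
            class = c("de_table", "data.frame"))
}

check_p <- function(p, what = "p") {
  if (any(!is.finite(p) | p <= 0 | p > 1))
    stopf("%s-values must lie in (0, 1]; offending index %d",
          what, which(!is.finite(p) | p <= 0 | p > 1)[1])
  invisible(p)
}

#' Signed log10 p-value ranking statistic
#'
#' The per-gene ranking metric used to order genes for pre-ranked enrichment:
#' `sign(log2fc) * (-log10(p))`. Strongly significant upregulated genes get
#' large positive values, downregulated ones large negative values, and
#' `p = 1` or `log2fc = 0` maps to 0.
#'
#' @param log2fc Numeric vector of log2 fold-changes.
#' @param p Numeric vector of raw p-values in (0, 1].
#' @return Numeric vector of ranking statistics.
#' @export
#' @examples
#' rank_statistic(c(2, -1), c(0.01, 0.001))  # +2, -3
rank_statistic <- function(log2fc, p) {
  check_p(p)
  sign(log2fc) * (-log10(p))
}

#' Build a ranked gene list from a DE table
#'
#' Orders genes by [rank_statistic()] descending, so upregulated significant
#' genes are at the top and downregulated ones at the bottom. Ties are broken
#' by gene identifier (C-locale lexicographic), making the order fully
#' deterministic.
#'
#' @param table A [de_table()] (or data.frame with `gene`, `log2fc`, `p`).
#' @return A data.frame of class `ranked_list` with columns `gene`, `score`,
#'   ordered top to bottom.
#' @export
build_ranked_list <- function(table) {
  if (anyDuplicated(table$gene)) stopf("duplicate genes in DE table")
  score <- rank_statistic(table$log2fc, table$p)
  o <- order(-score, table$gene, method = "radix")
  structure(data.frame(gene = as.character(table$gene)[o], score = score[o],
                       stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of raw p-values (delegating to
#' `stats::p.adjust(method = "BH")` after validating the inputs):
#' `adj_p(i) = min_{j >= i} min(1, p(j) * m / j)` on the sorted p-values,
#' mapped back to input order.
#'
#' @param p Raw p-values in (0, 1].
#' @return Adjusted p-values, same order as the input, never below raw p.
#' @export
bh_adjust <- function(p) {
  check_p(p)
  stats::p.adjust(p, method = "BH")
}

#' Filter differentially expressed genes
#'
#' Selects genes with `adj_p < alpha` and a log2 fold-change strictly beyond
#' `min_abs_lfc` — both inequalities strict, matching the convention
#' "adjusted p < 0.05 and |log2FC| > 1". `direction = "up"` keeps only
#' `log2fc > min_abs_lfc` (e.g. the NF-kB-responsive gene-list criterion),
#' `"down"` only `log2fc < -min_abs_lfc`.
#'
#' @param table A [de_table()] with `adj_p` set on every record (run
#'   [bh_adjust()] first).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param min_abs_lfc Absolute log2 fold-change threshold (default 1).
#' @param direction One of `"both"`, `"up"`, `"down"`.
#' @return Character vector of passing gene identifiers, in table order.
#' @export
deg_filter <- function(table, alpha = 0.05, min_abs_lfc = 1,
                       direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  if (any(is.na(table$adj_p)))
    stopf("adj_p is unset on %d record(s); run bh_adjust() on the p column first",
          sum(is.na(table$adj_p)))
  keep <- table$adj_p < alpha & switch(direction,
    both = abs(table$log2fc) > min_abs_lfc,
    up = table$log2fc > min_abs_lfc,
    down = table$log2fc < -min_abs_lfc)
  as.character(table$gene)[keep]
}

#' Weighted running-sum enrichment score
#'
#' Classic pre-ranked enrichment: walking down the ranked list, the running
#' sum gains `|score|^weight / sum(|score_members|^weight)` at each set
#' member and loses `1 / (N - K)` at each non-member; the enrichment score
#' (ES) is the signed extremum of this walk, in `[-1, 1]` (an exact tie
#' between the positive and negative excursion resolves to the positive one). The leading edge
#' is the subset of members at or before the extremum (for positive ES) or at
#' or after it (negative ES).
#'
#' If every member statistic is zero the member increments degenerate; equal
#' increments `1/K` are used in that case.
#'
#' @param ranked A [build_ranked_list()] result (columns `gene`, `score`).
#' @param set A [gene_set()].
#' @param weight Exponent applied to `|score|` in the member increments
#'   (default 1).
#' @return A list with `es`, `running_sum` (length N), `hit_positions`,
#'   `leading_edge`, `overlap`. When no set member is present in the list,
#'   `es` is `NA` and `overlap` is 0 (an explicit empty-overlap result).
#' @export
gsea_es <- function(ranked, set, weight = 1) {
  genes <- as.character(ranked$gene)
  score <- as.numeric(ranked$score)
  N <- length(genes)
  hit <- genes %in% set$members
  K <- sum(hit)
  if (K == 0L) {
    return(list(es = NA_real_, running_sum = NULL,
                hit_positions = integer(), leading_edge = character(),
                overlap = 0L, note = "empty overlap"))
  }
  if (K == N)
    stopf("gene set covers the whole ranked universe (N - K = 0); ES undefined")
  w <- abs(score[hit])^weight
  W <- sum(w)
  inc <- rep(-1 / (N - K), N)
  inc[hit] <- if (W > 0) w / W else 1 / K
  running <- cumsum(inc)
  # signed extremum; a tie between the positive and negative excursion
  # (possible structurally, e.g. a single mid-list member) resolves to the
  # positive side, with a small tolerance so the choice is insensitive to
  # accumulation order
  max_p <- max(running); min_p <- min(running)
  if (max_p >= -min_p - 1e-10) {
    peak <- which.max(running); es <- max_p
  } else {
    peak <- which.min(running); es <- min_p
  }
  pos <- which(hit)
  leading <- if (es > 0) genes[pos[pos <= peak]]
             else if (es < 0) genes[pos[pos >= peak]]
             else character()
  list(es = es, running_sum = running, hit_positions = pos,
       leading_edge = leading, overlap = K)
}

# ES from sorted member positions only: O(K) instead of O(N). Candidate
# extrema are the running-sum values at each member position and just before
# it (the end of the preceding down-slope); the tail after the last member
# decays monotonically to 0 and contributes no extremum.
es_from_positions <- function(pos, w, N) {
  K <- length(pos)
  dec <- 1 / (N - K)
  W <- sum(w)
  cw <- if (W > 0) cumsum(w) / W else seq_len(K) / K
  drop_at <- (pos - seq_len(K)) * dec
  at <- cw - drop_at
  before <- c(0, cw[-K]) - drop_at
  cand <- c(at, before)
  max_p <- max(cand, 0); min_p <- min(cand, 0)
  if (max_p >= -min_p - 1e-10) max_p else min_p
}

#' Permutation test for a running-sum enrichment score
#'
#' Builds the null distribution of [gsea_es()] by drawing `n_perm` random
#' member sets of the same size from the ranked universe (gene permutation,
#' the only null available from a pre-ranked list). The p-value compares the
#' observed |ES| with sign-matched permuted scores,
#' `p = (1 + #\{|ES_perm| >= |ES_obs|, same sign\}) / (1 + #\{same sign\})`,
#' and NES normalises the observed ES by the mean |ES| of the sign-matched
#' permutations.
#'
#' @inheritParams gsea_es
#' @param n_perm Number of permutations, at least 10 (default 1000).
#' @param seed Integer seed for reproducible draws, or NULL.
#' @return An object of class `enrichment_result`: `set`, `es`, `nes`,
#'   `p_perm`, `n_perm`, `n_sign_matched`, `leading_edge`, `overlap`.
#' @export
gsea_permutation <- function(ranked, set, n_perm = 1000, seed = NULL,
                             weight = 1) {
  if (n_perm < 10) stopf("n_perm must be at least 10")
  obs <- gsea_es(ranked, set, weight = weight)
  if (obs$overlap == 0L)
    stopf("gene set '%s' has no members in the ranked list", set$name)
  N <- nrow(ranked)
  K <- obs$overlap
  aw <- abs(as.numeric(ranked$score))^weight
  es_perm <- with_seed_or_global(seed, vapply(seq_len(n_perm), function(i) {
    pos <- sort.int(sample.int(N, K))
    es_from_positions(pos, aw[pos], N)
  }, numeric(1)))
  if (obs$es == 0) {
    matched <- rep(FALSE, n_perm)
  } else {
    matched <- sign(es_perm) == sign(obs$es)
  }
  n_match <- sum(matched)
  p_perm <- (1 + sum(matched & abs(es_perm) >= abs(obs$es))) / (1 + n_match)
  nes <- if (n_match > 0) obs$es / mean(abs(es_perm[matched])) else NA_real_
  structure(
    list(set = set$name, es = obs$es, nes = nes, p_perm = p_perm,
         n_perm = n_perm, n_sign_matched = n_match,
         leading_edge = obs$leading_edge, overlap = K),
    class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %s: ES = %.4f, NES = %.4f, p_perm = %.4g (%d perms, overlap %d)\n",
              x$set, x$es, x$nes, x$p_perm, x$n_perm, x$overlap))
  invisible(x)
}

#' Hypergeometric overrepresentation test
#'
#' One-sided upper-tail hypergeometric test of whether a gene set overlaps a
#' DEG list more than expected by chance when drawing `n = |deg|` genes from
#' a universe of `N`: `p = P(X >= k)` with `K` set members in the universe
#' and `k` observed in the list. Computed exactly with `stats::phyper`.
#'
#' @param deg Character vector of selected genes (e.g. [deg_filter()]
#'   output); must be a subset of `universe`.
#' @param set A [gene_set()]; members outside the universe are ignored.
#' @param universe Character vector of all assayed genes.
#' @return An object of class `ora_result`: `set`, `k`, `n`, `K`, `N`,
#'   `p_hyper`.
#' @export
ora_hypergeom <- function(deg, set, universe) {
  deg <- unique(as.character(deg))
  universe <- unique(as.character(universe))
  missing <- setdiff(deg, universe)
  if (length(missing))
    stopf("DEG list contains genes outside the universe: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  members <- intersect(set$members, universe)
  k <- length(intersect(deg, members))
  n <- length(deg); K <- length(members); N <- length(universe)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(list(set = set$name, k = k, n = n, K = K, N = N, p_hyper = p),
            class = "ora_result")
}

#' @export
print.ora_result <- function(x, ...) {
  cat(sprintf("<ora_result> %s: k = %d of n = %d (set %d / universe %d), p = %.4g\n",
              x$set, x$k, x$n, x$K, x$N, x$p_hyper))
  invisible(x)
}

#' Per-sample gene-set activity scores
#'
#' Summarises a gene set's expression in each sample as the mean of the set
#' genes' z-scores: each gene is standardised across samples (sample sd,
#' `n - 1` denominator; genes constant across samples contribute 0), then
#' averaged within the set per sample. This mimics per-sample pathway
#' activity readouts (e.g. androgen-induced or NF-kB target gene activity
#' compared between castrated and sham-operated groups).
#'
#' @param expr Numeric matrix, genes in rows (rownames = identifiers),
#'   samples in columns.
#' @param set A [gene_set()]; must share at least one gene with `expr`.
#' @return Named numeric vector of per-sample scores.
#' @export
set_activity_scores <- function(expr, set) {
  if (is.null(rownames(expr))) stopf("expr must have gene rownames")
  genes <- intersect(rownames(expr), set$members)
  if (length(genes) == 0L)
    stopf("no members of gene set '%s' found in the expression matrix",
          set$name)
  sub <- expr[genes, , drop = FALSE]
  mu <- rowMeans(sub)
  sdv <- apply(sub, 1, stats::sd)
  z <- (sub - mu) / ifelse(sdv > 0, sdv, Inf)  # constant genes -> 0
  colMeans(z)
}

#' Two-group Wilcoxon rank-sum comparison
#'
#' Two-sided rank-sum test between two score vectors. For small samples
#' (both groups of size 8 or fewer) the null is enumerated exactly over all
#' `choose(n_a + n_b, n_a)` group assignments of the midranks, which remains
#' exact in the presence of ties; for larger samples the normal approximation
#' with tie correction (and continuity correction) is used via
#' `stats::wilcox.test`.
#'
#' @param scores_a,scores_b Numeric vectors, at least 2 values each.
#' @return A list of class `ranksum_test` with `statistic` (Mann-Whitney U
#'   for the first group), `p_value`, `method`, `n_a`, `n_b`.
#' @export
#' @examples
#' ranksum_test(c(1, 2), c(3, 4))$p_value  # exact: 1/3
ranksum_test <- function(scores_a, scores_b) {
  a <- as.numeric(scores_a); b <- as.numeric(scores_b)
  if (length(a) < 2L || length(b) < 2L)
    stopf("each group needs at least 2 values (got %d and %d)",
          length(a), length(b))
  if (!all(is.finite(c(a, b)))) stopf("scores must be finite")
  n_a <- length(a); n_b <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n_a)])
  u_obs <- w_obs - n_a * (n_a + 1) / 2
  if (n_a <= 8L && n_b <= 8L) {
    mu <- n_a * (sum(r) / (n_a + n_b))  # = n_a * (n+1)/2 without ties; general mean
    combs <- utils::combn(n_a + n_b, n_a)
    w_all <- colSums(matrix(r[combs], nrow = n_a))
    p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
    method <- "exact enumeration (midranks)"
  } else {
    p <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    method <- "normal approximation with tie correction"
  }
  structure(list(statistic = u_obs, p_value = p, method = method,
                 n_a = n_a, n_b = n_b),
            class = "ranksum_test")
}

#' @export
print.ranksum_test <- function(x, ...) {
  cat(sprintf("<ranksum_test> U = %g, p = %.4g (%s; n = %d vs %d)\n",
              x$statistic, x$p_value, x$method, x$n_a, x$n_b))
  invisible(x)
}
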