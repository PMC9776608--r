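#' Read and write network model files
#'
#' Models are exchanged as JSON (or YAML, by file extension) with keys
#' `labels`, `J`, `d` and `A` (a list of rows, row = target node). All
#' [network_model()] invariants are re-validated on load, so dimension
#' mismatches, non-numeric entries and duplicate labels are reported with
#' the offending field named.
#'
#' @param path File path; extension `.yaml`/`.yml` selects YAML, anything
#'   else JSON.
#' @return `read_model()` returns a [network_model()]; `write_model()`
#'   returns `path` invisibly.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stopf("model file not found: %s", path)
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyMatrix = FALSE)
  for (key in c("labels", "J", "d", "A"))
    if (is.null(obj[[key]])) stopf("model file %s: missing key '%s'", path, key)
  A <- obj$A
  if (is.list(A)) {
    lens <- lengths(A)
    if (length(unique(lens)) != 1L)
      stopf("model file %s: rows of 'A' have unequal lengths", path)
    A <- do.call(rbind, lapply(A, as.numeric))
  }
  if (any(is.na(suppressWarnings(as.numeric(unlist(obj$J))))))
    stopf("model file %s: non-numeric entries in 'J'", path)
  network_model(obj$labels, as.numeric(unlist(obj$J)),
                as.numeric(unlist(obj$d)), A)
}

#' @rdname read_model
#' @param model A [network_model()].
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "network_model"))
  obj <- list(labels = model$labels, J = unname(model$J), d = unname(model$d),
              A = lapply(seq_len(model$n), function(i) unname(model$A[i, ])))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read and write gene sets in GMT format
#'
#' One set per line: `name<TAB>description<TAB>member1<TAB>member2...`.
#' Duplicate members within a set are removed with a warning; malformed
#' lines (fewer than three fields) are reported with their line number.
#'
#' @param path File path.
#' @return `read_gmt()` returns a named list of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stopf("%s line %d: expected at least 3 tab-separated fields, got %d",
            path, i, length(f))
    gene_set(f[1], f[-(1:2)], description = f[2])
  })
  stats::setNames(sets, vapply(sets, `[[`, character(1), "name"))
}

#' @rdname read_gmt
#' @param sets A list of [gene_set()] objects.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s)
    paste(c(s$name, s$description, s$members), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write differential-expression tables
#'
#' Tab-separated with header `gene  log2fc  pvalue [adj_p]`. Values are
#' written with 15 significant digits so a round trip preserves them well
#' beyond 12 significant digits. On read, missing or out-of-range p-values
#' and duplicate gene rows are rejected with the offending row named.
#'
#' @param path File path.
#' @return `read_de_table()` returns a [de_table()].
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stopf("DE table not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene", "log2fc", "pvalue")
  if (!all(need %in% names(df)))
    stopf("%s: header must contain %s", path, paste(need, collapse = ", "))
  bad <- which(!is.finite(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1)
  if (length(bad))
    stopf("%s: invalid p-value in row(s) %s (must be in (0, 1])",
          path, paste(utils::head(bad, 5), collapse = ", "))
  de_table(df$gene, df$log2fc, df$pvalue,
           adj_p = if ("adj_p" %in% names(df)) df$adj_p else NULL)
}

#' @rdname read_de_table
#' @param table A [de_table()].
#' @export
write_de_table <- function(table, path) {
  out <- data.frame(gene = table$gene,
                    log2fc = sprintf("%.15g", table$log2fc),
                    pvalue = sprintf("%.15g", table$p),
                    stringsAsFactors = FALSE)
  if (!all(is.na(table$adj_p))) out$adj_p <- sprintf("%.15g", table$adj_p)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write RNK-style ranked gene lists
#'
#' Two tab-separated columns, `gene` and `score`, ordered top to bottom.
#'
#' @param path File path.
#' @return `read_rnk()` returns a `ranked_list` data.frame.
#' @export
read_rnk <- function(path) {
  if (!file.exists(path)) stopf("RNK file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "score") %in% names(df)))
    stopf("%s: header must contain gene, score", path)
  structure(df[, c("gene", "score")],
            class = c("ranked_list", "data.frame"))
}

#' @rdname read_rnk
#' @param ranked A ranked list (columns `gene`, `score`).
#' @export
write_rnk <- function(ranked, path) {
  out <- data.frame(gene = ranked$gene,
                    score = sprintf("%.15g", ranked$score))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a trajectory as CSV with a JSON metadata sidecar
#'
#' The CSV has header `time,<node1>,...,<nodeN>`; the sidecar
#' `<path>.meta.json` records `dt`, `seed`, `noise_amplitude` and the
#' applied perturbations, so a stored trajectory is reproducible.
#'
#' @param traj A [simulate_network()] trajectory.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "network_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  meta <- list(dt = traj$dt,
               seed = if (is.null(traj$seed)) NULL else traj$seed,
               noise_amplitude = traj$noise_amplitude,
               events_applied = traj$events_applied)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
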