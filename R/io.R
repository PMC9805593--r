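#' Read a tab-separated expression matrix (DREAM dialect)
#'
#' First row: gene identifiers; body: numeric, one sample per row.
#' Ragged rows, non-numeric cells and duplicate identifiers are rejected
#' with the offending line (and column) named. Parsing is
#' locale-independent (C-locale decimal point).
#'
#' @param path file path.
#' @param transpose set `TRUE` when the file is genes-by-samples: first
#'   row sample identifiers, first column gene identifiers.
#' @return Samples-by-genes numeric matrix with gene column names.
#' @export
read_expression <- function(path, transpose = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2)
    stop("expression file needs a header and at least one data row",
         call. = FALSE)
  header <- trimws(strsplit(lines[1], "\t", fixed = TRUE)[[1]])
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  row_ids <- character(length(body))
  vals <- NULL
  for (r in seq_along(body)) {
    row <- trimws(body[[r]])
    if (transpose) {
      row_ids[r] <- row[1]
      row <- row[-1]
    }
    if (length(row) != length(header))
      stop(sprintf("line %d: %d numeric fields, expected %d", r + 1L,
                   length(row), length(header)), call. = FALSE)
    v <- suppressWarnings(as.numeric(row))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop(sprintf("line %d, column %d: non-numeric value '%s'",
                   r + 1L, bad + if (transpose) 1L else 0L, row[bad]),
           call. = FALSE)
    }
    if (is.null(vals))
      vals <- matrix(NA_real_, length(body), length(row))
    vals[r, ] <- v
  }
  if (transpose) {
    vals <- t(vals)
    colnames(vals) <- row_ids
  } else {
    colnames(vals) <- header
  }
  gid <- colnames(vals)
  if (anyDuplicated(gid))
    stop("duplicate gene identifiers: ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "),
         call. = FALSE)
  vals
}

#' Write an expression matrix in the DREAM dialect
#'
#' Full-precision output (17 significant digits) so that a write/read
#' round trip reproduces the matrix to within 1e-12.
#'
#' @param x samples-by-genes numeric matrix with gene column names.
#' @param path output path.
#' @export
write_expression <- function(x, path) {
  x <- as_expression_matrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(x), collapse = "\t"), con)
  writeLines(apply(x, 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t")), con)
  invisible(path)
}

#' Read a gold-standard edge list
#'
#' Three tab-separated columns: gene, gene, label in {0, 1}. Rows
#' labelled 1 are positives; rows labelled 0 explicit negatives.
#' Self-pairs and duplicate pairs with conflicting labels are rejected
#' with the line number.
#'
#' @param path file path.
#' @param genes optional gene universe (defaults to the genes listed).
#' @return A [gold_standard()].
#' @export
read_gold <- function(path, genes = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  seen <- new.env(parent = emptyenv())
  pos <- list(); neg <- list()
  for (r in seq_along(lines)) {
    f <- trimws(strsplit(lines[r], "\t", fixed = TRUE)[[1]])
    if (length(f) != 3)
      stop(sprintf("line %d: expected 3 tab-separated fields", r),
           call. = FALSE)
    if (!f[3] %in% c("0", "1"))
      stop(sprintf("line %d: label must be 0 or 1, got '%s'", r, f[3]),
           call. = FALSE)
    if (f[1] == f[2])
      stop(sprintf("line %d: self-pair %s", r, f[1]), call. = FALSE)
    key <- pair_key(f[1], f[2])
    prev <- if (exists(key, envir = seen)) get(key, envir = seen) else NULL
    if (!is.null(prev) && prev != f[3])
      stop(sprintf("line %d: pair %s-%s has conflicting labels", r,
                   f[1], f[2]), call. = FALSE)
    assign(key, f[3], envir = seen)
    if (is.null(prev)) {
      if (f[3] == "1") pos[[length(pos) + 1L]] <- f[1:2]
      else neg[[length(neg) + 1L]] <- f[1:2]
    }
  }
  gold_standard(do.call(rbind, pos), do.call(rbind, neg), genes = genes)
}

#' Write / read a ranked edge list
#'
#' Output columns: geneA, geneB, score (6 significant digits), rank —
#' descending score, ties broken by identifier pair.
#'
#' @param fit a `meomi` fit (or a data.frame with columns gene_a, gene_b,
#'   score, rank, as in `fit$edges`).
#' @param path output path.
#' @export
write_edges <- function(fit, path) {
  edges <- if (inherits(fit, "meomi")) fit$edges else fit
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(edges))
    writeLines(sprintf("%s\t%s\t%.6g\t%d", edges$gene_a, edges$gene_b,
                       edges$score, edges$rank), con)
  invisible(path)
}

#' @rdname write_edges
#' @return `read_edges()` returns the edge data.frame.
#' @export
read_edges <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(gene_a = character(), gene_b = character(),
                      score = numeric(), rank = integer()))
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  if (ncol(f) != 4) stop("expected 4 tab-separated columns", call. = FALSE)
  data.frame(gene_a = f[, 1], gene_b = f[, 2],
             score = as.numeric(f[, 3]), rank = as.integer(f[, 4]),
             stringsAsFactors = FALSE)
}

#' Write an adjacency matrix as tab-separated 0/1
#'
#' @param fit a `meomi` fit or logical adjacency matrix.
#' @param path output path.
#' @export
write_adjacency <- function(fit, path) {
  adj <- if (inherits(fit, "meomi")) fit$adjacency else fit
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(adj), collapse = "\t"), con)
  writeLines(apply(adj * 1, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Write an evaluation report
#'
#' Emits both a flat `key: value` text report and, when `json` is given,
#' a machine-readable JSON file at full precision.
#'
#' @param report a `meomi_eval` object (or named list of scalars).
#' @param path text report path.
#' @param json optional JSON path.
#' @export
write_metrics <- function(report, path, json = NULL) {
  vals <- unclass(report)
  vals <- vals[vapply(vals, is.numeric, logical(1))]
  writeLines(sprintf("%s: %.6g", names(vals), unlist(vals)), path)
  if (!is.null(json))
    jsonlite::write_json(vals, json, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run manifest
#'
#' A reproducibility record for a pipeline run: configuration snapshot,
#' input file digests, package version, seed and per-stage timings.
#' Re-running with the manifest's configuration and inputs reproduces
#' the outputs byte-identically (the pipeline itself is deterministic).
#'
#' @param config named list of configuration values.
#' @param inputs character vector of input file paths (digested with
#'   md5).
#' @param seed integer seed used for the run.
#' @param timings named numeric vector of per-stage elapsed seconds.
#' @param warnings character vector of collected warnings.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(config = list(), inputs = character(),
                         seed = NA_integer_, timings = numeric(),
                         warnings = character()) {
  digests <- if (length(inputs)) {
    d <- tools::md5sum(inputs)
    stats::setNames(as.character(d), inputs)
  } else {
    character()
  }
  structure(list(
    package = "meomi",
    version = as.character(utils::packageVersion("meomi")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, config = config, input_digests = as.list(digests),
    timings = as.list(timings), warnings = warnings),
    class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`.
#' @param path output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
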