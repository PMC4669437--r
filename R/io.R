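# Readers and writers for the two plain-text interchange formats:
#   classification file: TSV `sid<TAB>sccs` (dir.cla-like; extra columns ignored)
#   feature table: TSV `query_sid  template_sid  f1..fF  [label]  [tm_score]`

#' Read a SCOP-style classification file
#'
#' Tab-separated, two leading columns `sid` and `sccs`; any further columns
#' are ignored. A header line is optional and detected by the literal
#' column name `sid`.
#'
#' @param path file path.
#' @return a [domain_records()] table.
#' @export
read_classification <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty classification file: ", path, call. = FALSE)
  has_header <- startsWith(lines[1L], "sid")
  body <- if (has_header) lines[-1L] else lines
  offset <- if (has_header) 1L else 0L
  fields <- strsplit(body, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 2L)
  if (length(short)) {
    stop(sprintf("classification file %s line %d: expected at least 2 tab-separated columns",
                 path, short[1L] + offset), call. = FALSE)
  }
  sid <- vapply(fields, `[[`, "", 1L)
  sccs <- vapply(fields, `[[`, "", 2L)
  domain_records(sid, sccs)
}

#' Write a classification file
#'
#' @param domains a [domain_records()] table.
#' @param path output file path.
#' @export
write_classification <- function(domains, path) {
  writeLines(c("sid\tsccs", paste(domains$sid, domains$sccs, sep = "\t")), path)
  invisible(path)
}

#' Write a pair feature table
#'
#' Emits a UTF-8 TSV with header
#' `query_sid  template_sid  f1..fF  [label]  [tm_score]`, '.' decimal.
#' The `label` column is written whenever relationships are known; the
#' `tm_score` column whenever any pair carries one.
#'
#' @param dataset a [pair_dataset()] with features.
#' @param path output file path.
#' @export
write_feature_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "pair_dataset"))
  if (is.null(dataset$features)) stop("dataset has no features to write", call. = FALSE)
  df <- data.frame(query_sid = dataset$pairs$query_sid,
                   template_sid = dataset$pairs$template_sid,
                   stringsAsFactors = FALSE)
  feats <- dataset$features
  colnames(feats) <- paste0("f", seq_len(ncol(feats)))
  df <- cbind(df, as.data.frame(feats))
  if (!all(is.na(dataset$pairs$relationship))) df$label <- dataset$pairs$binary_label
  if (!is.null(dataset$pairs$tm_score) && any(!is.na(dataset$pairs$tm_score))) {
    df$tm_score <- dataset$pairs$tm_score
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a pair feature table
#'
#' Parses the TSV format written by [write_feature_table()]. Feature
#' columns are `f1..fF` in order; `label` and `tm_score` columns are
#' optional. When a classification table is supplied, every sid must be
#' known and relationships are (re)derived from the sccs codes; otherwise
#' relationships are taken from the `label` column (positive pairs get the
#' generic `FOLD` level).
#'
#' @param path file path.
#' @param classification optional [domain_records()] table (or path to a
#'   classification file).
#' @return a [pair_dataset()].
#' @export
read_feature_table <- function(path, classification = NULL) {
  if (is.character(classification)) classification <- read_classification(classification)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("feature table ", path, " has no data rows", call. = FALSE)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header[1:2], c("query_sid", "template_sid"))) {
    stop("feature table ", path,
         " header must start with query_sid, template_sid", call. = FALSE)
  }
  fcols <- grep("^f[0-9]+$", header)
  if (length(fcols) == 0) stop("feature table ", path, " declares no feature columns", call. = FALSE)
  if (!identical(header[fcols], paste0("f", seq_along(fcols)))) {
    stop("feature columns must be f1..fF in order", call. = FALSE)
  }
  ncols <- length(header)
  fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != ncols)
  if (length(bad)) {
    stop(sprintf("feature table %s line %d: expected %d columns, found %d",
                 path, bad[1L] + 1L, ncols, lengths(fields)[bad[1L]]), call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = ncols, byrow = TRUE)
  colnames(m) <- header
  feats <- suppressWarnings(matrix(as.numeric(m[, fcols]), ncol = length(fcols)))
  if (anyNA(feats)) {
    bad_row <- which(apply(feats, 1L, anyNA))[1L]
    stop(sprintf("feature table %s line %d: non-numeric or missing feature value",
                 path, bad_row + 1L), call. = FALSE)
  }
  query_sid <- m[, "query_sid"]
  template_sid <- m[, "template_sid"]
  label <- if ("label" %in% header) as.integer(m[, "label"]) else NULL
  tm <- if ("tm_score" %in% header) as.numeric(m[, "tm_score"]) else NULL

  if (!is.null(classification)) {
    unknown <- setdiff(unique(c(query_sid, template_sid)), classification$sid)
    if (length(unknown)) {
      bad_row <- which(query_sid %in% unknown | template_sid %in% unknown)[1L]
      stop(sprintf("feature table %s line %d: sid '%s' not in classification file",
                   path, bad_row + 1L, unknown[1L]), call. = FALSE)
    }
    sccs_of <- stats::setNames(classification$sccs, classification$sid)
    rel <- scop_relationship(sccs_of[query_sid], sccs_of[template_sid])
    domains <- classification
  } else if (!is.null(label)) {
    if (!all(label %in% c(0L, 1L))) stop("label column must be 0/1", call. = FALSE)
    rel <- ifelse(label == 1L, "FOLD", "NONE")
    sids <- unique(c(query_sid, template_sid))
    domains <- data.frame(sid = sids, sccs = NA_character_, stringsAsFactors = FALSE)
  } else {
    stop("feature table has no label column and no classification file was supplied",
         call. = FALSE)
  }
  pairs <- data.frame(query_sid = query_sid, template_sid = template_sid,
                      relationship = rel,
                      binary_label = as.integer(rel != "NONE"),
                      stringsAsFactors = FALSE)
  if (!is.null(tm)) pairs$tm_score <- tm
  pair_dataset(domains, pairs, features = feats)
}

#' Write per-pair prediction scores
#'
#' TSV `query_sid  template_sid  score`; pairs without a score (removed by
#' the cross-validation template rule) are omitted.
#'
#' @param dataset a [pair_dataset()].
#' @param scores numeric vector aligned with `dataset$pairs` (NA allowed).
#' @param path output file path.
#' @export
write_predictions <- function(dataset, scores, path) {
  stopifnot(length(scores) == nrow(dataset$pairs))
  keep <- !is.na(scores)
  df <- data.frame(query_sid = dataset$pairs$query_sid[keep],
                   template_sid = dataset$pairs$template_sid[keep],
                   score = scores[keep], stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
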