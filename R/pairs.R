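# Domain tables, all-against-all pair enumeration, TM-score label choice.

#' Construct a validated table of classified protein domains
#'
#' @param sid character vector of unique domain identifiers
#'   (e.g. `"d1alo_5"`).
#' @param sccs character vector of SCOP-style classification codes; see
#'   [parse_sccs()].
#' @param length optional positive integer residue counts (used by the
#'   synthetic generator and reports only).
#' @return data.frame of class `domain_records` with columns `sid`, `sccs`
#'   and optionally `length`.
#' @export
domain_records <- function(sid, sccs, length = NULL) {
  if (length(sid) != length(sccs)) {
    stop("sid and sccs must have the same length", call. = FALSE)
  }
  if (anyDuplicated(sid)) {
    stop(sprintf("duplicate domain sid: '%s'", sid[duplicated(sid)][1L]), call. = FALSE)
  }
  parse_sccs(sccs)  # validates
  out <- data.frame(sid = as.character(sid), sccs = as.character(sccs),
                    stringsAsFactors = FALSE)
  if (!is.null(length)) {
    if (any(length <= 0 | length != as.integer(length))) {
      stop("domain lengths must be positive integers", call. = FALSE)
    }
    out$length <- as.integer(length)
  }
  class(out) <- c("domain_records", "data.frame")
  out
}

#' Bundle domains, pairs and features into one dataset object
#'
#' A `pair_dataset` holds the domain table, the ordered (query, template)
#' pair table with relationship labels, and optionally an aligned numeric
#' feature matrix (one row per pair) and per-pair TM-scores.
#'
#' @param domains a [domain_records()] table (or data.frame with `sid`,
#'   `sccs`).
#' @param pairs data.frame with columns `query_sid`, `template_sid`,
#'   `relationship`, `binary_label` and optionally `tm_score`.
#' @param features optional numeric matrix with `nrow(pairs)` rows.
#' @return object of class `pair_dataset` with elements `domains`, `pairs`,
#'   `features` and `feature_count`.
#' @export
pair_dataset <- function(domains, pairs, features = NULL) {
  req <- c("query_sid", "template_sid", "relationship", "binary_label")
  if (!all(req %in% names(pairs))) {
    stop("pairs must have columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(pairs$query_sid == pairs$template_sid)) {
    stop("self-pairs (query_sid == template_sid) are not allowed", call. = FALSE)
  }
  if (!all(pairs$relationship %in% RELATIONSHIP_LEVELS)) {
    stop("unknown relationship level in pairs", call. = FALSE)
  }
  expected <- as.integer(pairs$relationship != "NONE")
  if (!all(pairs$binary_label == expected)) {
    stop("binary_label must be 1 exactly for FAMILY/SUPERFAMILY/FOLD pairs", call. = FALSE)
  }
  feature_count <- 0L
  if (!is.null(features)) {
    features <- as_feature_matrix(features)
    if (nrow(features) != nrow(pairs)) {
      stop("features must have one row per pair", call. = FALSE)
    }
    feature_count <- ncol(features)
  }
  if (!is.null(pairs$tm_score)) {
    bad <- !is.na(pairs$tm_score) & (pairs$tm_score < 0 | pairs$tm_score > 1)
    if (any(bad)) stop("tm_score values must lie in [0, 1]", call. = FALSE)
  }
  structure(list(domains = domains, pairs = pairs, features = features,
                 feature_count = feature_count),
            class = "pair_dataset")
}

#' @export
print.pair_dataset <- function(x, ...) {
  cat(sprintf("pair_dataset: %d domains, %d ordered pairs, %d features\n",
              nrow(x$domains), nrow(x$pairs), x$feature_count))
  tab <- table(factor(x$pairs$relationship, levels = RELATIONSHIP_LEVELS))
  cat("  relationships:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "), "\n")
  if (!is.null(x$pairs$tm_score)) {
    cat(sprintf("  tm_score present for %d pairs\n", sum(!is.na(x$pairs$tm_score))))
  }
  invisible(x)
}

#' Enumerate all ordered query-template pairs
#'
#' Pairs every domain with every other domain (ordered, no self-pairs), so
#' `n` domains yield exactly `n * (n - 1)` pairs, each labelled with the
#' most specific shared structural level. Order is deterministic:
#' query-major in the order of the domain table.
#'
#' @param domains a [domain_records()] table.
#' @return a [pair_dataset()] without features.
#' @examples
#' d <- domain_records(c("dA", "dB"), c("a.1.1.1", "a.1.1.2"))
#' enumerate_pairs(d)$pairs
#' @export
enumerate_pairs <- function(domains) {
  if (nrow(domains) < 2L) stop("need at least 2 domains", call. = FALSE)
  if (anyDuplicated(domains$sid)) {
    stop(sprintf("duplicate domain sid: '%s'",
                 domains$sid[duplicated(domains$sid)][1L]), call. = FALSE)
  }
  n <- nrow(domains)
  qi <- rep(seq_len(n), each = n)
  ti <- rep(seq_len(n), times = n)
  keep <- qi != ti
  qi <- qi[keep]
  ti <- ti[keep]
  comps <- parse_sccs(domains$sccs)
  rel <- relationship_from_components(comps[qi, , drop = FALSE],
                                      comps[ti, , drop = FALSE])
  pairs <- data.frame(query_sid = domains$sid[qi],
                      template_sid = domains$sid[ti],
                      relationship = rel,
                      binary_label = as.integer(rel != "NONE"),
                      stringsAsFactors = FALSE)
  pair_dataset(domains, pairs)
}

#' Choose the TM-score label for a pair
#'
#' TM-align reports two scores per structure pair, one normalized by each
#' chain length; normalizing by the shorter chain gives the larger value.
#' The regression label takes the higher (short-normalized) score for
#' same-fold pairs and the lower (long-normalized) score otherwise, which
#' sharpens the separation between the two classes.
#'
#' @param tm_norm_short,tm_norm_long numeric vectors in `[0, 1]` with
#'   `tm_norm_short >= tm_norm_long` elementwise.
#' @param same_fold logical vector: does the pair share a structural fold?
#' @return numeric vector of chosen similarity labels.
#' @examples
#' choose_tm_label(0.62, 0.48, same_fold = TRUE)   # 0.62
#' choose_tm_label(0.62, 0.48, same_fold = FALSE)  # 0.48
#' @export
choose_tm_label <- function(tm_norm_short, tm_norm_long, same_fold) {
  if (any(tm_norm_short < 0 | tm_norm_short > 1 |
          tm_norm_long < 0 | tm_norm_long > 1)) {
    stop("TM-scores must lie in [0, 1]", call. = FALSE)
  }
  if (any(tm_norm_short < tm_norm_long)) {
    stop("tm_norm_short must be >= tm_norm_long (shorter-chain normalization cannot decrease the score)",
         call. = FALSE)
  }
  ifelse(same_fold, tm_norm_short, tm_norm_long)
}
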