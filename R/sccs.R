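# SCOP concise classification strings (sccs) and pair relationships.

#' Relationship levels of a query-template domain pair
#'
#' Ordered from most to least specific. A pair labelled `FAMILY` shares
#' family, superfamily and fold; `SUPERFAMILY` shares superfamily and fold
#' but not family; `FOLD` shares only the fold; `NONE` differs in fold (or
#' structural class). Labels are always the *most specific* shared level,
#' so the three positive sets are disjoint.
#'
#' @export
RELATIONSHIP_LEVELS <- c("FAMILY", "SUPERFAMILY", "FOLD", "NONE")

# Specificity rank used when excluding more-specific pairs from ranked lists.
relationship_rank <- function(level) {
  match(level, rev(RELATIONSHIP_LEVELS)) - 1L  # NONE=0 ... FAMILY=3
}

#' Parse SCOP concise classification strings
#'
#' An sccs code has four dot-separated components,
#' `class.fold.superfamily.family` (e.g. `"a.1.1.1"`): a single-letter
#' structural class followed by three positive integers.
#'
#' @param code character vector of sccs codes.
#' @return A data.frame with one row per code and columns `class_id`
#'   (character), `fold_id`, `superfamily_id`, `family_id` (integer).
#' @examples
#' parse_sccs(c("a.1.1.1", "b.12.3.4"))
#' @export
parse_sccs <- function(code) {
  if (length(code) == 0 || !is.character(code) || anyNA(code) || any(!nzchar(code))) {
    stop("sccs codes must be non-empty strings", call. = FALSE)
  }
  parts <- strsplit(code, ".", fixed = TRUE)
  n_comp <- lengths(parts)
  if (any(n_comp != 4L)) {
    bad <- code[n_comp != 4L][1L]
    stop(sprintf("malformed sccs code '%s': expected 4 dot-separated components, got %d",
                 bad, n_comp[n_comp != 4L][1L]), call. = FALSE)
  }
  m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  if (any(!grepl("^[A-Za-z]$", m[, 1L]))) {
    bad <- code[!grepl("^[A-Za-z]$", m[, 1L])][1L]
    stop(sprintf("malformed sccs code '%s': class component must be a single letter", bad),
         call. = FALSE)
  }
  ints <- suppressWarnings(matrix(as.integer(m[, 2:4]), ncol = 3L))
  if (anyNA(ints) || any(ints <= 0L)) {
    bad_row <- which(apply(ints, 1L, function(r) anyNA(r) || any(r <= 0L)))[1L]
    stop(sprintf("malformed sccs code '%s': fold/superfamily/family components must be positive integers",
                 code[bad_row]), call. = FALSE)
  }
  data.frame(class_id = m[, 1L], fold_id = ints[, 1L],
             superfamily_id = ints[, 2L], family_id = ints[, 3L],
             stringsAsFactors = FALSE)
}

#' Format sccs components back into a code string
#'
#' Inverse of [parse_sccs()]; `format_sccs(parse_sccs(x))` round-trips.
#'
#' @param comps data.frame as returned by [parse_sccs()].
#' @return character vector of sccs codes.
#' @export
format_sccs <- function(comps) {
  paste(comps$class_id, comps$fold_id, comps$superfamily_id, comps$family_id, sep = ".")
}

#' Most-specific shared relationship of two classified domains
#'
#' Compares two sccs codes componentwise and returns the most specific
#' structural level they share: `"FAMILY"` (all four components equal),
#' `"SUPERFAMILY"` (equal up to superfamily, family differs), `"FOLD"`
#' (equal class and fold, superfamily differs) or `"NONE"` (fold or class
#' differs). Symmetric in its arguments and vectorized.
#'
#' @param sccs1,sccs2 character vectors of sccs codes (recycled to common
#'   length).
#' @return character vector of levels from [RELATIONSHIP_LEVELS].
#' @examples
#' scop_relationship("a.1.1.1", "a.1.1.2")  # "SUPERFAMILY"
#' @export
scop_relationship <- function(sccs1, sccs2) {
  n <- max(length(sccs1), length(sccs2))
  c1 <- parse_sccs(rep_len(sccs1, n))
  c2 <- parse_sccs(rep_len(sccs2, n))
  relationship_from_components(c1, c2)
}

# Vectorized core working on pre-parsed component tables (same nrow).
relationship_from_components <- function(c1, c2) {
  same_class <- c1$class_id == c2$class_id
  same_fold <- same_class & c1$fold_id == c2$fold_id
  same_sf <- same_fold & c1$superfamily_id == c2$superfamily_id
  same_fam <- same_sf & c1$family_id == c2$family_id
  out <- rep("NONE", nrow(c1))
  out[same_fold] <- "FOLD"
  out[same_sf] <- "SUPERFAMILY"
  out[same_fam] <- "FAMILY"
  out
}
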