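# Seeded generator of SCOP-like hierarchies, pairwise features and
# TM-score-like similarities. The generator emulates the structure of the
# all-against-all fold-recognition benchmarks: a nested
# class/fold/superfamily/family hierarchy, feature vectors whose
# class-conditional separability decreases from family to superfamily to
# fold to unrelated, and similarity scores whose same-fold and
# different-fold distributions overlap in the 0.30-0.50 band.

#' Configuration of the synthetic fold-recognition data generator
#'
#' @param n_folds,superfamilies_per_fold,families_per_superfamily,domains_per_family
#'   hierarchy sizes (all >= 1); the defaults give 2x2x2x2 = 16 domains
#'   and 240 ordered pairs.
#' @param feature_count number of pairwise features F (default 84, the
#'   width of the classic alignment-derived feature set).
#' @param signal_means named shift of the informative features per
#'   relationship; defaults FAMILY 1.5, SUPERFAMILY 1.0, FOLD 0.5,
#'   NONE 0, so separability decays with evolutionary distance.
#' @param noise_sd Gaussian feature noise (default 1).
#' @param informative_fraction fraction of features carrying signal, in
#'   (0, 1] (default 0.5); the rest are pure noise.
#' @param tm_location mean TM-score-like similarity per relationship
#'   (must decrease FAMILY > SUPERFAMILY > FOLD > NONE); defaults 0.65,
#'   0.52, 0.42, 0.30 put substantial same-fold and different-fold mass
#'   in the ambiguous 0.30-0.50 band.
#' @param tm_concentration Beta concentration (location * conc,
#'   (1 - location) * conc shape parameters); `Inf` gives degenerate
#'   spread (every pair gets exactly its location).
#' @param length_range residue-count range for simulated domain lengths.
#' @param seed integer seed; the generator is fully deterministic given
#'   the configuration.
#' @return list of class `fold_sim_config`.
#' @export
fold_sim_config <- function(n_folds = 2, superfamilies_per_fold = 2,
                            families_per_superfamily = 2,
                            domains_per_family = 2, feature_count = 84,
                            signal_means = c(FAMILY = 1.5, SUPERFAMILY = 1.0,
                                             FOLD = 0.5, NONE = 0),
                            noise_sd = 1, informative_fraction = 0.5,
                            tm_location = c(FAMILY = 0.65, SUPERFAMILY = 0.52,
                                            FOLD = 0.42, NONE = 0.30),
                            tm_concentration = 30, length_range = c(50, 300),
                            seed = 1L) {
  stopifnot(n_folds >= 1, superfamilies_per_fold >= 1,
            families_per_superfamily >= 1, domains_per_family >= 1,
            feature_count >= 1, noise_sd > 0,
            informative_fraction > 0, informative_fraction <= 1,
            tm_concentration > 0)
  if (!all(RELATIONSHIP_LEVELS %in% names(signal_means))) {
    stop("signal_means must name all of ", paste(RELATIONSHIP_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  if (!all(RELATIONSHIP_LEVELS %in% names(tm_location))) {
    stop("tm_location must name all relationship levels", call. = FALSE)
  }
  tl <- tm_location[RELATIONSHIP_LEVELS]
  if (any(diff(tl) >= 0)) {
    stop("tm_location must decrease strictly from FAMILY to NONE", call. = FALSE)
  }
  if (any(tl <= 0 | tl >= 1)) stop("tm_location values must lie in (0, 1)", call. = FALSE)
  structure(list(n_folds = as.integer(n_folds),
                 superfamilies_per_fold = as.integer(superfamilies_per_fold),
                 families_per_superfamily = as.integer(families_per_superfamily),
                 domains_per_family = as.integer(domains_per_family),
                 feature_count = as.integer(feature_count),
                 signal_means = signal_means[RELATIONSHIP_LEVELS],
                 noise_sd = noise_sd,
                 informative_fraction = informative_fraction,
                 tm_location = tl,
                 tm_concentration = tm_concentration,
                 length_range = as.integer(length_range),
                 seed = as.integer(seed)),
            class = "fold_sim_config")
}

#' Generate a SCOP-like domain hierarchy
#'
#' Deterministically enumerates
#' `n_folds * superfamilies_per_fold * families_per_superfamily *
#' domains_per_family` domains with consistent sccs codes (each fold gets
#' its own class letter and fold number) and seeded random lengths.
#'
#' @param config a [fold_sim_config()].
#' @return a [domain_records()] table.
#' @export
simulate_domains <- function(config) {
  stopifnot(inherits(config, "fold_sim_config"))
  grid <- expand.grid(dom = seq_len(config$domains_per_family),
                      fam = seq_len(config$families_per_superfamily),
                      sf = seq_len(config$superfamilies_per_fold),
                      fold = seq_len(config$n_folds))
  grid <- grid[order(grid$fold, grid$sf, grid$fam, grid$dom), , drop = FALSE]
  n <- nrow(grid)
  sccs <- paste(letters[(grid$fold - 1L) %% 26L + 1L], grid$fold, grid$sf,
                grid$fam, sep = ".")
  lens <- with_seed(config$seed,
                    sample(config$length_range[1L]:config$length_range[2L], n,
                           replace = TRUE))
  domain_records(sprintf("ds%04d", seq_len(n)), sccs, length = lens)
}

#' Generate class-conditional pairwise feature vectors
#'
#' The first `round(F * informative_fraction)` features (at least one) are
#' informative: Gaussian with mean `signal_means[relationship]` and sd
#' `noise_sd`. The remaining features are pure noise. The two orderings of
#' a domain pair receive independent draws, mirroring the asymmetry of
#' alignment-derived features.
#'
#' @param pairs a [pair_dataset()] or pairs data.frame with a
#'   `relationship` column.
#' @param config a [fold_sim_config()].
#' @return numeric matrix, one row per pair.
#' @export
simulate_pair_features <- function(pairs, config) {
  if (inherits(pairs, "pair_dataset")) pairs <- pairs$pairs
  n <- nrow(pairs)
  F <- config$feature_count
  n_inf <- max(1L, round(F * config$informative_fraction))
  with_seed(config$seed + 1L, {
    x <- matrix(rnorm(n * F, mean = 0, sd = config$noise_sd), n, F)
    shift <- config$signal_means[pairs$relationship]
    x[, seq_len(n_inf)] <- x[, seq_len(n_inf), drop = FALSE] + shift
    x
  })
}

#' Generate TM-score-like similarity values
#'
#' Per-relationship scaled Beta draws with mean `tm_location[level]` and
#' concentration `tm_concentration`, so values stay in `[0, 1]`, location
#' ordering FAMILY > SUPERFAMILY > FOLD > NONE holds in expectation, and
#' under the defaults same-fold and different-fold pairs overlap in the
#' ambiguous 0.30-0.50 band. `tm_concentration = Inf` returns each pair's
#' location exactly.
#'
#' @inheritParams simulate_pair_features
#' @return numeric vector in `[0, 1]`, one value per pair.
#' @export
simulate_tm_scores <- function(pairs, config) {
  if (inherits(pairs, "pair_dataset")) pairs <- pairs$pairs
  loc <- unname(config$tm_location[pairs$relationship])
  if (!is.finite(config$tm_concentration)) return(loc)
  with_seed(config$seed + 2L, {
    a <- loc * config$tm_concentration
    b <- (1 - loc) * config$tm_concentration
    rbeta(length(loc), a, b)
  })
}

#' Simulate a complete synthetic fold-recognition dataset
#'
#' Hierarchy, all-against-all ordered pairs with most-specific
#' relationship labels, class-conditional features and TM-score-like
#' similarities, all deterministic given the configuration seed.
#'
#' @param config a [fold_sim_config()].
#' @return a [pair_dataset()] with features and `tm_score`.
#' @examples
#' sim <- simulate_fold_data(fold_sim_config(feature_count = 10))
#' sim
#' @export
simulate_fold_data <- function(config = fold_sim_config()) {
  domains <- simulate_domains(config)
  ds <- enumerate_pairs(domains)
  ds$pairs$tm_score <- simulate_tm_scores(ds$pairs, config)
  pair_dataset(domains, ds$pairs,
               features = simulate_pair_features(ds$pairs, config))
}
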