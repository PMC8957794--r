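# Synthetic omics data with planted informative features.
#
# Two value models mirror the two families of real matrices the selection
# methods target: unbounded Gaussian expression-like values and
# beta-distributed methylation-like values in [0, 1]. A known subset of
# "informative" features carries a class-conditional location shift; all
# remaining features are class-independent noise, so recovery of the
# planted subset can be scored exactly.

#' Specification for a synthetic dataset
#'
#' @param n_per_class samples per class, default 30.
#' @param n_features total features, default 2000.
#' @param n_informative number of planted class-associated features,
#'   default 5.
#' @param effect_size standardized between-class mean shift of informative
#'   features (in units of the feature's noise sd), default 3.
#' @param noise_sd residual standard deviation of the Gaussian model,
#'   default 1.
#' @param value_model `"gaussian"` (expression-like, unbounded) or
#'   `"beta"` (methylation-like, bounded in `[0, 1]`).
#' @param missing_rate fraction of cells set missing uniformly at random,
#'   in `[0, 1)`, default 0.
#' @param n_classes number of classes, default 2.
#' @param beta_precision precision parameter of the beta model (larger
#'   means tighter beta values), default 30.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return an object of class `SynthSpec`.
#' @export
synth_spec <- function(n_per_class = 30, n_features = 2000, n_informative = 5,
                       effect_size = 3, noise_sd = 1,
                       value_model = c("gaussian", "beta"),
                       missing_rate = 0, n_classes = 2,
                       beta_precision = 30, seed = 1) {
  value_model <- match.arg(value_model)
  if (n_informative > n_features)
    stop_validation("n_informative (%d) exceeds n_features (%d)",
                    n_informative, n_features)
  if (missing_rate < 0 || missing_rate >= 1)
    stop_validation("missing_rate must be in [0, 1)")
  if (n_classes < 2) stop_validation("need at least 2 classes")
  structure(list(n_per_class = as.integer(n_per_class),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size, noise_sd = noise_sd,
                 value_model = value_model, missing_rate = missing_rate,
                 n_classes = as.integer(n_classes),
                 beta_precision = beta_precision, seed = as.integer(seed)),
            class = "SynthSpec")
}

#' Generate a synthetic dataset with planted informative features
#'
#' Informative features carry a between-class mean shift of
#' `effect_size * noise_sd` (Gaussian model) or an `effect_size`-standardized
#' shift of the beta location (bounded model); all other features are drawn
#' identically for every class. Informative features are placed at random
#' positions. Missing entries are planted uniformly at rate `missing_rate`.
#'
#' @param spec a [synth_spec()].
#' @return list with `matrix` (a [feature_matrix()]) and `truth` (logical
#'   mask of the planted informative features).
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "SynthSpec"))
  n <- spec$n_per_class * spec$n_classes
  d <- spec$n_features
  labels <- rep(paste0("C", seq_len(spec$n_classes)), each = spec$n_per_class)
  with_seed(spec$seed, {
    informative <- sort(sample.int(d, spec$n_informative))
    truth <- rep(FALSE, d)
    truth[informative] <- TRUE
    # per-class centered offsets in sd units: adjacent classes differ by
    # effect_size
    offsets <- (seq_len(spec$n_classes) - (spec$n_classes + 1) / 2) *
      spec$effect_size
    class_idx <- rep(seq_len(spec$n_classes), each = spec$n_per_class)
    if (spec$value_model == "gaussian") {
      values <- matrix(stats::rnorm(n * d, sd = spec$noise_sd), n, d)
      for (j in informative)
        values[, j] <- values[, j] + offsets[class_idx] * spec$noise_sd
    } else {
      phi <- spec$beta_precision
      mu <- stats::runif(d, 0.2, 0.8)
      values <- matrix(0, n, d)
      for (j in seq_len(d)) {
        mu_j <- rep(mu[j], n)
        if (truth[j]) {
          sd_j <- sqrt(mu[j] * (1 - mu[j]) / (1 + phi))
          mu_j <- pmin(pmax(mu[j] + offsets[class_idx] * sd_j, 0.02), 0.98)
        }
        values[, j] <- stats::rbeta(n, mu_j * phi, (1 - mu_j) * phi)
      }
    }
    if (spec$missing_rate > 0) {
      miss <- stats::runif(n * d) < spec$missing_rate
      values[matrix(miss, n, d)] <- NA_real_
    }
  })
  fm <- feature_matrix(values, labels,
                       feature_ids = sprintf("F%05d", seq_len(d)),
                       sample_ids = sprintf("S%03d", seq_len(n)))
  list(matrix = fm, truth = truth)
}

#' Overlap between a selected subset and the planted truth
#'
#' @param selected,truth logical masks of equal length.
#' @return list with `jaccard` (`|S∩T| / |S∪T|`; defined as 0 with
#'   `both_empty = TRUE` when both masks are empty) and `recall_of_planted`
#'   (`|S∩T| / |T|`).
#' @export
recovery_score <- function(selected, truth) {
  selected <- as.logical(selected)
  truth <- as.logical(truth)
  if (length(selected) != length(truth))
    stop_validation("masks have differing lengths")
  inter <- sum(selected & truth)
  uni <- sum(selected | truth)
  both_empty <- uni == 0
  list(jaccard = if (both_empty) 0 else inter / uni,
       recall_of_planted = if (sum(truth) == 0) NA_real_ else inter / sum(truth),
       both_empty = both_empty)
}
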