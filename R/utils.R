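#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# Columns of an exemplar table that are not feature coordinates.
.meta_cols <- c("exemplar_id", "identity_id", "capture_age", "segment")

#' Names of the feature columns of an exemplar table
#'
#' Exemplar tables store the face-space coordinates in columns `f0 ... f{d-1}`
#' alongside the metadata columns `exemplar_id`, `identity_id`, `capture_age`
#' (and, for synthetic data, the ground-truth `segment`).
#'
#' @param exemplars A data frame with `f*` feature columns.
#' @return Character vector of feature column names, in dimension order.
#' @export
feature_cols <- function(exemplars) {
  nm <- names(exemplars)
  fc <- grep("^f[0-9]+$", nm, value = TRUE)
  if (length(fc) == 0) abort("no feature columns (f0, f1, ...) found")
  fc[order(as.integer(sub("^f", "", fc)))]
}

#' Extract the feature matrix of an exemplar table
#'
#' @inheritParams feature_cols
#' @return Numeric matrix, one row per exemplar, rownames = `exemplar_id`.
#' @export
feature_matrix <- function(exemplars) {
  m <- as.matrix(exemplars[, feature_cols(exemplars), drop = FALSE])
  if (!is.numeric(m)) abort("feature columns must be numeric")
  if ("exemplar_id" %in% names(exemplars)) {
    rownames(m) <- as.character(exemplars$exemplar_id)
  }
  m
}

# Deterministic child seed for the i-th internal random stream.
.child_seed <- function(seed, i) {
  (as.integer(seed) + 10007L * as.integer(i)) %% 2147483562L
}

.euclid <- function(a, b) sqrt(sum((a - b)^2))

.assert_finite <- function(x, what) {
  if (!all(is.finite(x))) abort(paste0(what, " must be finite"))
}
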