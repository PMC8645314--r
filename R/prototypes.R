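#' Build episodic prototypes from a cluster labeling
#'
#' One prototype per cluster, its centroid the arithmetic mean of the member
#' feature vectors — the feature-space stand-in for morphing the member
#' photographs into one image. The episode tag records the cluster's capture
#' age span.
#'
#' @param exemplars Exemplar table (see [generate_trajectory()]).
#' @param labels Cluster labels, one per exemplar, either named by
#'   `exemplar_id` or in row order.
#' @return Tibble with one row per prototype: `episode` tag, `n_members`,
#'   `age_min`, `age_max`, member ids (list column), `excluded_id` (`NA`),
#'   and the `centroid` list column.
#' @export
episodic_prototypes <- function(exemplars, labels) {
  exemplars <- as_tibble(exemplars)
  if (!is.null(names(labels))) {
    labels <- labels[exemplars$exemplar_id]
  }
  if (length(labels) != nrow(exemplars) || anyNA(labels)) {
    abort("labels must cover every exemplar")
  }
  fm <- feature_matrix(exemplars)
  purrr::map_dfr(split(seq_len(nrow(exemplars)), labels), function(idx) {
    ages <- exemplars$capture_age[idx]
    tibble(
      episode = sprintf("%.0f-%.0f", min(ages), max(ages)),
      n_members = length(idx),
      age_min = min(ages),
      age_max = max(ages),
      member_ids = list(exemplars$exemplar_id[idx]),
      excluded_id = NA_character_,
      centroid = list(colMeans(fm[idx, , drop = FALSE]))
    )
  }) %>% dplyr::arrange(.data$age_min)
}

#' Build the exhaustive prototype of an identity
#'
#' The centroid over all exemplars across the whole observed lifespan — the
#' single averaged representation the episodic account argues against.
#'
#' @inheritParams episodic_prototypes
#' @return One-row tibble in the same shape as [episodic_prototypes()], with
#'   episode tag `"exhaustive"`.
#' @export
exhaustive_prototype <- function(exemplars) {
  exemplars <- as_tibble(exemplars)
  if (nrow(exemplars) < 1) abort("need at least one exemplar")
  fm <- feature_matrix(exemplars)
  tibble(
    episode = "exhaustive",
    n_members = nrow(exemplars),
    age_min = min(exemplars$capture_age),
    age_max = max(exemplars$capture_age),
    member_ids = list(exemplars$exemplar_id),
    excluded_id = NA_character_,
    centroid = list(colMeans(fm))
  )
}

#' Leave-one-out versions of a prototype
#'
#' For each member, a version of the prototype recomputed with that member
#' excluded ("drawn without placing back"): a set of near-identical but
#' non-identical probe stimuli. A prototype of m members yields exactly m
#' versions of m-1 members each, and the mean of all version centroids equals
#' the full centroid.
#'
#' @param exemplars Exemplar table restricted to the prototype's members
#'   (>= 2 rows), or a one-row prototype tibble together with the full
#'   exemplar table in `from`.
#' @param from Optional full exemplar table when `exemplars` is a prototype
#'   row.
#' @return Tibble of versions: `episode`, `version`, `excluded_id`,
#'   `n_members`, `member_ids`, `centroid`.
#' @export
loo_versions <- function(exemplars, from = NULL) {
  if (!is.null(from) && "member_ids" %in% names(exemplars)) {
    tag <- exemplars$episode[[1]]
    exemplars <- dplyr::filter(as_tibble(from),
                               .data$exemplar_id %in% exemplars$member_ids[[1]])
  } else {
    tag <- "episode"
    exemplars <- as_tibble(exemplars)
  }
  m <- nrow(exemplars)
  if (m < 2) abort("leave-one-out versions need at least 2 members")
  fm <- feature_matrix(exemplars)
  total <- colSums(fm)
  purrr::map_dfr(seq_len(m), function(i) {
    tibble(
      episode = tag,
      version = i,
      excluded_id = exemplars$exemplar_id[i],
      n_members = m - 1L,
      member_ids = list(exemplars$exemplar_id[-i]),
      centroid = list((total - fm[i, ]) / (m - 1))
    )
  })
}

#' Write prototype tables as JSON
#'
#' @param prototypes A prototype or version tibble.
#' @param path File path.
#' @export
write_prototypes <- function(prototypes, path) {
  doc <- purrr::pmap(prototypes, function(...) {
    row <- list(...)
    keep <- intersect(c("episode", "version", "excluded_id", "n_members",
                        "age_min", "age_max"), names(row))
    c(row[keep],
      list(member_ids = unlist(row$member_ids),
           centroid = as.numeric(row$centroid)))
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
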