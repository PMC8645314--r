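#' All unordered pairwise displays of a stimulus set
#'
#' Enumerates the choose(n, 2) unordered pairs of n stimuli — the trial set
#' of a pairwise similarity-rating task that ignores left/right placement.
#' 20 presentations of one identity give 190 displays; 8 give 28.
#'
#' @param n_items Number of stimuli (>= 2).
#' @param items Optional stimulus ids (defaults to `item1..itemN`).
#' @return Tibble with columns `trial`, `left`, `right`; attribute `n_pairs`.
#' @export
pairwise_displays <- function(n_items, items = NULL) {
  if (n_items < 2) abort("need at least 2 items")
  if (is.null(items)) items <- sprintf("item%02d", seq_len(n_items))
  if (length(items) != n_items) abort("items length must equal n_items")
  idx <- utils::combn(n_items, 2)
  out <- tibble(trial = seq_len(ncol(idx)),
                left = items[idx[1, ]],
                right = items[idx[2, ]])
  structure(out, n_pairs = ncol(idx))
}

#' Repeated-evaluation (RET) trial block
#'
#' The familiarization schedule of a repeated evaluation procedure: every
#' stimulus is rated on every evaluation variable, the full block repeated
#' `n_reps` times, each block shuffled independently. 8 presentations x 9
#' variables = 72 trials per block; three repetitions give 216.
#'
#' @param n_items,n_vars,n_reps Counts of stimuli, rating variables and
#'   block repetitions (all >= 0).
#' @param seed Seed for the blockwise shuffles.
#' @return Tibble with columns `trial`, `block`, `item`, `variable`.
#' @export
ret_trials <- function(n_items, n_vars, n_reps, seed = 1L) {
  if (any(c(n_items, n_vars, n_reps) < 0)) abort("counts must be >= 0")
  if (n_items * n_vars * n_reps == 0) {
    return(tibble(trial = integer(), block = integer(),
                  item = character(), variable = character()))
  }
  base <- tidyr::expand_grid(item = sprintf("item%02d", seq_len(n_items)),
                             variable = sprintf("var%02d", seq_len(n_vars)))
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_reps), function(b) {
      dplyr::mutate(base[sample.int(nrow(base)), ], block = b)
    })
  }) %>%
    dplyr::mutate(trial = dplyr::row_number()) %>%
    dplyr::select("trial", "block", "item", "variable")
}

#' Verification trial set over prototype versions
#'
#' One verification trial per prototype version (episodic and exhaustive
#' pooled), each pairing a face with a name. Within every model the trials
#' are split as evenly as possible between match (the model's own name) and
#' mismatch (the name of another model of the same sex), so match/mismatch
#' counts are counterbalanced within sex; the full set is then shuffled.
#'
#' @param versions Version tibble with columns `model`, `condition`
#'   (`"episodic"`/`"exhaustive"`), `version_id` (e.g. from
#'   [loo_versions()] output augmented with a model column).
#' @param name_map Tibble with columns `model`, `name`, `sex`.
#' @param seed Shuffle seed.
#' @return Tibble with columns `trial`, `model`, `version_id`, `condition`,
#'   `probe_name`, `is_match`.
#' @export
verification_trial_set <- function(versions, name_map, seed = 1L) {
  versions <- as_tibble(versions)
  name_map <- as_tibble(name_map)
  if (nrow(versions) == 0) abort("empty version list")
  if (!all(versions$model %in% name_map$model)) {
    abort("name_map must assign a name to every model")
  }
  withr::with_seed(seed, {
    # carry the odd-count remainder across same-sex models so match and
    # mismatch totals within each sex differ by at most one
    carry <- stats::setNames(rep(0L, length(unique(name_map$sex))),
                             unique(name_map$sex))
    out <- purrr::map_dfr(split(versions, versions$model), function(v) {
      mod <- v$model[[1]]
      own <- name_map$name[name_map$model == mod]
      sex <- name_map$sex[name_map$model == mod]
      foils <- name_map$name[name_map$sex == sex & name_map$model != mod]
      n <- nrow(v)
      n_match <- n %/% 2
      if (n %% 2 == 1 && carry[[sex]] <= 0) n_match <- n_match + 1L
      carry[[sex]] <<- carry[[sex]] + (2L * n_match - n)
      is_match <- sample(c(rep(TRUE, n_match), rep(FALSE, n - n_match)))
      if (length(foils) == 0 && any(!is_match)) {
        abort("mismatch trials need another model of the same sex")
      }
      dplyr::mutate(
        v,
        is_match = is_match,
        probe_name = ifelse(is_match, own,
                            sample(foils, n, replace = TRUE))
      )
    })
    out <- out[sample.int(nrow(out)), ]
  })
  out %>%
    dplyr::mutate(trial = dplyr::row_number()) %>%
    dplyr::select("trial", "model", "version_id", "condition",
                  "probe_name", "is_match")
}

#' Reaction-time outlier filter
#'
#' Removes, in a single pass, RTs faster than 200 ms (a global validity
#' floor) and RTs more than 2.5 SD above the participant's own mean, with
#' mean and SD computed once on that participant's raw data (no iterative
#' re-filtering).
#'
#' @param rts Tibble with columns `participant` and `rt` (ms, positive).
#' @return List with `kept` and `removed` tibbles and the global
#'   `loss_fraction`.
#' @export
rt_filter <- function(rts) {
  rts <- as_tibble(rts)
  if (nrow(rts) == 0) abort("empty RT table")
  if (any(rts$rt <= 0)) abort("RTs must be positive")
  flagged <- rts %>%
    dplyr::group_by(.data$participant) %>%
    dplyr::mutate(
      upper = mean(.data$rt) + 2.5 * stats::sd(.data$rt),
      out = .data$rt < 200 | (!is.na(.data$upper) & .data$rt > .data$upper)
    ) %>%
    dplyr::ungroup()
  list(kept = dplyr::select(dplyr::filter(flagged, !.data$out),
                            -"upper", -"out"),
       removed = dplyr::select(dplyr::filter(flagged, .data$out),
                               -"upper", -"out"),
       loss_fraction = mean(flagged$out))
}

#' Cohen's d from group means and SDs
#'
#' Pooled-SD standardized mean difference,
#' `d = (m1 - m2) / sqrt((sd1^2 + sd2^2) / 2)` (equal-weight pooling).
#'
#' @param m1,sd1 Mean and SD of group 1.
#' @param m2,sd2 Mean and SD of group 2.
#' @return One-row tibble: `kind`, `value`, and the echoed inputs.
#' @export
cohen_d <- function(m1, sd1, m2, sd2) {
  if (sd1 < 0 || sd2 < 0) abort("SDs must be nonnegative")
  if (sd1 == 0 && sd2 == 0) abort("at least one SD must be positive")
  tibble(kind = "cohen_d",
         value = (m1 - m2) / sqrt((sd1^2 + sd2^2) / 2),
         m1 = m1, sd1 = sd1, m2 = m2, sd2 = sd2)
}

#' Partial eta squared from an F statistic
#'
#' `eta_p^2 = F * df1 / (F * df1 + df2)`, the association-strength measure
#' reported alongside repeated-measures F tests.
#'
#' @param F_value F statistic (>= 0).
#' @param df1,df2 Numerator and denominator degrees of freedom (>= 1).
#' @return One-row tibble: `kind`, `value`, and the echoed inputs.
#' @export
partial_eta_sq <- function(F_value, df1, df2) {
  if (F_value < 0) abort("F must be >= 0")
  if (df1 < 1 || df2 < 1) abort("degrees of freedom must be >= 1")
  tibble(kind = "partial_eta_sq",
         value = F_value * df1 / (F_value * df1 + df2),
         F_value = F_value, df1 = df1, df2 = df2)
}

#' Fisher-Z-aggregated squared correlation
#'
#' Averages per-participant correlations on the Fisher Z scale and reports
#' the squared back-transformed mean:
#' `r^2 = tanh(mean(atanh(r_i)))^2` — the aggregation used when a regression
#' is fitted per participant and summarised across the sample.
#'
#' @param r Vector of per-participant correlations, each strictly inside
#'   (-1, 1).
#' @return One-row tibble: `n`, `mean_z`, `r` (back-transformed mean),
#'   `r_squared`, `slope_sign`.
#' @export
fisherz_r2 <- function(r) {
  if (any(abs(r) >= 1)) abort("correlations must lie strictly in (-1, 1)")
  mean_z <- mean(atanh(r))
  rbar <- tanh(mean_z)
  tibble(n = length(r), mean_z = mean_z, r = rbar,
         r_squared = rbar^2, slope_sign = sign(rbar))
}

#' Export a trial set to CSV
#'
#' @param trials A trial-set tibble.
#' @param path File path.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE)
  invisible(path)
}
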