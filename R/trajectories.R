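#' Generate a lifespan face-feature trajectory
#'
#' Simulates the appearance of one identity across life as a random walk in an
#' abstract d-dimensional face space. The per-year drift scale decreases with
#' age as `sigma(age) = sigma0 / (1 + age / tau)`, so facial change is strong
#' in the early years and levels off later. On top of the slow drift, discrete
#' appearance jumps (a haircut, an accident, a style change) can be injected
#' at known ages: each jump displaces the walk by `magnitude` along a random
#' unit direction, and the age of every jump is retained as ground truth so
#' that segmentation methods can be scored against it.
#'
#' Between consecutive exemplars the walk accumulates Gaussian steps whose
#' per-dimension variance is the exact integral of `sigma(age)^2` over the
#' elapsed ages, so the marginal variance of the path does not depend on how
#' densely it is sampled.
#'
#' @param identity_id Label of the simulated identity.
#' @param n_exemplars Number of dated appearances to generate (default 20).
#' @param age_start,age_end Age span in years (default 0--60, giving the
#'   classic 20 exemplars at roughly 3-year spacing).
#' @param spacing_jitter Uniform jitter (years) applied to interior capture
#'   ages; 0 gives exactly even spacing.
#' @param d Feature-space dimension (default 16).
#' @param sigma0 Drift scale (feature units per sqrt-year) at age 0.
#' @param tau Age constant (years) of the drift decay; `Inf` gives
#'   age-constant drift.
#' @param jumps `NULL`, or a data frame with columns `age` and `magnitude`
#'   giving deterministic sudden-change events within the age span.
#' @param baseline_sd SD of the identity's baseline appearance at `age_start`.
#' @param ages Optional explicit capture ages (strictly increasing);
#'   overrides `n_exemplars`, `age_start`, `age_end` and `spacing_jitter`.
#' @param seed Integer seed; identical seeds give identical trajectories.
#'
#' @return A tibble of class `epm_trajectory` with columns `exemplar_id`,
#'   `identity_id`, `capture_age`, the ground-truth `segment` (1 + number of
#'   jumps experienced), and features `f0 ... f{d-1}`. The jump table and
#'   drift parameters are attached as attributes `jumps` and `drift`.
#' @examples
#' tr <- generate_trajectory("id1", seed = 1,
#'                           jumps = data.frame(age = 30, magnitude = 10))
#' attr(tr, "jumps")
#' @export
generate_trajectory <- function(identity_id,
                                n_exemplars = 20,
                                age_start = 0,
                                age_end = 60,
                                spacing_jitter = 0.25,
                                d = 16,
                                sigma0 = 0.25,
                                tau = 20,
                                jumps = NULL,
                                baseline_sd = 1,
                                ages = NULL,
                                seed = NULL) {
  if (!is.null(ages)) {
    .assert_finite(ages, "ages")
    if (is.unsorted(ages, strictly = TRUE)) abort("ages must be strictly increasing")
    n_exemplars <- length(ages)
    age_start <- ages[1]
    age_end <- ages[length(ages)]
    if (n_exemplars > 1 && age_end <= age_start) abort("ages must span an interval")
  }
  .assert_finite(c(n_exemplars, age_start, age_end, spacing_jitter, d,
                   sigma0, baseline_sd), "trajectory parameters")
  if (!is.finite(tau) && !is.infinite(tau)) abort("tau must be finite or Inf")
  if (n_exemplars < 1) abort("n_exemplars must be >= 1")
  if (is.null(ages) && age_end <= age_start) abort("age_end must exceed age_start")
  if (sigma0 < 0) abort("sigma0 must be nonnegative")
  if (!is.null(jumps)) {
    jumps <- as_tibble(jumps)
    if (!all(c("age", "magnitude") %in% names(jumps))) {
      abort("jumps needs columns `age` and `magnitude`")
    }
    .assert_finite(c(jumps$age, jumps$magnitude), "jump events")
    if (any(jumps$age < age_start | jumps$age > age_end)) {
      abort("jump ages must lie within [age_start, age_end]")
    }
    jumps <- dplyr::arrange(jumps, .data$age)
  } else {
    jumps <- tibble(age = numeric(), magnitude = numeric())
  }

  fixed_ages <- ages
  gen <- function() {
    if (is.null(fixed_ages)) {
      ages <- seq(age_start, age_end, length.out = n_exemplars)
      if (n_exemplars > 2 && spacing_jitter > 0) {
        ages[2:(n_exemplars - 1)] <- ages[2:(n_exemplars - 1)] +
          stats::runif(n_exemplars - 2, -spacing_jitter, spacing_jitter)
        ages <- sort(ages)
      }
    } else {
      ages <- fixed_ages
    }
    x <- matrix(0, n_exemplars, d)
    x[1, ] <- stats::rnorm(d, 0, baseline_sd)
    jump_dirs <- matrix(stats::rnorm(nrow(jumps) * d), nrow(jumps), d)
    if (nrow(jumps) > 0) {
      jump_dirs <- jump_dirs / sqrt(rowSums(jump_dirs^2))
    }
    # jumps at or before the first capture age displace the baseline
    applied <- jumps$age <= ages[1]
    for (j in which(applied)) {
      x[1, ] <- x[1, ] + jumps$magnitude[j] * jump_dirs[j, ]
    }
    seg <- integer(n_exemplars)
    seg[1] <- 1L + sum(applied)
    if (n_exemplars > 1) {
      for (i in 2:n_exemplars) {
        v <- .drift_variance(ages[i - 1], ages[i], sigma0, tau)
        x[i, ] <- x[i - 1, ] + stats::rnorm(d, 0, sqrt(v))
        newly <- which(jumps$age > ages[i - 1] & jumps$age <= ages[i])
        for (j in newly) {
          x[i, ] <- x[i, ] + jumps$magnitude[j] * jump_dirs[j, ]
        }
        seg[i] <- seg[i - 1] + length(newly)
      }
    }
    list(ages = ages, x = x, seg = seg)
  }
  out <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())

  feats <- as_tibble(out$x, .name_repair = ~ paste0("f", seq_len(d) - 1))
  tr <- dplyr::bind_cols(
    tibble(
      exemplar_id = sprintf("%s_e%02d", identity_id, seq_len(n_exemplars)),
      identity_id = identity_id,
      capture_age = out$ages,
      segment = out$seg
    ),
    feats
  )
  structure(tr,
            class = c("epm_trajectory", class(tr)),
            jumps = jumps,
            drift = list(sigma0 = sigma0, tau = tau))
}

# Exact per-dimension variance accumulated by the walk between ages a1 < a2:
# integral of sigma(t)^2 dt with sigma(t) = sigma0 / (1 + t/tau).
.drift_variance <- function(a1, a2, sigma0, tau) {
  if (is.infinite(tau)) return(sigma0^2 * (a2 - a1))
  sigma0^2 * tau * (1 / (1 + a1 / tau) - 1 / (1 + a2 / tau))
}

#' Pairwise dissimilarity matrix of an exemplar table
#'
#' Euclidean distances between the feature vectors of all exemplars; the
#' face-space metric used throughout the clustering pipeline.
#'
#' @param exemplars An exemplar table (see [generate_trajectory()]) or a
#'   numeric feature matrix with rownames.
#' @return Square symmetric matrix with zero diagonal, dimnames =
#'   exemplar ids.
#' @export
dissimilarity_matrix <- function(exemplars) {
  m <- if (is.matrix(exemplars)) exemplars else feature_matrix(exemplars)
  if (nrow(m) < 2) abort("need at least 2 exemplars")
  as.matrix(stats::dist(m))
}

#' Simulate Likert similarity ratings from a dissimilarity matrix
#'
#' Maps face-space distances onto a noisy 7-point similarity scale
#' (1 = very unsimilar, 7 = very similar), emulating a pairwise
#' similarity-rating task. The mapping is affine in distance,
#' `7 - 6 * D/max(D)`, plus Gaussian rater noise, rounded and clamped to
#' `{1..7}`. When all distances are zero every rating is 7.
#'
#' @param D Square symmetric dissimilarity matrix.
#' @param noise_sd SD of the additive rater noise (rating units).
#' @param seed Integer seed for the noise.
#' @return Symmetric integer matrix of ratings in 1..7 with `NA` diagonal,
#'   class `epm_ratings`.
#' @export
simulate_ratings <- function(D, noise_sd = 0.5, seed = NULL) {
  .check_dissim(D)
  if (noise_sd < 0) abort("noise_sd must be nonnegative")
  n <- nrow(D)
  dmax <- max(D)
  gen <- function() {
    R <- matrix(NA_integer_, n, n, dimnames = dimnames(D))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        base <- if (dmax == 0) 7 else 7 - 6 * D[i, j] / dmax
        r <- round(base + stats::rnorm(1, 0, noise_sd))
        R[i, j] <- R[j, i] <- as.integer(min(7, max(1, r)))
      }
    }
    R
  }
  R <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  structure(R, class = c("epm_ratings", class(R)))
}

.check_dissim <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) abort("D must be a square matrix")
  if (max(abs(D - t(D))) > 1e-8) abort("D must be symmetric")
  if (any(abs(diag(D)) > 1e-8)) abort("D must have a zero diagonal")
  invisible(D)
}

#' Write / read exemplar tables as CSV
#'
#' Plain-CSV exchange format: columns
#' `exemplar_id,identity_id,capture_age,f0..f{d-1}` (ground-truth columns are
#' dropped on write).
#'
#' @param exemplars Exemplar table.
#' @param path File path.
#' @return `read_exemplars()` returns a tibble; `write_exemplars()` its path,
#'   invisibly.
#' @export
write_exemplars <- function(exemplars, path) {
  keep <- c("exemplar_id", "identity_id", "capture_age",
            feature_cols(exemplars))
  utils::write.csv(as.data.frame(exemplars)[, keep], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_exemplars
#' @export
read_exemplars <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write / read square dissimilarity matrices as CSV
#'
#' Header row of exemplar ids, square numeric body.
#'
#' @param D Square symmetric matrix.
#' @param path File path.
#' @export
write_dissimilarity <- function(D, path) {
  .check_dissim(D)
  utils::write.csv(as.data.frame(D), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dissimilarity
#' @export
read_dissimilarity <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  D <- as.matrix(df)
  dimnames(D) <- list(colnames(df), colnames(df))
  .check_dissim(D)
  D
}

#' @export
#' @method autoplot epm_trajectory
autoplot.epm_trajectory <- function(object, ...) {
  coords <- mds_embed(dissimilarity_matrix(object), dim = 2)
  df <- tibble(
    x = coords[, 1], y = coords[, 2],
    capture_age = object$capture_age,
    segment = factor(object$segment)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$segment,
                                     size = .data$capture_age)) +
    ggplot2::scale_size_continuous(range = c(1.5, 4)) +
    ggplot2::labs(x = "face-space dim 1", y = "face-space dim 2",
                  colour = "episode", size = "age (yr)",
                  title = unique(object$identity_id)) +
    ggplot2::theme_minimal()
}
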