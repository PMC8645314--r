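#' Create an empty episodic-prototype memory store
#'
#' The store holds every face trace an observer has encoded, partitioned into
#' episodic prototypes. A new trace joins the prototype to which its maximum
#' delta (largest Euclidean distance to the prototype's centroid and members)
#' is smallest, unless even that distance exceeds the pre-fixed threshold
#' delta, in which case the trace founds a new prototype on the spot. With a
#' threshold larger than the data diameter the store degenerates to a single
#' exhaustive prototype; with threshold 0 (and all-distinct traces) to a pure
#' exemplar model — the two classical poles the episodic-prototype account
#' sits between.
#'
#' Retrieval is echo-based: see [echo()], [prototypicality()], [verify()].
#' Recency is modelled by exponentially decaying trace weights with the given
#' half-life; `Inf` disables recency weighting.
#'
#' @param threshold_delta Nonnegative threshold on the maximum delta
#'   (feature-space distance units) above which a new prototype is created.
#' @param recency_half_life Half-life (in encoding-time units, typically
#'   years) of the trace recency weight; `Inf` for no decay.
#' @return An object of class `epm_store`.
#' @seealso [assimilate()], [assimilate_stream()]
#' @export
memory_store <- function(threshold_delta, recency_half_life = Inf) {
  if (threshold_delta < 0) abort("threshold_delta must be >= 0")
  if (recency_half_life <= 0) abort("recency_half_life must be positive")
  structure(
    list(prototypes = list(),
         threshold_delta = threshold_delta,
         recency_half_life = recency_half_life,
         now = -Inf),
    class = "epm_store"
  )
}

#' @export
print.epm_store <- function(x, ...) {
  cat(sprintf(
    "<epm_store> %d prototype(s), %d trace(s), threshold_delta = %g, half-life = %g, now = %g\n",
    length(x$prototypes), sum(vapply(x$prototypes, function(p) nrow(p$f), 1L)),
    x$threshold_delta, x$recency_half_life, x$now))
  invisible(x)
}

#' Cosine similarity between a probe and a stored trace
#'
#' The first retrieval step: similarity of the probe to a single stored
#' exemplar, as the cosine of the angle between their feature vectors, in
#' `[-1, 1]`. A zero trace vector yields similarity 0.
#'
#' @param probe Numeric probe feature vector (must be nonzero).
#' @param trace Numeric trace feature vector of the same dimension.
#' @return Scalar in `[-1, 1]`.
#' @export
trace_similarity <- function(probe, trace) {
  if (length(probe) != length(trace)) abort("dimension mismatch")
  np <- sqrt(sum(probe^2))
  if (np == 0) abort("probe vector must be nonzero")
  nt <- sqrt(sum(trace^2))
  if (nt == 0) return(0)
  sum(probe * trace) / (np * nt)
}

# Stack all traces of a store (or of one prototype) into matrices/vectors.
.store_traces <- function(store, prototype = NULL) {
  protos <- if (is.null(prototype)) store$prototypes else list(prototype)
  if (length(protos) == 0) abort("memory store is empty")
  list(
    f = do.call(rbind, lapply(protos, function(p) p$f)),
    exemplar_id = unlist(lapply(protos, function(p) p$exemplar_id)),
    encoding_time = unlist(lapply(protos, function(p) p$encoding_time))
  )
}

.recency_weights <- function(store, encoding_time) {
  if (is.infinite(store$recency_half_life)) return(rep(1, length(encoding_time)))
  2^(-(store$now - encoding_time) / store$recency_half_life)
}

#' Echo of a probe against a memory store
#'
#' Computes the multiple-trace echo: each trace's cosine similarity `S_i` to
#' the probe is turned into a sign-preserving cubic activation `A_i = S_i^3`
#' (so highly similar traces dominate), weighted by the recency weight
#' `w_i = 2^-(now - t_i)/half_life`. The echo intensity is `sum(w_i * A_i)`
#' and the echo content is the activation-weighted sum of the trace vectors.
#'
#' @param probe Numeric probe vector.
#' @param store An `epm_store`.
#' @param prototype Optional single prototype (element of `store$prototypes`)
#'   to restrict the echo to; by default the echo pools all traces.
#' @return An object of class `epm_echo`: list with `intensity`, `content`,
#'   and a `per_trace` tibble (`exemplar_id`, `similarity`, `activation`,
#'   `weight`).
#' @export
echo <- function(probe, store, prototype = NULL) {
  tr <- .store_traces(store, prototype)
  if (ncol(tr$f) != length(probe)) abort("dimension mismatch")
  s <- vapply(seq_len(nrow(tr$f)),
              function(i) trace_similarity(probe, tr$f[i, ]), 0)
  a <- s^3
  w <- .recency_weights(store, tr$encoding_time)
  structure(
    list(intensity = sum(w * a),
         content = as.numeric(crossprod(tr$f, w * a)),
         per_trace = tibble(exemplar_id = tr$exemplar_id,
                            similarity = s, activation = a, weight = w)),
    class = "epm_echo"
  )
}

#' Maximum delta of an exemplar to a prototype
#'
#' The decision variable of prototype genesis: the largest Euclidean distance
#' from the candidate exemplar's feature vector to the prototype's centroid
#' and to each of its member traces.
#'
#' @param exemplar Numeric feature vector of the candidate exemplar.
#' @param prototype A prototype (element of an `epm_store`'s `prototypes`).
#' @return Nonnegative scalar.
#' @export
max_delta <- function(exemplar, prototype) {
  if (length(exemplar) != length(prototype$centroid)) abort("dimension mismatch")
  d_centroid <- .euclid(exemplar, prototype$centroid)
  d_members <- apply(prototype$f, 1, function(r) .euclid(exemplar, r))
  max(d_centroid, d_members)
}

#' Assimilate one exemplar into the memory store
#'
#' The online genesis step. The maximum delta of the new exemplar to every
#' existing prototype is computed; if the smallest of these exceeds the
#' store's threshold delta (or the store is empty) a new prototype is founded
#' with the exemplar as its sole member, otherwise the exemplar is integrated
#' into the closest prototype (smallest maximum delta, ties going to the most
#' recently created prototype) and that prototype's centroid is updated as
#' the incremental mean of its members — so each additional exemplar moves
#' the centroid by only 1/n of its deviation. Prototypes are never merged or
#' re-assigned afterwards; the process is forward-only and order-dependent.
#'
#' @param store An `epm_store`.
#' @param exemplar Numeric feature vector.
#' @param time Encoding time (must be >= the store's current time).
#' @param exemplar_id Optional trace label.
#' @param capture_age Source capture age of the exemplar (defaults to `time`).
#' @return The updated `epm_store`.
#' @export
assimilate <- function(store, exemplar, time,
                       exemplar_id = NULL, capture_age = time) {
  exemplar <- unname(as.numeric(exemplar))
  .assert_finite(exemplar, "exemplar features")
  if (!is.finite(time)) abort("time must be finite")
  if (time < store$now) {
    abort("stream must be chronological: time precedes store$now")
  }
  if (is.null(exemplar_id)) {
    exemplar_id <- sprintf("trace%04d",
                           sum(vapply(store$prototypes,
                                      function(p) nrow(p$f), 1L)) + 1L)
  }
  store$now <- time
  k <- length(store$prototypes)
  if (k > 0) {
    deltas <- vapply(store$prototypes,
                     function(p) max_delta(exemplar, p), 0)
  } else {
    deltas <- numeric()
  }
  # tolerance keeps the bracketing exact when the threshold equals the
  # data diameter up to floating-point error
  tol <- 1e-9 * max(1, store$threshold_delta)
  if (k == 0 || min(deltas) > store$threshold_delta + tol) {
    store$prototypes[[k + 1]] <- list(
      id = sprintf("P%03d", k + 1L),
      centroid = exemplar,
      f = matrix(exemplar, 1, dimnames = list(exemplar_id, NULL)),
      exemplar_id = exemplar_id,
      encoding_time = time,
      capture_age = capture_age,
      created_at = time
    )
  } else {
    # ties broken toward the most recently created prototype
    best <- max(which(deltas == min(deltas)))
    p <- store$prototypes[[best]]
    p$f <- rbind(p$f, exemplar)
    rownames(p$f)[nrow(p$f)] <- exemplar_id
    p$exemplar_id <- c(p$exemplar_id, exemplar_id)
    p$encoding_time <- c(p$encoding_time, time)
    p$capture_age <- c(p$capture_age, capture_age)
    p$centroid <- p$centroid + (exemplar - p$centroid) / nrow(p$f)
    store$prototypes[[best]] <- p
  }
  store
}

#' Assimilate a whole exemplar table in capture-age order
#'
#' Convenience wrapper feeding the rows of an exemplar table (see
#' [generate_trajectory()]) through [assimilate()] in chronological order,
#' using `capture_age` as encoding time.
#'
#' @param store An `epm_store`.
#' @param exemplars Exemplar table.
#' @return The updated `epm_store`.
#' @export
assimilate_stream <- function(store, exemplars) {
  exemplars <- dplyr::arrange(as_tibble(exemplars), .data$capture_age)
  fm <- feature_matrix(exemplars)
  for (i in seq_len(nrow(fm))) {
    store <- assimilate(store, fm[i, ], time = exemplars$capture_age[i],
                        exemplar_id = exemplars$exemplar_id[i])
  }
  store
}

#' Prototypicality of a probe face
#'
#' Recency-weighted echo intensity of the probe against all traces pooled —
#' the model quantity standing in for a rated typicality judgement: faces
#' resembling recently encoded traces feel more "like the person".
#'
#' @inheritParams echo
#' @return Scalar; larger = more prototypical.
#' @export
prototypicality <- function(probe, store) {
  echo(probe, store)$intensity
}

#' Verify a probe face against the memory store
#'
#' Face-verification decision with a simulated latency. The probe is echoed
#' against each prototype separately; the verification strength is the
#' strongest per-prototype echo intensity. A match is declared when the
#' strength reaches `decision_threshold`, and the simulated reaction time is
#' `base_ms - slope_ms * log(strength)` (strength floored at 1e-6), clamped
#' below at 200 ms so simulated latencies respect the usual validity floor
#' for human RTs.
#'
#' @param store An `epm_store`.
#' @param probe Numeric probe vector.
#' @param decision_threshold Strength required for a match.
#' @param rt_base_ms,rt_slope_ms Latency linking parameters (ms); the slope
#'   must be positive.
#' @return Tibble with one row: `match`, `strength`, `latency_ms`,
#'   `best_prototype`.
#' @export
verify <- function(store, probe, decision_threshold,
                   rt_base_ms = 800, rt_slope_ms = 100) {
  if (rt_slope_ms <= 0) abort("rt_slope_ms must be positive")
  if (length(store$prototypes) == 0) abort("memory store is empty")
  strengths <- vapply(store$prototypes,
                      function(p) echo(probe, store, prototype = p)$intensity,
                      0)
  best <- which.max(strengths)
  strength <- strengths[best]
  latency <- max(200, rt_base_ms - rt_slope_ms * log(max(strength, 1e-6)))
  tibble(match = strength >= decision_threshold,
         strength = strength,
         latency_ms = latency,
         best_prototype = store$prototypes[[best]]$id)
}

#' Calibrate the threshold delta from ground-truth segments
#'
#' For synthetic trajectories with known jump events, returns the midpoint
#' between the largest within-segment diameter (distances a prototype must
#' absorb) and the smallest across-jump displacement (distances that must
#' found a new prototype). Warns when the two overlap, i.e. when no single
#' threshold can separate drift from jumps.
#'
#' @param trajectory An `epm_trajectory` with a ground-truth `segment` column.
#' @return Scalar threshold delta.
#' @export
calibrate_threshold <- function(trajectory) {
  if (!"segment" %in% names(trajectory)) abort("trajectory lacks ground-truth segments")
  fm <- feature_matrix(trajectory)
  seg <- trajectory$segment
  diam <- max(vapply(split(seq_len(nrow(fm)), seg), function(idx) {
    if (length(idx) < 2) return(0)
    max(stats::dist(fm[idx, , drop = FALSE]))
  }, 0))
  bounds <- unique(seg)
  bounds <- bounds[-length(bounds)]
  gaps <- vapply(bounds, function(s) {
    last_prev <- max(which(seg == s))
    first_next <- min(which(seg == s + 1))
    .euclid(fm[last_prev, ], fm[first_next, ])
  }, 0)
  if (length(gaps) == 0) return(diam + 1)
  if (min(gaps) <= diam) {
    warn("within-segment diameter reaches across-jump displacement; threshold may not separate")
  }
  (diam + min(gaps)) / 2
}

#' @export
#' @method tidy epm_store
tidy.epm_store <- function(x, ...) {
  purrr::map_dfr(x$prototypes, function(p) {
    tibble(prototype = p$id,
           exemplar_id = p$exemplar_id,
           encoding_time = p$encoding_time,
           capture_age = p$capture_age,
           created_at = p$created_at)
  })
}

#' @export
#' @method glance epm_store
glance.epm_store <- function(x, ...) {
  tibble(n_prototypes = length(x$prototypes),
         n_traces = sum(vapply(x$prototypes, function(p) nrow(p$f), 1L)),
         threshold_delta = x$threshold_delta,
         recency_half_life = x$recency_half_life,
         now = x$now)
}

#' Prototype summary of a memory store
#'
#' @param store An `epm_store`.
#' @return Tibble with one row per prototype: id, member count, age span,
#'   creation time, and the centroid as a list column.
#' @export
prototype_table <- function(store) {
  purrr::map_dfr(store$prototypes, function(p) {
    tibble(prototype = p$id,
           n_members = nrow(p$f),
           age_min = min(p$capture_age),
           age_max = max(p$capture_age),
           created_at = p$created_at,
           centroid = list(p$centroid))
  })
}

#' Serialize / restore a memory store as JSON
#'
#' Lossless round trip of prototypes, members, parameters and the clock.
#'
#' @param store An `epm_store`.
#' @param path File path.
#' @export
write_store <- function(store, path) {
  doc <- list(
    threshold_delta = store$threshold_delta,
    recency_half_life = .inf_encode(store$recency_half_life),
    now = .inf_encode(store$now),
    prototypes = lapply(store$prototypes, function(p) {
      list(id = p$id, centroid = p$centroid,
           members = lapply(seq_along(p$exemplar_id), function(i) {
             list(exemplar_id = p$exemplar_id[i],
                  encoding_time = p$encoding_time[i],
                  capture_age = p$capture_age[i],
                  feature_vector = as.numeric(p$f[i, ]))
           }),
           created_at = p$created_at)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_store
#' @export
read_store <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  store <- memory_store(doc$threshold_delta, .inf_decode(doc$recency_half_life))
  store$now <- .inf_decode(doc$now)
  store$prototypes <- lapply(doc$prototypes, function(p) {
    f <- do.call(rbind, lapply(p$members, function(m) unlist(m$feature_vector)))
    ids <- vapply(p$members, function(m) m$exemplar_id, "")
    rownames(f) <- ids
    list(id = p$id,
         centroid = unlist(p$centroid),
         f = f,
         exemplar_id = ids,
         encoding_time = vapply(p$members, function(m) m$encoding_time, 0),
         capture_age = vapply(p$members, function(m) m$capture_age, 0),
         created_at = p$created_at)
  })
  store
}

.inf_encode <- function(x) if (is.infinite(x)) paste0(sign(x) * 1, "Inf") else x
.inf_decode <- function(x) {
  if (identical(x, "1Inf")) return(Inf)
  if (identical(x, "-1Inf")) return(-Inf)
  as.numeric(x)
}

#' @export
#' @method autoplot epm_store
autoplot.epm_store <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$capture_age, .data$prototype,
                                   colour = .data$prototype)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "capture age (yr)", y = NULL,
                  title = "prototype membership along the lifespan") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
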