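#' Classical MDS embedding of a dissimilarity matrix
#'
#' Torgerson scaling (double-centering of squared dissimilarities followed by
#' a spectral decomposition, via [stats::cmdscale()]). When the input is a
#' Euclidean distance matrix of intrinsic dimension at most `dim`, pairwise
#' distances of the embedding reproduce the input exactly; otherwise the
#' discarded spectrum is reported as `attr(, "stress")` (sum of the dropped
#' positive eigenvalues).
#'
#' @param D Square symmetric dissimilarity matrix with zero diagonal.
#' @param dim Embedding dimension (default 2, the plotted face-space).
#' @return Numeric coordinate matrix (n x dim), rownames carried over, with
#'   attributes `eig` (all eigenvalues) and `stress`.
#' @export
mds_embed <- function(D, dim = 2) {
  .check_dissim(D)
  n <- nrow(D)
  if (dim >= n) abort("dim must be smaller than the number of points")
  fit <- stats::cmdscale(D, k = dim, eig = TRUE)
  coords <- fit$points
  if (ncol(coords) < dim) {  # degenerate input: pad zero dimensions
    coords <- cbind(coords, matrix(0, n, dim - ncol(coords)))
  }
  rownames(coords) <- rownames(D)
  pos <- fit$eig[fit$eig > 1e-9]
  structure(coords, eig = fit$eig,
            stress = sum(pos[-seq_len(min(dim, length(pos)))]))
}

# Total within-cluster sum of squares of a labeling, computed from the
# dissimilarity matrix via the Euclidean identity
#   W_c = (1/n_c) * sum_{i<j in c} D_ij^2.
.within_ss_D <- function(D, labels) {
  sum(vapply(split(seq_len(nrow(D)), labels), function(idx) {
    if (length(idx) < 2) return(0)
    sum(D[idx, idx]^2) / (2 * length(idx))
  }, 0))
}

.within_ss_coords <- function(coords, labels) {
  sum(vapply(split(seq_len(nrow(coords)), labels), function(idx) {
    m <- coords[idx, , drop = FALSE]
    sum(sweep(m, 2, colMeans(m))^2)
  }, 0))
}

.new_solution <- function(k, labels, within_ss, method, ...) {
  structure(list(k = k, labels = labels, within_ss = within_ss,
                 method = method, ...),
            class = "epm_clusters")
}

#' @export
print.epm_clusters <- function(x, ...) {
  cat(sprintf("<epm_clusters> k = %d (%s), within-SS = %.4g, n = %d\n",
              x$k, x$method, x$within_ss, length(x$labels)))
  invisible(x)
}

#' @export
#' @method tidy epm_clusters
tidy.epm_clusters <- function(x, ...) {
  tibble(exemplar_id = names(x$labels), cluster = unname(x$labels))
}

#' @export
#' @method glance epm_clusters
glance.epm_clusters <- function(x, ...) {
  tibble(k = x$k, within_ss = x$within_ss, method = x$method,
         n = length(x$labels))
}

#' Ward hierarchical clustering cut at k clusters
#'
#' Agglomerative clustering under Ward's minimum-increase-in-SS criterion
#' (squared Euclidean implementation, `hclust(method = "ward.D2")`), with the
#' dendrogram cut at `k`.
#'
#' @param D Square symmetric Euclidean dissimilarity matrix.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return An `epm_clusters` solution; `within_ss` is the total
#'   within-cluster sum of squares implied by `D`.
#' @export
ward_cluster <- function(D, k) {
  .check_dissim(D)
  if (k < 1 || k > nrow(D)) abort("k must be in 1..n")
  hc <- stats::hclust(stats::as.dist(D), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  names(labels) <- rownames(D)
  .new_solution(k, labels, .within_ss_D(D, labels), "ward", hclust = hc)
}

# k-means W_k profile over k = 1..k_max on a coordinate matrix; guarded
# against k exceeding the number of distinct points.
.kmeans_W <- function(coords, k, seed = 1L, nstart = 10L) {
  n_distinct <- nrow(unique(round(coords, 12)))
  if (k == 1) return(.within_ss_coords(coords, rep(1, nrow(coords))))
  if (k >= n_distinct) return(0)
  withr::with_seed(seed, suppressWarnings(
    stats::kmeans(coords, centers = k, nstart = nstart,
                  iter.max = 100)$tot.withinss))
}

#' Elbow profile of within-cluster sum of squares
#'
#' Runs k-means for `k = 1..k_max` (fixed seed) and looks for a distinct drop
#' of the within-groups sum of squares. The suggested k maximises the second
#' difference `W_{k-1} - 2 W_k + W_{k+1}`, and the drop counts as distinct
#' only when it leaves less than 10% of `W_1` behind; smooth power-law
#' profiles (no real elbow) instead fall back to the first k whose W drops
#' below 10% of `W_1`.
#'
#' @param coords Coordinate matrix (points x dims).
#' @param k_max Largest k profiled; must be at least 3 to bracket an elbow.
#' @param seed Seed for the k-means restarts.
#' @return Tibble of `(k, within_ss)` with attributes `suggested_k` and
#'   `distinct_elbow`.
#' @export
elbow_profile <- function(coords, k_max, seed = 1L) {
  if (k_max < 3) abort("k_max must be >= 3 to identify an elbow")
  if (k_max > nrow(coords)) abort("k_max must not exceed n")
  W <- vapply(seq_len(k_max), function(k) .kmeans_W(coords, k, seed), 0)
  W <- cummin(W)  # enforce profile monotonicity against k-means local minima
  d2 <- W[seq_len(k_max - 2)] - 2 * W[seq(2, k_max - 1)] + W[seq(3, k_max)]
  k_curv <- which.max(d2) + 1L
  # a distinct drop leaves only a small residual dispersion behind; smooth
  # power-law profiles (no real elbow) fail this and fall back
  distinct <- W[1] > 0 && W[k_curv] < 0.1 * W[1]
  if (distinct) {
    suggested <- k_curv
  } else {
    below <- which(W < 0.1 * W[1])
    suggested <- if (length(below)) min(below) else k_max
  }
  structure(tibble(k = seq_len(k_max), within_ss = W),
            suggested_k = as.integer(suggested), distinct_elbow = distinct)
}

#' Gap statistic for choosing the number of clusters
#'
#' Compares the log within-cluster dispersion of the data with that of `B`
#' reference datasets drawn uniformly over the data's bounding box:
#' `Gap(k) = mean_b log W_k(ref_b) - log W_k(data)`, with simulation error
#' `s_k = sd_b(log W_k(ref_b)) * sqrt(1 + 1/B)`. The chosen k is the smallest
#' k with `Gap(k) >= Gap(k+1) - s_{k+1}`.
#'
#' @param coords Coordinate matrix.
#' @param k_max Largest k evaluated.
#' @param B Number of reference datasets (>= 10).
#' @param seed Seed for the reference draws and k-means restarts.
#' @return Object of class `epm_gap`: tibble `(k, gap, se, log_W)` with
#'   attribute `chosen_k`.
#' @export
gap_statistic <- function(coords, k_max, B = 50, seed = 1L) {
  if (B < 10) abort("B must be >= 10")
  if (k_max < 1 || k_max > nrow(coords)) abort("k_max must be in 1..n")
  rng <- apply(coords, 2, range)
  if (any(rng[2, ] - rng[1, ] == 0) && ncol(coords) > 0 &&
      all(rng[2, ] - rng[1, ] == 0)) {
    abort("degenerate (zero-variance) data")
  }
  logW <- log(pmax(vapply(seq_len(k_max),
                          function(k) .kmeans_W(coords, k, seed), 0), 1e-12))
  ref_logW <- withr::with_seed(.child_seed(seed, 1), {
    vapply(seq_len(B), function(b) {
      ref <- apply(rng, 2, function(r) stats::runif(nrow(coords), r[1], r[2]))
      vapply(seq_len(k_max), function(k) {
        log(max(.kmeans_W(ref, k, seed = .child_seed(seed, b * k_max + k),
                          nstart = 5L), 1e-12))
      }, 0)
    }, numeric(k_max))
  })
  ref_logW <- matrix(ref_logW, nrow = k_max)
  gap <- rowMeans(ref_logW) - logW
  se <- apply(ref_logW, 1, stats::sd) * sqrt(1 + 1 / B)
  chosen <- k_max
  for (k in seq_len(k_max - 1)) {
    if (gap[k] >= gap[k + 1] - se[k + 1]) { chosen <- k; break }
  }
  structure(tibble(k = seq_len(k_max), gap = gap, se = se, log_W = logW),
            chosen_k = as.integer(chosen), B = B, class = c("epm_gap", "tbl_df", "tbl", "data.frame"))
}

#' @export
#' @method glance epm_gap
glance.epm_gap <- function(x, ...) {
  tibble(chosen_k = attr(x, "chosen_k"), B = attr(x, "B"),
         k_max = max(x$k))
}

#' @export
#' @method autoplot epm_gap
autoplot.epm_gap <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$k, .data$gap)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$gap - .data$se,
                                          ymax = .data$gap + .data$se)) +
    ggplot2::geom_vline(xintercept = attr(object, "chosen_k"),
                        linetype = "dashed") +
    ggplot2::labs(y = "Gap(k)", title = "gap statistic") +
    ggplot2::theme_minimal()
}

#' Two-step clustering of a face dissimilarity matrix
#'
#' The reference analysis route for one identity's exemplars: embed the
#' dissimilarities into the 2-D face-space ([mds_embed()]), choose the number
#' of clusters by consensus of the gap statistic (primary) and the elbow
#' criterion (when the two disagree by exactly one, the larger k wins), then
#' run a hierarchical Ward clustering cut at k and refine it with k-means
#' started from the Ward cluster means (no random restarts, so the whole
#' routine is deterministic given `D` and `seed`).
#'
#' @param D Square symmetric dissimilarity matrix (n >= 3).
#' @param k_max Largest k considered.
#' @param B Reference sets for the gap statistic.
#' @param seed Integer seed.
#' @param cluster_on Cluster on the MDS embedding (`"embedding"`, reference
#'   path) or directly on `D` via Ward only (`"dissimilarity"`). The embedding
#'   used for the statistics keeps every eigen-dimension carrying at least 5%
#'   of the leading eigenvalue (capped at 10), which avoids collapsing
#'   genuinely separated clusters when the data are not intrinsically planar;
#'   the reported `coords` are always the 2-D face-space for plotting.
#' @return An `epm_clusters` solution with `gap`, `elbow` and `coords`
#'   diagnostics attached.
#' @export
two_step <- function(D, k_max = 8, B = 50, seed = 1L,
                     cluster_on = c("embedding", "dissimilarity")) {
  .check_dissim(D)
  cluster_on <- match.arg(cluster_on)
  n <- nrow(D)
  if (n < 3) abort("need at least 3 exemplars")
  k_max <- min(k_max, n - 1)
  if (max(D) == 0) {
    labels <- stats::setNames(rep(1L, n), rownames(D))
    coords <- matrix(0, n, 2, dimnames = list(rownames(D), NULL))
    return(.new_solution(1L, labels, 0, "two_step",
                         gap = NULL, elbow = NULL, coords = coords))
  }
  coords <- mds_embed(D, dim = 2)
  # adaptive-dimension embedding for the statistics: keep every spectral
  # component above 5% of the leading eigenvalue (cap 10), so clusters that a
  # planar projection would collide stay separated
  eig <- attr(coords, "eig")
  cdim <- min(10L, n - 1L, max(2L, sum(eig > 0.05 * max(eig, 0))))
  cluster_coords <- if (cdim > 2) mds_embed(D, dim = cdim) else coords
  gap <- gap_statistic(cluster_coords, k_max, B = B, seed = seed)
  elb <- elbow_profile(cluster_coords, k_max, seed = seed)
  k_gap <- attr(gap, "chosen_k")
  k_elb <- attr(elb, "suggested_k")
  # The 1-SE stop rule can halt on a flat prefix of the gap curve when tight
  # clusters lie near a line (data and reference dispersion then shrink at the
  # same rate for k < k*), or overshoot when within-cluster structure keeps
  # the gap creeping upward past k*. A single-step jump of the gap curve
  # dominating its simulation error marks the true k and takes precedence.
  if (k_max > 1) {
    jumps <- diff(gap$gap)
    k_jump <- which.max(jumps) + 1L
    if (jumps[k_jump - 1L] > 2 * gap$se[k_jump]) {
      k_gap <- k_jump
    }
  }
  k <- if (abs(k_gap - k_elb) == 1) max(k_gap, k_elb) else k_gap
  ward <- ward_cluster(D, k)
  if (cluster_on == "dissimilarity") {
    sol <- .new_solution(k, ward$labels, ward$within_ss, "two_step_dissim",
                         gap = gap, elbow = elb, coords = coords)
    return(sol)
  }
  centers <- do.call(rbind, lapply(split(seq_len(n), ward$labels), function(idx) {
    colMeans(cluster_coords[idx, , drop = FALSE])
  }))
  km <- stats::kmeans(cluster_coords, centers = centers, iter.max = 50)
  labels <- stats::setNames(km$cluster, rownames(D))
  .new_solution(k, labels, km$tot.withinss, "two_step",
                gap = gap, elbow = elb, coords = coords,
                cluster_dim = cdim,
                ward_within_ss = .within_ss_coords(cluster_coords, ward$labels))
}

#' Flag singleton outliers of a cluster solution
#'
#' Members of singleton clusters whose nearest-neighbour distance exceeds the
#' 95th percentile of all nearest-neighbour distances are flagged as
#' outliers, mirroring the treatment of isolated, highly distinctive
#' exemplars in face-space analyses.
#'
#' @param solution An `epm_clusters` solution.
#' @param coords Coordinate matrix the solution refers to.
#' @return Character vector of flagged exemplar ids (possibly empty).
#' @export
flag_outliers <- function(solution, coords) {
  labels <- solution$labels
  n <- nrow(coords)
  if (n != length(labels)) abort("coords and solution disagree on n")
  D <- as.matrix(stats::dist(coords))
  diag(D) <- Inf
  nn <- apply(D, 1, min)
  cutoff <- stats::quantile(nn, 0.95, names = FALSE)
  singls <- names(table(labels))[table(labels) == 1]
  idx <- which(as.character(labels) %in% singls & nn > cutoff)
  names(labels)[idx]
}

#' @export
#' @method autoplot epm_clusters
autoplot.epm_clusters <- function(object, ...) {
  if (is.null(object$coords)) abort("solution carries no embedding to plot")
  df <- tibble(x = object$coords[, 1], y = object$coords[, 2],
               cluster = factor(object$labels))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$cluster)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = "face-space dim 1", y = "face-space dim 2",
                  title = sprintf("%d-cluster solution", object$k)) +
    ggplot2::theme_minimal()
}
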