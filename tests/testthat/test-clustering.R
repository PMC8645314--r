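test_that("classical scaling reproduces Euclidean configurations", {
  D2 <- matrix(c(0, 5, 5, 0), 2)
  co <- mds_embed(D2, dim = 1)
  expect_equal(abs(co[1, 1] - co[2, 1]), 5)

  pts <- withr::with_seed(1, matrix(rnorm(24), 12, 2))
  D <- as.matrix(dist(pts))
  co2 <- mds_embed(D, dim = 2)
  expect_equal(as.matrix(dist(co2)), D, tolerance = 1e-8,
               ignore_attr = TRUE)

  Dasym <- D; Dasym[1, 2] <- Dasym[1, 2] + 1
  expect_error(mds_embed(Dasym, 2), "symmetric")
})

test_that("embedding stress equals the discarded spectral mass", {
  # regular 3-simplex: three equal positive eigenvalues, one is dropped
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  D <- as.matrix(dist(pts))
  co <- mds_embed(D, dim = 2)
  eig <- attr(co, "eig")
  pos <- eig[eig > 1e-9]
  expect_equal(attr(co, "stress"), sum(pos[-(1:2)]))
  expect_gt(attr(co, "stress"), 0)
})

test_that("Ward clustering recovers separated pairs and the SS identities", {
  m <- rbind(c(0, 0), c(0.5, 0), c(20, 0), c(20.5, 0))
  D <- as.matrix(dist(m))
  sol <- ward_cluster(D, 2)
  expect_equal(sol$labels[1], sol$labels[2], ignore_attr = TRUE)
  expect_equal(sol$labels[3], sol$labels[4], ignore_attr = TRUE)
  expect_false(sol$labels[1] == sol$labels[3])
  # exhaustive-partition oracle: no 2-partition has lower within-SS
  best <- min(vapply(1:7, function(code) {
    g <- as.integer(intToBits(code))[1:4]
    if (length(unique(g)) != 2) return(Inf)
    epmfaces:::.within_ss_D(D, g)
  }, 0))
  expect_equal(sol$within_ss, best)

  expect_equal(ward_cluster(D, 4)$within_ss, 0)
  total_ss <- sum(sweep(m, 2, colMeans(m))^2)
  expect_equal(ward_cluster(D, 1)$within_ss, total_ss)
  expect_error(ward_cluster(D, 0), "k must be")
})

test_that("the elbow criterion finds a distinct drop", {
  tri <- make_blobs(rbind(c(0, 0), c(16, 0), c(8, 14)), seed = 5)
  prof <- elbow_profile(tri, 8, seed = 1)
  expect_equal(attr(prof, "suggested_k"), 3L)
  expect_true(attr(prof, "distinct_elbow"))
  expect_false(is.unsorted(rev(prof$within_ss)))
  expect_error(elbow_profile(tri, 2), "k_max")
})

test_that("a smooth monotone profile falls back to the relative-drop rule", {
  line <- cbind(seq(0, 30, length.out = 24), 0)
  prof <- elbow_profile(line, 8, seed = 1)
  expect_false(attr(prof, "distinct_elbow"))
  W <- prof$within_ss
  expect_equal(attr(prof, "suggested_k"),
               as.integer(min(which(W < 0.1 * W[1]))))
})

test_that("the gap statistic recovers blob counts", {
  one <- withr::with_seed(7, matrix(rnorm(60), 30, 2))
  g1 <- gap_statistic(one, 8, B = 50, seed = 1)
  expect_equal(attr(g1, "chosen_k"), 1L)
  # chosen k satisfies its defining rule
  kc <- attr(g1, "chosen_k")
  if (kc < 8) expect_gte(g1$gap[kc], g1$gap[kc + 1] - g1$se[kc + 1])

  four <- make_blobs(square_centers, seed = 11)
  g4 <- gap_statistic(four, 8, B = 50, seed = 2)
  expect_equal(attr(g4, "chosen_k"), 4L)

  expect_error(gap_statistic(matrix(1, 10, 2), 3, B = 50), "degenerate")
  expect_error(gap_statistic(four, 8, B = 5), "B must be")
})

test_that("gap curve shape and chosen k are invariant under rigid rotation", {
  # the bounding-box reference volume changes under rotation, shifting the
  # gap curve by a constant; its shape and the chosen k are isometry
  # invariants
  four <- make_blobs(square_centers, seed = 3)
  th <- 0.7
  rot <- four %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  g <- gap_statistic(four, 6, B = 50, seed = 4)
  gr <- gap_statistic(rot, 6, B = 50, seed = 4)
  expect_equal(gr$gap - mean(gr$gap), g$gap - mean(g$gap), tolerance = 0.1)
  expect_equal(attr(gr, "chosen_k"), attr(g, "chosen_k"))
  # the data dispersion term is exactly isometric
  expect_equal(gr$log_W, g$log_W, tolerance = 1e-6)
})

test_that("gap dispersion agrees with an independent implementation", {
  skip_if_not_installed("cluster")
  four <- make_blobs(square_centers, n_per = 10, seed = 9)
  g <- gap_statistic(four, 5, B = 50, seed = 1)
  cg <- withr::with_seed(1, cluster::clusGap(
    four, FUN = stats::kmeans, nstart = 10, K.max = 5, B = 50,
    verbose = FALSE, d.power = 2, spaceH0 = "original"))
  # data log-dispersion matches up to clusGap's factor-2 convention
  # (loose digits absorb k-means local-minimum differences above k*)
  expect_equal(g$log_W, unname(cg$Tab[, "logW"]) + log(2), tolerance = 0.02)
  # gap is convention-free; reference terms are Monte-Carlo, so agree
  # within a few simulation errors
  expect_equal(g$gap, unname(cg$Tab[, "gap"]), tolerance = 0.2)
})

test_that("two-step clustering segments lifespan trajectories exactly", {
  for (s in c(1, 9, 13)) {
    tr <- std_trajectory(seed = s)
    sol <- two_step(dissimilarity_matrix(tr), seed = s)
    expect_equal(sol$k, 4)
    lab <- sol$labels[tr$exemplar_id]
    expect_equal(mclust::adjustedRandIndex(lab, tr$segment), 1)
    ord <- order(tr$capture_age)
    expect_false(is.unsorted(match(lab[ord], unique(lab[ord]))))
  }
})

test_that("two-step is deterministic and never undoes the Ward refinement", {
  tr <- std_trajectory(seed = 4)
  D <- dissimilarity_matrix(tr)
  a <- two_step(D, seed = 2)
  b <- two_step(D, seed = 2)
  expect_identical(a$labels, b$labels)
  expect_lte(a$within_ss, a$ward_within_ss + 1e-9)
})

test_that("degenerate and identical-exemplar inputs collapse to one cluster", {
  D <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  sol <- two_step(D, seed = 1)
  expect_equal(sol$k, 1)
  expect_equal(sol$within_ss, 0)
})

test_that("two-step matches assimilation-produced memberships", {
  # cross-module consistency: the analysis pipeline recovers the same
  # episodes the online memory forms when the threshold matches the jumps
  for (s in c(21, 22)) {
    tr <- std_trajectory(seed = s)
    sol <- two_step(dissimilarity_matrix(tr), seed = s)
    st <- assimilate_stream(memory_store(calibrate_threshold(tr)), tr)
    lab_mem <- tidy(st)
    m <- match(tr$exemplar_id, lab_mem$exemplar_id)
    ari <- mclust::adjustedRandIndex(sol$labels[tr$exemplar_id],
                                     lab_mem$prototype[m])
    expect_gte(ari, 0.9)
  }
})

test_that("only isolated singleton clusters are flagged as outliers", {
  base <- make_blobs(rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10)),
                     n_per = 6, sd = 0.3, seed = 2)
  pts <- rbind(base, c(60, 60))
  rownames(pts) <- sprintf("p%02d", seq_len(nrow(pts)))
  D <- as.matrix(dist(pts))
  sol <- two_step(D, k_max = 6, seed = 1)
  out <- flag_outliers(sol, pts)
  if (min(table(sol$labels)) == 1) expect_equal(out, "p25")

  # no singleton clusters: nothing flagged
  sol4 <- ward_cluster(as.matrix(dist(base)), 4)
  expect_length(flag_outliers(sol4, base), 0)

  # duplicated points have zero nearest-neighbour distance: never flagged
  dup <- rbind(base, base[1, , drop = FALSE])
  rownames(dup) <- sprintf("q%02d", seq_len(nrow(dup)))
  sol_dup <- ward_cluster(as.matrix(dist(dup)), 5)
  expect_false(any(c("q01", "q25") %in% flag_outliers(sol_dup, dup)))
})
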