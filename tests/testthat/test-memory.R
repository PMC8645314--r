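test_that("trace similarity is the cosine with its edge cases", {
  expect_equal(trace_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(trace_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(trace_similarity(c(1, 0), c(1, 1)), 1 / sqrt(2))
  expect_equal(trace_similarity(c(1, 0), c(0, 0)), 0)
  expect_error(trace_similarity(c(0, 0), c(1, 0)), "nonzero")
  expect_error(trace_similarity(c(1, 0), c(1, 0, 0)), "dimension")
})

test_that("echo intensity is the recency-weighted sum of cubed similarities", {
  st <- memory_store(10)
  st <- assimilate(st, c(1, 0), time = 0)
  e <- echo(c(1, 0), st)
  expect_equal(e$intensity, 1)
  expect_equal(echo(c(0, 1), st)$intensity, 0)

  # traces at cosine 1 and 0.5 from the probe: I = 1 + 0.5^3
  st2 <- memory_store(10)
  st2 <- assimilate(st2, c(1, 0), time = 0)
  st2 <- assimilate(st2, c(0.5, sqrt(3) / 2), time = 0)
  e2 <- echo(c(1, 0), st2)
  expect_equal(e2$intensity, 1.125)
  # EchoResult identities hold exactly
  expect_equal(e2$intensity,
               sum(e2$per_trace$weight * e2$per_trace$activation))
  f <- rbind(c(1, 0), c(0.5, sqrt(3) / 2))
  expect_equal(e2$content,
               colSums(f * e2$per_trace$weight * e2$per_trace$activation),
               ignore_attr = TRUE)
  expect_error(echo(c(1, 0), memory_store(1)), "empty")
})

test_that("maximum delta spans centroid and members", {
  st <- memory_store(10)
  st <- assimilate(st, c(2, 2), time = 0)
  expect_equal(max_delta(c(2, 2), st$prototypes[[1]]), 0)

  p <- list(centroid = c(0.5, 0), f = rbind(c(0, 0), c(1, 0)))
  expect_equal(max_delta(c(5, 0), p), 5)
  expect_error(max_delta(c(1, 2, 3), p), "dimension")
})

test_that("assimilation splits a stream at the threshold delta", {
  st <- memory_store(threshold_delta = 1)
  st <- assimilate(st, c(0, 0), time = 1, exemplar_id = "a")
  expect_equal(length(st$prototypes), 1)
  expect_equal(nrow(st$prototypes[[1]]$f), 1)

  st <- assimilate(st, c(0.1, 0), time = 2, exemplar_id = "b")
  st <- assimilate(st, c(5, 0), time = 3, exemplar_id = "c")
  expect_equal(length(st$prototypes), 2)
  expect_equal(st$prototypes[[1]]$exemplar_id, c("a", "b"))
  expect_equal(st$prototypes[[2]]$exemplar_id, "c")
  expect_equal(st$prototypes[[1]]$centroid, c(0.05, 0))

  expect_error(assimilate(st, c(0, 0), time = 0), "chronological")
})

test_that("centroids remain the mean of members and counts never shrink", {
  tr <- std_trajectory(seed = 6)
  st <- memory_store(calibrate_threshold(tr))
  counts <- integer(0)
  fm <- feature_matrix(tr)
  for (i in seq_len(nrow(fm))) {
    st <- assimilate(st, fm[i, ], time = tr$capture_age[i],
                     exemplar_id = tr$exemplar_id[i])
    counts <- c(counts, length(st$prototypes))
  }
  expect_false(is.unsorted(counts))
  for (p in st$prototypes) {
    expect_equal(p$centroid, colMeans(p$f), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  # every trace belongs to exactly one prototype
  ids <- unlist(lapply(st$prototypes, `[[`, "exemplar_id"))
  expect_setequal(ids, tr$exemplar_id)
  expect_equal(length(ids), 20)
})

test_that("threshold bracketing degenerates to the two classical models", {
  for (s in 1:10) {
    tr <- std_trajectory(seed = 100 + s)
    fm <- feature_matrix(tr)
    diam <- max(dist(fm))
    one <- assimilate_stream(memory_store(diam + 1e-6), tr)
    expect_equal(length(one$prototypes), 1)
    each <- assimilate_stream(memory_store(0), tr)
    expect_equal(length(each$prototypes), nrow(tr))
  }
})

test_that("injected jumps are recovered as prototype boundaries", {
  ok <- vapply(1:20, function(s) {
    tr <- std_trajectory(seed = 200 + s)
    st <- assimilate_stream(memory_store(calibrate_threshold(tr)), tr)
    lab <- tidy(st)
    m <- match(tr$exemplar_id, lab$exemplar_id)
    length(st$prototypes) == 4 &&
      mclust::adjustedRandIndex(lab$prototype[m], tr$segment) == 1
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})

test_that("a single novel exemplar spawns a prototype in one step", {
  st <- memory_store(threshold_delta = 2)
  st <- assimilate(st, c(0, 0), time = 1)
  st <- assimilate(st, c(0.5, 0), time = 2)
  n_before <- length(st$prototypes)
  st <- assimilate(st, c(40, 0), time = 3)
  expect_equal(length(st$prototypes), n_before + 1)
  expect_equal(nrow(st$prototypes[[n_before + 1]]$f), 1)
})

test_that("prototypicality applies the exponential recency weights", {
  st <- memory_store(10, recency_half_life = 5)
  st <- assimilate(st, c(1, 0), time = 0)
  st <- assimilate(st, c(1, 0), time = 5)
  # weights at now = 5: 0.5 (old) + 1 (new)
  expect_equal(prototypicality(c(1, 0), st), 1.5)

  st_inf <- memory_store(10, recency_half_life = Inf)
  st_inf <- assimilate(st_inf, c(1, 0), time = 0)
  st_inf <- assimilate(st_inf, c(1, 0), time = 5)
  expect_equal(prototypicality(c(1, 0), st_inf), 2)
})

test_that("recency weighting favours the most recent episode", {
  for (s in 1:5) {
    tr <- std_trajectory(seed = 300 + s)
    st <- assimilate_stream(memory_store(calibrate_threshold(tr), 15),
                            center_to_norm(tr))
    pt <- dplyr::arrange(prototype_table(st), age_min)
    p <- vapply(pt$centroid, function(cn) prototypicality(cn, st), 0)
    expect_gt(p[length(p)], p[1])
  }
})

test_that("verification links strength to latency on a log scale", {
  st <- memory_store(10)
  st <- assimilate(st, c(1, 0), time = 0)
  v <- verify(st, c(1, 0), decision_threshold = 0.5)
  expect_true(v$match)
  expect_equal(v$strength, 1)
  expect_equal(v$latency_ms, 800)   # base - slope * log(1)

  st3 <- memory_store(10)
  for (t in 1:3) st3 <- assimilate(st3, c(1, 0), time = t)
  v3 <- verify(st3, c(1, 0), decision_threshold = 0.5)
  expect_equal(v3$strength, 3)
  expect_equal(v3$latency_ms, 800 - 100 * log(3))

  # orthogonal probe: strength ~ 0, latency at the floor-capped maximum
  vo <- verify(st, c(0, 1), decision_threshold = 0.5)
  expect_false(vo$match)
  expect_equal(vo$strength, 0)
  expect_equal(vo$latency_ms, 800 - 100 * log(1e-6))
  expect_error(verify(st, c(1, 0), 0.5, rt_slope_ms = 0), "positive")
})

test_that("simulated latencies never undercut the 200 ms validity floor", {
  st <- memory_store(10)
  for (t in 1:50) st <- assimilate(st, c(1, 0), time = t)
  v <- verify(st, c(1, 0), 0.5, rt_base_ms = 300, rt_slope_ms = 100)
  expect_equal(v$latency_ms, 200)
})

test_that("memory stores round-trip through JSON losslessly", {
  tr <- std_trajectory(seed = 7)
  st <- assimilate_stream(memory_store(calibrate_threshold(tr), 15), tr)
  f <- withr::local_tempfile(fileext = ".json")
  write_store(st, f)
  back <- read_store(f)
  expect_equal(back, st, tolerance = 1e-12)

  st_inf <- assimilate_stream(memory_store(5, Inf), tr)
  write_store(st_inf, f)
  expect_equal(read_store(f)$recency_half_life, Inf)
})

test_that("tidy and glance summarise the store", {
  tr <- std_trajectory(seed = 8)
  st <- assimilate_stream(memory_store(calibrate_threshold(tr)), tr)
  td <- tidy(st)
  expect_equal(nrow(td), 20)
  expect_named(td, c("prototype", "exemplar_id", "encoding_time",
                     "capture_age", "created_at"))
  gl <- glance(st)
  expect_equal(gl$n_traces, 20)
  expect_equal(gl$n_prototypes, length(st$prototypes))
})
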