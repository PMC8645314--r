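# Shared fixtures, all generated in code.

std_jumps <- data.frame(age = c(15, 30, 45), magnitude = 12)

std_trajectory <- function(seed = 1, ...) {
  generate_trajectory("id1", jumps = std_jumps, seed = seed, ...)
}

# Gaussian blobs around the given 2-D centers.
make_blobs <- function(centers, n_per = 15, sd = 0.5, seed = 1) {
  withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
      cbind(stats::rnorm(n_per, centers[i, 1], sd),
            stats::rnorm(n_per, centers[i, 2], sd))
    }))
  })
}

square_centers <- matrix(c(0, 0, 16, 0, 0, 16, 16, 16), 4, 2, byrow = TRUE)

# Tiny exemplar table from an explicit feature matrix.
exemplar_table <- function(m, ages = seq_len(nrow(m))) {
  colnames(m) <- paste0("f", seq_len(ncol(m)) - 1)
  dplyr::bind_cols(
    tibble::tibble(exemplar_id = sprintf("e%02d", seq_len(nrow(m))),
                   identity_id = "id1", capture_age = ages),
    tibble::as_tibble(m)
  )
}
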