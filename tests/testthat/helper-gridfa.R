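# Shared fixtures and independent oracles.

# Literal two-loop weighted kappa, kept deliberately naive and independent
# of the package implementation.
oracle_kappa <- function(tab, weights = "linear") {
  K <- nrow(tab)
  n <- sum(tab)
  num <- 0; den <- 0
  pr <- rowSums(tab) / n
  pc <- colSums(tab) / n
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      w <- switch(weights,
        none = as.numeric(i != j),
        linear = abs(i - j) / (K - 1),
        quadratic = (abs(i - j) / (K - 1))^2)
      num <- num + w * tab[i, j] / n
      den <- den + w * pr[i] * pc[j]
    }
  }
  1 - num / den
}

# Concordant/discordant pair counting for tau-b (O(n^2), one explicit loop).
oracle_tau_b <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1)) {
    dx <- x[(i + 1):n] - x[i]
    dy <- y[(i + 1):n] - y[i]
    C <- C + sum(dx * dy > 0)
    D <- D + sum(dx * dy < 0)
    tx <- tx + sum(dx == 0)
    ty <- ty + sum(dy == 0)
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# A full-grid session with a fixed grade everywhere (optionally overridden
# per cell by a named vector flat_id -> grade).
uniform_session <- function(grade = "P100", image_id = "img1",
                            grader_id = "g1", grid = grid_spec(),
                            overrides = NULL) {
  cells <- grid_cells(grid)
  grades <- rep(grade, nrow(cells))
  if (!is.null(overrides)) grades[match(as.integer(names(overrides)), cells$id)] <- overrides
  grading_session(image_id, grader_id,
                  data.frame(ring = cells$ring, sector = cells$sector,
                             grade = grades),
                  grid = grid)
}

# Random ground-truth perfusion over the grid: a fraction of cells fully
# perfused, the rest uniform in (0, 1).
random_truth <- function(grid = grid_spec(), p_perfused = 0.6, seed = 1) {
  cells <- grid_cells(grid)
  withr::with_seed(seed, {
    n <- nrow(cells)
    frac <- ifelse(stats::runif(n) < p_perfused, 1, stats::runif(n))
    data.frame(ring = cells$ring, sector = cells$sector, fraction = frac)
  })
}

# A paired multi-image dataset from two simulated graders.
simulated_pairs <- function(n_images = 6, noise_sd = 0.1, seed = 1,
                            grid = grid_spec()) {
  do.call(rbind, lapply(seq_len(n_images), function(i) {
    truth <- random_truth(grid, seed = seed * 1000 + i)
    a <- simulate_grader(truth, grader_model(noise_sd = noise_sd,
                                             seed = seed * 1000 + 2 * i),
                         image_id = sprintf("img%02d", i), grader_id = "g1",
                         grid = grid)
    b <- simulate_grader(truth, grader_model(noise_sd = noise_sd,
                                             seed = seed * 1000 + 2 * i + 1),
                         image_id = sprintf("img%02d", i), grader_id = "g2",
                         grid = grid)
    pair_sessions(a, b)$pairs
  }))
}
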