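# shared builders for the test suite

tiny_scale <- function(n_items = 3, option_max = 7) {
  items <- paste0("I", seq_len(n_items))
  scale_definition(items, setNames(list(items), "S"), 1, option_max,
                   name = "tiny")
}

# ratings_matrix from a plain matrix of option codes
ratings_from_matrix <- function(m, scale) {
  df <- as.data.frame(m)
  names(df) <- scale$items[seq_len(ncol(m))]
  as_ratings(df, scale)
}

# brute-force Nadaraya-Watson OCC oracle: explicit loops, no shared code path
occ_brute <- function(values, theta, grid, h, opts = 1:7) {
  P <- matrix(0, length(grid), length(opts))
  for (q in seq_along(grid)) {
    w <- numeric(length(theta))
    for (i in seq_along(theta))
      w[i] <- exp(-((grid[q] - theta[i]) / h)^2 / 2) / sqrt(2 * pi)
    for (m in seq_along(opts)) {
      num <- 0
      for (i in seq_along(theta))
        if (values[i] == opts[m]) num <- num + w[i]
      P[q, m] <- num / sum(w)
    }
  }
  colnames(P) <- as.character(opts)
  P
}

# true OCC matrix of a grm_item on a grid, with option-code column names
true_occ <- function(item, grid, option_min = 1L) {
  P <- grm_option_probs(grid, item)
  colnames(P) <- as.character(seq(option_min, length.out = ncol(P)))
  P
}

# cohort of identical archetype items on the PANSS layout, normal severity
archetype_cohort <- function(n, seed, weak = character(0),
                             kind = "ideal") {
  sc <- panss_scale()
  items <- setNames(rep(list(make_archetype(kind)), 30), sc$items)
  for (id in names(weak)) items[[id]] <- make_archetype(weak[[id]])
  simulate_cohort(cohort_config(
    sc, items, n, severity = list(dist = "normal", mean = 0, sd = 1),
    seed = seed))
}

# fixture ratings columns as a 5-column character matrix
fixture_rating_matrix <- function(fx) {
  as.matrix(fx[c("c1", "c2", "c3", "c4", "c5")])
}
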