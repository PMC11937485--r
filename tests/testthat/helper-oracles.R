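# Independent oracles, written against the definitions rather than the
# package implementation, plus memoised fixtures shared across test files.

# brute-force single-level Haar analysis: loop over disjoint 2x2 blocks
oracle_haar2 <- function(x) {
  h2 <- nrow(x) %/% 2L
  w2 <- ncol(x) %/% 2L
  ca <- ch <- cv <- cd <- matrix(0, h2, w2)
  for (i in seq_len(h2)) {
    for (j in seq_len(w2)) {
      a <- x[2 * i - 1, 2 * j - 1]
      b <- x[2 * i - 1, 2 * j]
      c_ <- x[2 * i, 2 * j - 1]
      d <- x[2 * i, 2 * j]
      ca[i, j] <- (a + b + c_ + d) / 2
      ch[i, j] <- (a + b - c_ - d) / 2
      cv[i, j] <- (a - b + c_ - d) / 2
      cd[i, j] <- (a - b - c_ + d) / 2
    }
  }
  list(CA = ca, CH = ch, CV = cv, CD = cd)
}

# brute-force gradient-magnitude energy: explicit stencil double loop
# (central differences inside, one-sided at the borders)
oracle_energy <- function(x) {
  h <- nrow(x)
  w <- ncol(x)
  total <- 0
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      gy <- if (i == 1) x[2, j] - x[1, j] else
        if (i == h) x[h, j] - x[h - 1, j] else (x[i + 1, j] - x[i - 1, j]) / 2
      gx <- if (j == 1) x[i, 2] - x[i, 1] else
        if (j == w) x[i, w] - x[i, w - 1] else (x[i, j + 1] - x[i, j - 1]) / 2
      total <- total + sqrt(gx^2 + gy^2)
    }
  }
  total
}

# brute-force majority vote
oracle_majority <- function(votes) {
  as.integer(sum(votes == 1) > length(votes) / 2)
}

# memoised test fixtures (built once per test run)
.fixtures <- new.env(parent = emptyenv())

# route features of a small phantom cohort at the scaled test profile
fixture_features <- function(effect, n_per_class = 10, seed = 301,
                             n_slices = 16, slice_size = 64) {
  key <- paste("feat", effect, n_per_class, seed, n_slices, slice_size,
               sep = "_")
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  dir <- file.path(tempdir(), paste0("mvmdm_", key))
  cfg <- phantom_config(n_slices = n_slices, slice_size = slice_size,
                        effect = effect)
  man <- generate_cohort(n_per_class, cfg, dir = dir, seed = seed,
                         write_manifest = FALSE)
  f <- cohort_route_features(man, n_keep = n_slices)
  .fixtures[[key]] <- list(manifest = man, features = f, cfg = cfg)
  .fixtures[[key]]
}

# one small decomposed phantom subject
fixture_subject <- function(label = 0, effect = 0.5, seed = 11) {
  key <- paste("subj", label, effect, seed, sep = "_")
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  cfg <- phantom_config(n_slices = 8, slice_size = 32, effect = effect)
  sv <- normalize_volume(generate_subject(label, cfg, seed))
  .fixtures[[key]] <- list(volume = sv, subbands = decompose_volume(sv))
  .fixtures[[key]]
}
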