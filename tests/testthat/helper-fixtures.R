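# Shared fixtures: everything is generated in code at test time.

# Small spatial parcellation with mirror pairs.
tiny_parcellation <- function(n_pairs = 5, n_medial = 0, seed = 11) {
  make_parcellation(n_pairs = n_pairs, n_medial = n_medial, extent = 140,
                    seed = seed)
}

# Connectivity dataset sampled from the generator under the stated
# study conditions; small defaults keep unit tests fast.
quick_dataset <- function(n_pairs = 10, n_conditions = 2, n_subjects = 8,
                          n_timepoints = 60, n_groups = 1,
                          effect_profile = "flat", effect_size = 0.1,
                          homotopic_stability = 0, seed = 21) {
  p <- make_parcellation(n_pairs, seed = seed)
  truth <- make_ground_truth(p, n_conditions = n_conditions,
                             effect_profile = effect_profile,
                             effect_size = effect_size,
                             homotopic_stability = homotopic_stability,
                             seed = seed + 1)
  dat <- sample_dataset(p, truth, n_subjects_per_group = n_subjects,
                        n_timepoints = n_timepoints, n_groups = n_groups,
                        seed = seed + 2)
  list(parcellation = p, truth = truth, raw = dat,
       ds = connectivity_dataset(dat))
}

# Hand-rolled Newman modularity for weighted undirected graphs: the
# independent oracle for Louvain Q.
modularity_oracle <- function(w, membership) {
  diag(w) <- 0
  m2 <- sum(w)                 # 2m
  k <- rowSums(w)
  q <- 0
  for (i in seq_len(nrow(w))) {
    for (j in seq_len(ncol(w))) {
      if (membership[i] == membership[j]) {
        q <- q + w[i, j] - k[i] * k[j] / m2
      }
    }
  }
  q / m2
}

# Second, independent Pearson correlation implementation.
pearson_oracle <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# Spearman through explicit ranks + the Pearson oracle.
spearman_oracle <- function(x, y) {
  pearson_oracle(rank(x), rank(y))
}
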