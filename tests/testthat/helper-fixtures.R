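# fixtures built in code; nothing is stored on disk

# the 3-sample worked example: samples 1,2 carry only class c1 (motif {A}),
# sample 3 carries both classes (motif {A,B}); y = (2, 4, 10)
worked_example <- function() {
  ind <- matrix(c(1, 1, 1,
                  0, 0, 1), ncol = 2,
                dimnames = list(c("s1", "s2", "s3"), c("c1", "c2")))
  list(encoding = class_encoding(ind),
       partition = functional_partition(c(c1 = "A", c2 = "B"), c("A", "B")),
       y = c(2, 4, 10))
}

# random binary encoding with per-class presence probabilities
random_encoding <- function(n, m, seed, p_range = c(0.25, 0.75)) {
  set.seed(seed)
  p <- runif(m, p_range[1], p_range[2])
  ind <- matrix(rbinom(n * m, 1, rep(p, each = n)), n, m)
  colnames(ind) <- paste0("c", seq_len(m))
  class_encoding(ind)
}

# random small count table guaranteed to have every family observed
random_table <- function(n, p, seed, reads = 200) {
  simulate_abundance_table(n_samples = n, n_families = p,
                           freq_range = c(0.3, 1),
                           reads_per_sample = reads, seed = seed)
}
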