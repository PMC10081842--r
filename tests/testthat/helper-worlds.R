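# shared fixtures built in code

tiny_truth <- function(seed = 1, n = 16, clen = 4) {
  gen_true_surface(world_spec(n, n, correlation_length = clen, seed = seed))
}

# Moran's I with binary weights for pairs whose center distance falls in
# [lag - 0.5, lag + 0.5) cells; direct definition, used as an oracle
morans_i <- function(values, lag) {
  n_r <- nrow(values); n_c <- ncol(values)
  coords <- cbind(rep(seq_len(n_r), times = n_c),
                  rep(seq_len(n_c), each = n_r))
  z <- as.vector(values) - mean(values)
  d <- as.matrix(dist(coords))
  W <- (d >= lag - 0.5) & (d < lag + 0.5)
  diag(W) <- FALSE
  n <- length(z)
  (n / sum(W)) * sum(W * outer(z, z)) / sum(z^2)
}
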