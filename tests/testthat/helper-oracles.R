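# Independent brute-force oracles, written literally from the defining
# formulas; deliberately slow and kept separate from the package's
# cumulative-sum implementations.

# Tail MSE profile over candidate split points l = 1..floor(lambda*M),
# computed with an explicit double loop.
brute_mse_profile <- function(max_ranks, lambda = 0.9) {
  M <- length(max_ranks)
  l_max <- floor(lambda * M)
  vapply(seq_len(l_max), function(l) {
    p <- l / M
    sq <- vapply(l:M, function(x) {
      shat <- mean(max_ranks / M >= x / M)
      xi <- x / M
      sideal <- if (xi < p) 1
      else if (xi <= 1) 1 - (xi - p)^2 / (1 - p)^2
      else 0
      (shat - (1 - p) * sideal)^2
    }, numeric(1))
    sum(sq) / (M - l)
  }, numeric(1))
}

# Marginal FDR curve by direct counting.
brute_mfdr <- function(max_ranks, k_hat) {
  M <- length(max_ranks)
  vapply(seq.int(k_hat + 1, M), function(l) {
    q <- sum(max_ranks <= l)
    ev <- (l - k_hat)^2 / (M - k_hat)
    if (q == 0) 0 else ev / q
  }, numeric(1))
}

# Small fully crossed nested-design table built in code.
toy_table <- function(n_features = 20, layers = c(op = 2, rep = 3),
                      seed = 1) {
  set.seed(seed)
  combos <- expand.grid(lapply(rev(layers), seq_len))[, rev(seq_along(layers)),
                                                      drop = FALSE]
  names(combos) <- names(layers)
  for (nm in names(layers)) combos[[nm]] <- paste0(nm, combos[[nm]])
  ids <- apply(combos, 1, paste, collapse = "_")
  v <- matrix(rexp(n_features * length(ids)) + 1, n_features,
              dimnames = list(sprintf("f%02d", seq_len(n_features)), ids))
  abundance_table(v, cbind(data.frame(sample_id = ids), combos))
}
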