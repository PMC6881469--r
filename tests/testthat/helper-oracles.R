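# Shared fixtures and independent oracles used across the suite.

# The 36 anchored records as a training frame (channels + labels).
anchor_training_frame <- function() {
  t1 <- load_table1()
  t1[, c("e_coli", "m_capsulatus", "s_oneidensis", "pollutant", "level_uM")]
}

# Per-class mean response matrix over all 60 codebook classes (rows follow
# codebook() order), built from the response surface.
class_mean_matrix <- function() {
  cb <- codebook()
  t(vapply(seq_len(nrow(cb)), function(i)
    vapply(channel_names(), function(ch)
      response_surface(ch, cb$pollutant[i], cb$level_uM[i]), numeric(1)),
    numeric(3)))
}

# Maximum-likelihood oracle under the generator's multiplicative Gaussian
# noise model: per-sample log-likelihood of each of the 60 classes.
class_loglik <- function(X, noise_cv = 0.10) {
  M <- class_mean_matrix()
  S <- noise_cv * abs(M)
  vapply(seq_len(nrow(M)), function(cl) {
    z <- sweep(sweep(X, 2, M[cl, ], "-"), 2, S[cl, ], "/")
    rowSums(stats::dnorm(z, log = TRUE)) - sum(log(S[cl, ]))
  }, numeric(nrow(X)))
}

# Bayes-optimal continuous codeword output (posterior-weighted bits): the
# function an MSE-trained network approximates.
bayes_codeword_output <- function(X, noise_cv = 0.10) {
  ll <- class_loglik(X, noise_cv)
  post <- exp(ll - apply(ll, 1, max))
  post <- post / rowSums(post)
  B <- t(vapply(strsplit(codebook()$codeword, ""), as.integer, integer(6)))
  pmin(pmax(post %*% B, 1e-12), 1 - 1e-12)
}

# Central finite-difference Jacobian of the network outputs w.r.t. weights.
fd_jacobian <- function(w, X, cfg, h = 1e-6) {
  J <- matrix(0, nrow(X) * cfg$n_output, length(w))
  for (i in seq_along(w)) {
    wp <- w; wp[i] <- w[i] + h
    wm <- w; wm[i] <- w[i] - h
    Op <- ann_forward(wp, X, cfg)$output
    Om <- ann_forward(wm, X, cfg)$output
    J[, i] <- (as.vector(Op) - as.vector(Om)) / (2 * h)
  }
  J
}
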