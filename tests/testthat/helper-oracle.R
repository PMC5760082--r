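# Exact stationary-distribution oracle for the risk-gene sampling chain.
#
# Enumerates every size-n state of the chain, computes each state's
# integrated-score weight vector with the package's scoring functions,
# derives the exact transition probabilities of sequential weighted
# sampling without replacement by summing over draw orderings, and solves
# for the stationary distribution. Independent of the MCMC path: no
# sampling is involved.

# Probability that sequential weighted sampling without replacement with
# weights w draws exactly the (unordered) set `idx`.
oracle_set_probability <- function(w, idx) {
  total <- sum(w)
  perms <- all_permutations(idx)
  sum(vapply(perms, function(ord) {
    remaining <- total
    p <- 1
    for (g in ord) {
      p <- p * w[g] / remaining
      remaining <- remaining - w[g]
    }
    p
  }, numeric(1)))
}

all_permutations <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

# Weight vector of one state, mirroring the spec of one sampler iteration.
oracle_state_weights <- function(risk_idx, assoc, net_model = NULL,
                                 phe_model = NULL, a = 0.1, b = 1,
                                 net_mode = "transition") {
  m <- length(assoc)
  v <- numeric(m)
  v[risk_idx] <- 1
  s_net <- if (!is.null(net_model)) {
    normalize_fn(network_raw_scores(net_model, v, net_mode), risk_idx)
  } else rep(1, m)
  s_phe <- if (!is.null(phe_model)) {
    normalize_fn(phenotype_raw_scores(phe_model, v), risk_idx)
  } else rep(1, m)
  ind <- ifelse(v == 1, 1, a)
  assoc * (ind + b * s_net * s_phe)
}

# Exact per-gene stationary marginals of the chain.
oracle_stationary_marginals <- function(assoc, net_model = NULL,
                                        phe_model = NULL, n = 2L,
                                        a = 0.1, b = 1,
                                        net_mode = "transition") {
  m <- length(assoc)
  states <- utils::combn(m, n)
  n_states <- ncol(states)
  trans <- matrix(0, n_states, n_states)
  for (i in seq_len(n_states)) {
    w <- oracle_state_weights(states[, i], assoc, net_model, phe_model,
                              a = a, b = b, net_mode = net_mode)
    for (j in seq_len(n_states)) {
      trans[i, j] <- oracle_set_probability(w, states[, j])
    }
  }
  stopifnot(max(abs(rowSums(trans) - 1)) < 1e-8)
  # stationary vector: left eigenvector of the transition matrix
  eig <- eigen(base::t(trans))
  k <- which.min(abs(eig$values - 1))
  pi_vec <- Re(eig$vectors[, k])
  pi_vec <- pi_vec / sum(pi_vec)
  stopifnot(all(pi_vec > -1e-10))
  marg <- numeric(m)
  for (i in seq_len(n_states)) {
    marg[states[, i]] <- marg[states[, i]] + pi_vec[i]
  }
  marg
}
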