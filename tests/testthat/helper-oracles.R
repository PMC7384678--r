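# Independent, loop-based oracles used to verify the linear-algebra
# implementations.  These deliberately avoid matrix shortcuts: everything is
# an explicit sum over entries.

oracle_objective <- function(problem, f, params) {
  x1 <- as.matrix(problem$x1$values)
  x2 <- as.matrix(problem$x2$values)
  s <- as.matrix(problem$anchors$matrix)
  total <- 0
  for (d in 1:2) {
    x <- if (d == 1) x1 else x2
    u <- f[[paste0("u", d)]]
    v <- f[[paste0("v", d)]]
    for (i in seq_len(nrow(x))) {
      for (j in seq_len(ncol(x))) {
        pred <- 0
        for (k in seq_len(ncol(u))) pred <- pred + u[i, k] * v[j, k]
        wij <- if (x[i, j] > 0) 1 else params$w
        total <- total + (wij * (x[i, j] - pred))^2
      }
    }
  }
  # cross-network consistency by explicit loops
  su1 <- matrix(0, nrow(s), ncol(f$u1))
  for (i in seq_len(nrow(s))) {
    for (j in seq_len(ncol(s))) {
      if (s[i, j] != 0) su1[i, ] <- su1[i, ] + s[i, j] * f$u1[j, ]
    }
  }
  cross <- 0
  for (i in seq_len(nrow(s))) {
    for (j in seq_len(nrow(s))) {
      g1 <- sum(su1[i, ] * su1[j, ])
      g2 <- sum(f$u2[i, ] * f$u2[j, ])
      cross <- cross + (g1 - g2)^2
    }
  }
  total <- total + params$beta * cross
  # smoothness traces: sum_ij A_ij * ||row_i - row_j||^2 / ... use L directly
  trace_term <- function(m, lap) {
    acc <- 0
    lm <- lap$laplacian
    for (a in seq_len(ncol(m))) {
      for (i in seq_len(nrow(m))) {
        for (j in seq_len(nrow(m))) {
          acc <- acc + m[i, a] * lm[i, j] * m[j, a]
        }
      }
    }
    acc
  }
  total <- total + params$alpha *
    (trace_term(f$u1, problem$lu1) + trace_term(f$v1, problem$lv1) +
       trace_term(f$u2, problem$lu2) + trace_term(f$v2, problem$lv2))
  total + params$gamma * (sum(f$u1) + sum(f$v1) + sum(f$u2) + sum(f$v2))
}

oracle_cross_consistency <- function(u1, u2, s) {
  s <- as.matrix(s)
  su1 <- s %*% u1
  acc <- 0
  for (i in seq_len(nrow(s))) {
    for (j in seq_len(nrow(s))) {
      acc <- acc + (sum(su1[i, ] * su1[j, ]) - sum(u2[i, ] * u2[j, ]))^2
    }
  }
  acc
}

# AUROC as explicit concordant-pair counting with 0.5 per tie.
oracle_auroc <- function(score, label) {
  label <- as.logical(label)
  pos <- score[label]
  neg <- score[!label]
  acc <- 0
  for (p in pos) {
    for (q in neg) {
      acc <- acc + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  acc / (length(pos) * length(neg))
}

# AUPR as an explicit sweep over distinct thresholds of the step curve.
oracle_aupr <- function(score, label) {
  label <- as.logical(label)
  np <- sum(label)
  ths <- sort(unique(score), decreasing = TRUE)
  area <- 0
  rec_prev <- 0
  for (th in ths) {
    taken <- score >= th
    tp <- sum(label & taken)
    prec <- tp / sum(taken)
    rec <- tp / np
    area <- area + (rec - rec_prev) * prec
    rec_prev <- rec
  }
  area
}

# Exact hypergeometric upper tail by summing the point mass written out with
# choose().
oracle_hyper_upper <- function(N, K, n, k) {
  acc <- 0
  for (x in k:min(n, K)) {
    acc <- acc + choose(K, x) * choose(N - K, n - x) / choose(N, n)
  }
  acc
}

random_problem <- function(n1 = 6, m1 = 5, n2 = 5, m2 = 4, seed = 1,
                           density = 0.3, overlap = 0.5) {
  sp <- synthetic_spec(n1 = n1, m1 = m1, n2 = n2, m2 = m2,
                       r_true = 2L, overlap_fraction = overlap,
                       density1 = density, density2 = density,
                       noise_flip_rate = 0, seed = seed)
  simulate_problem(sp)
}

random_factors <- function(problem, r1, r2, seed = 1) {
  withr::with_seed(seed, list(
    u1 = matrix(runif(nrow(problem$x1$values) * r1), ncol = r1),
    v1 = matrix(runif(ncol(problem$x1$values) * r1), ncol = r1),
    u2 = matrix(runif(nrow(problem$x2$values) * r2), ncol = r2),
    v2 = matrix(runif(ncol(problem$x2$values) * r2), ncol = r2)
  ))
}
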