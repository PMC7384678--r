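# The coupled factorization: objective, update rules, convergence loop,
# prediction and serialization.

test_that("the objective agrees with an explicit-loop oracle", {
  for (seed in 1:4) {
    sim <- random_problem(n1 = 4, m1 = 3, n2 = 4, m2 = 2, seed = seed)
    f <- random_factors(sim$problem, 2, 2, seed = seed + 10)
    params <- anchor_nmf_params(r1 = 2, r2 = 2, alpha = 0.05, beta = 0.2,
                                gamma = 0.01, w = 0.3, seed = 1)
    j <- anchor_nmf_objective(sim$problem, f, params)
    j_oracle <- oracle_objective(sim$problem, f, params)
    expect_equal(j, j_oracle, tolerance = 1e-10)
  }
})

test_that("degenerate objectives vanish", {
  sim <- random_problem(n1 = 4, m1 = 3, n2 = 4, m2 = 2, seed = 1)
  p <- sim$problem
  # perfect reconstruction with alpha = beta = gamma = 0 gives J = 0
  x1 <- as.matrix(p$x1$values)
  x2 <- as.matrix(p$x2$values)
  f <- list(u1 = x1, v1 = diag(ncol(x1)), u2 = x2, v2 = diag(ncol(x2)))
  params <- anchor_nmf_params(r1 = ncol(x1), r2 = ncol(x2),
                              alpha = 0, beta = 0, gamma = 0, w = 0.3)
  expect_equal(anchor_nmf_objective(p, f, params), 0, tolerance = 1e-12)

  # negative factors and shape mismatches are rejected
  f_bad <- f; f_bad$u1[1, 1] <- -1
  expect_error(anchor_nmf_objective(p, f_bad, params), "negative")
  f_shape <- f; f_shape$v1 <- f_shape$v1[-1, , drop = FALSE]
  expect_error(anchor_nmf_objective(p, f_shape, params), "shape")
})

test_that("cross-network consistency matches its loop oracle and limits", {
  # identical anchored factors, identity anchor map: zero disagreement
  u <- matrix(runif(12), 4, 3)
  s_id <- diag(4)
  expect_equal(cross_consistency(u, u, s_id), 0, tolerance = 1e-12)

  # no anchors: reduces to the Gram mass of u2
  u2 <- matrix(runif(8), 4, 2)
  s0 <- matrix(0, 4, 4)
  expect_equal(cross_consistency(u, u2, s0), sum(tcrossprod(u2)^2), tolerance = 1e-12)

  # 3-drug toy with one anchor vs the entrywise oracle
  withr::with_seed(7, {
    u1 <- matrix(runif(6), 3, 2)
    u2b <- matrix(runif(6), 3, 2)
  })
  s <- matrix(0, 3, 3); s[2, 1] <- 1
  expect_equal(cross_consistency(u1, u2b, s),
               oracle_cross_consistency(u1, u2b, s), tolerance = 1e-10)

  expect_error(cross_consistency(u1, u2b, matrix(0, 2, 3)), "shape")
})

test_that("multiplicative updates preserve non-negativity and exact zeros", {
  for (seed in 1:5) {
    sim <- random_problem(n1 = 6, m1 = 5, n2 = 5, m2 = 4, seed = seed)
    params <- anchor_nmf_params(r1 = 3, r2 = 3, alpha = 0.1, beta = 0.5,
                                gamma = 0.05, w = 0.3, seed = seed)
    st <- anchornmf:::make_state(sim$problem, params)
    f <- random_factors(sim$problem, 3, 3, seed = seed)
    f$u1[2, ] <- 0  # an exactly zero row must stay zero
    u1_new <- anchornmf:::update_u1(st, f, params)
    u2_new <- anchornmf:::update_u2(st, f, params)
    v1_new <- anchornmf:::update_v(st, f, params, 1L)
    v2_new <- anchornmf:::update_v(st, f, params, 2L)
    expect_true(all(u1_new >= 0) && all(u2_new >= 0) &&
                  all(v1_new >= 0) && all(v2_new >= 0))
    expect_true(all(u1_new[2, ] == 0))
  }
})

test_that("each single update does not increase the objective", {
  for (seed in 1:5) {
    sim <- random_problem(n1 = 5, m1 = 4, n2 = 5, m2 = 4, seed = seed)
    params <- anchor_nmf_params(r1 = 2, r2 = 2, alpha = 0.05, beta = 0.1,
                                gamma = 0.01, w = 0.3, seed = seed)
    st <- anchornmf:::make_state(sim$problem, params)
    f <- random_factors(sim$problem, 2, 2, seed = 100 + seed)
    j0 <- anchornmf:::objective_state(st, f, params)
    for (upd in list(
      function(f) { f$u1 <- anchornmf:::update_u1(st, f, params); f },
      function(f) { f$u2 <- anchornmf:::update_u2(st, f, params); f },
      function(f) { f$v1 <- anchornmf:::update_v(st, f, params, 1L); f },
      function(f) { f$v2 <- anchornmf:::update_v(st, f, params, 2L); f }
    )) {
      f1 <- upd(f)
      j1 <- anchornmf:::objective_state(st, f1, params)
      expect_lte(j1, j0 * (1 + 1e-8))
    }
  }
})

test_that("a stationary point is a fixed point of the updates", {
  # with exact reconstruction and no penalties, numerator and denominator of
  # the multiplicative ratio coincide analytically: the factors must not move
  sim <- random_problem(n1 = 5, m1 = 4, n2 = 5, m2 = 4, seed = 2)
  p <- sim$problem
  x1 <- as.matrix(p$x1$values)
  x2 <- as.matrix(p$x2$values)
  f <- list(u1 = x1, v1 = diag(ncol(x1)), u2 = x2, v2 = diag(ncol(x2)))
  params <- anchor_nmf_params(r1 = ncol(x1), r2 = ncol(x2),
                              alpha = 0, beta = 0, gamma = 0, w = 0.3)
  st <- anchornmf:::make_state(p, params)
  u1_next <- anchornmf:::update_u1(st, f, params)
  v1_next <- anchornmf:::update_v(st, f, params, 1L)
  expect_equal(u1_next, f$u1, tolerance = 1e-9)
  # columns with no observations have a flat objective; their factor rows are
  # not pinned, so compare only where data exists
  obs_cols <- colSums(x1) > 0
  expect_equal(unname(v1_next[obs_cols, ]), unname(f$v1[obs_cols, ]),
               tolerance = 1e-9)
})

test_that("the fit loop stops per the convergence rule and records its trace", {
  sim <- random_problem(seed = 6)
  # delta = Inf stops after exactly one sweep
  p_inf <- anchor_nmf_params(r1 = 2, r2 = 2, delta = Inf, seed = 1)
  fit1 <- anchor_nmf(sim$problem, p_inf)
  expect_equal(fit1$iterations, 1L)
  expect_true(fit1$converged)
  expect_length(fit1$objective_trace, 2L)

  # objective trace non-increasing within relative slack
  pp <- anchor_nmf_params(r1 = 2, r2 = 2, max_iter = 80, seed = 1)
  fit <- anchor_nmf(sim$problem, pp)
  tr <- fit$objective_trace
  expect_true(all(diff(tr) <= 1e-8 * abs(tr[-length(tr)])))
})

test_that("ranks exceeding the data are clamped with a warning", {
  sim <- random_problem(n1 = 12, m1 = 10, n2 = 10, m2 = 9, seed = 1, density = 0.2)
  pp <- anchor_nmf_params(delta = Inf)  # default ranks 90/70 on a tiny problem
  expect_warning(expect_warning(fit <- anchor_nmf(sim$problem, pp), "clamped"),
                 "clamped")  # both r1 and r2 are clamped
  expect_lte(ncol(fit$u1), 10)
})

test_that("beta = 0 with no anchors decouples into two single-domain fits", {
  sp <- synthetic_spec(n1 = 12, m1 = 10, n2 = 10, m2 = 8, r_true = 2,
                       overlap_fraction = 0, density1 = 0.15, density2 = 0.15,
                       noise_flip_rate = 0, seed = 5)
  sim <- simulate_problem(sp)
  expect_equal(nrow(sim$problem$anchors$pairs), 0)
  n_sweeps <- 25L
  pp <- anchor_nmf_params(r1 = 3, r2 = 3, beta = 0, delta = 1e-300,
                          max_iter = n_sweeps, seed = 11)
  joint <- anchor_nmf(sim$problem, pp)
  g1 <- grnmf(sim$problem$x1, sim$problem$au1, sim$problem$av1, r = 3,
              delta = 1e-300, max_iter = n_sweeps,
              seed = anchornmf:::derive_seed(11L, 1L))
  g2 <- grnmf(sim$problem$x2, sim$problem$au2, sim$problem$av2, r = 3,
              delta = 1e-300, max_iter = n_sweeps,
              seed = anchornmf:::derive_seed(11L, 2L))
  expect_equal(joint$u1, g1$u, tolerance = 1e-10)
  expect_equal(joint$v1, g1$v, tolerance = 1e-10)
  expect_equal(joint$u2, g2$u, tolerance = 1e-10)
  expect_equal(joint$v2, g2$v, tolerance = 1e-10)
})

test_that("permuting domain-1 drugs permutes factors and preserves scores", {
  sim <- random_problem(n1 = 8, m1 = 6, n2 = 6, m2 = 5, seed = 8, density = 0.2)
  p <- sim$problem
  n1 <- nrow(p$x1$values)
  perm <- withr::with_seed(3, sample(n1))

  ids_perm <- rownames(p$x1$values)[perm]
  x1p <- structure(list(values = p$x1$values[perm, ], domain = p$x1$domain),
                   class = "interaction_matrix")
  au1p <- similarity_matrix(p$au1$values[perm, perm])
  pb <- cross_domain_problem(x1p, au1p, p$av1, p$x2, p$au2, p$av2)

  f0 <- random_factors(p, 2, 2, seed = 9)
  f0p <- f0; f0p$u1 <- f0$u1[perm, , drop = FALSE]
  pp <- anchor_nmf_params(r1 = 2, r2 = 2, delta = 1e-300, max_iter = 10, seed = 1)

  fit_a <- anchor_nmf(p, pp, init = f0)
  fit_b <- anchor_nmf(pb, pp, init = f0p)
  expect_equal(fit_a$objective_trace, fit_b$objective_trace, tolerance = 1e-10)
  expect_equal(fit_a$u1[perm, ], fit_b$u1, tolerance = 1e-10)
  sc_a <- predict(fit_a, 1)[perm, ]
  sc_b <- predict(fit_b, 1)
  expect_equal(unname(sc_a), unname(sc_b), tolerance = 1e-10)
})

test_that("predicted scores are the factor outer product", {
  sim <- random_problem(seed = 2)
  pp <- anchor_nmf_params(r1 = 2, r2 = 2, delta = Inf, seed = 1)
  fit <- anchor_nmf(sim$problem, pp)
  # hand-checkable rank-1 case
  fit$u1 <- matrix(c(1, 2), 2, 1); fit$v1 <- matrix(c(3, 1), 2, 1)
  fit$ids$drugs1 <- c("a", "b"); fit$ids$cols1 <- c("p", "q")
  expect_equal(unname(predict(fit, 1)), matrix(c(3, 6, 1, 2), 2))
  fit$u1[] <- 0
  expect_true(all(predict(fit, 1) == 0))
})

test_that("fitted models serialize and restore with bit-identical predictions", {
  sim <- random_problem(seed = 12)
  pp <- anchor_nmf_params(r1 = 2, r2 = 2, max_iter = 15, delta = 1e-300, seed = 4)
  fit <- anchor_nmf(sim$problem, pp)
  dir <- withr::local_tempdir()
  write_anchor_nmf(fit, dir)
  fit2 <- read_anchor_nmf(dir)
  expect_identical(predict(fit, 1), predict(fit2, 1))
  expect_identical(predict(fit, 2), predict(fit2, 2))
  expect_equal(fit2$iterations, fit$iterations)
})

test_that("tidy, glance and autoplot summarize a fit", {
  sim <- random_problem(seed = 2)
  fit <- anchor_nmf(sim$problem, anchor_nmf_params(r1 = 2, r2 = 2, max_iter = 10,
                                                   delta = 1e-300, seed = 1))
  td <- tidy(fit)
  expect_named(td, c("iteration", "objective", "delta"))
  expect_equal(nrow(td), 11)
  gl <- glance(fit)
  expect_equal(gl$iterations, 10L)
  expect_s3_class(autoplot(fit), "ggplot")
})
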