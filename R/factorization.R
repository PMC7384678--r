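# The coupled factorization model: objective, multiplicative updates,
# convergence loop and score prediction.
#
# Each domain i holds a weighted reconstruction term
#   || W_i (.) (X_i - U_i V_i^T) ||_F^2
# with one-class weights W_i in {1, w}, graph-Laplacian smoothness penalties
#   alpha * ( tr(U_i^T L_u U_i) + tr(V_i^T L_v V_i) )
# and an l1 penalty gamma * ( ||U_i||_1 + ||V_i||_1 ).  The two domains are
# coupled through the anchor mapping matrix S (n2 x n1):
#   beta * || S U1 (S U1)^T - U2 U2^T ||_F^2
# forcing the Gram matrices of anchored drug factors to agree across domains.

#' Hyperparameters for the coupled factorization
#'
#' @param r1,r2 Ranks of the domain-1 and domain-2 factor pairs.  Defaults 90
#'   and 70; when a domain is too small, ranks are clamped to
#'   `max(1, floor(0.1 * min(n_i, m_i)))` with a warning (the rank heuristic
#'   `r_i <= 0.1 * min(n_i, m_i)` trades accuracy against running time).
#' @param alpha Weight of the within-network smoothness penalty.  Default 0.01.
#' @param beta Weight of the cross-network consistency penalty.  Default 0.01.
#' @param gamma Weight of the l1 sparsity penalty.  Default 0.01.
#' @param w One-class weight for unobserved entries, in `[0, 1)`.  Default 0.3.
#' @param delta Convergence tolerance on the objective change.  Default 1e-6.
#' @param max_iter Maximum number of full update sweeps.  Default 500.
#' @param seed Integer seed for factor initialization.
#' @param convergence `"absolute"` stops when `|J(t+1) - J(t)| <= delta` (the
#'   printed rule); `"relative"` divides by `|J(t)|` first, useful because the
#'   objective scale is data-dependent.
#' @param epsilon Additive guard on update denominators.  Default 1e-12.
#' @return A list of class `anchor_nmf_params`.
#' @export
anchor_nmf_params <- function(r1 = 90L, r2 = 70L, alpha = 0.01, beta = 0.01,
                              gamma = 0.01, w = 0.3, delta = 1e-6,
                              max_iter = 500L, seed = 1L,
                              convergence = c("absolute", "relative"),
                              epsilon = 1e-12) {
  convergence <- match.arg(convergence)
  stopifnot(r1 >= 1, r2 >= 1, alpha >= 0, beta >= 0, gamma >= 0,
            delta > 0 || is.infinite(delta), max_iter >= 1, epsilon >= 0)
  if (w < 0 || w >= 1) abort("`w` must lie in [0, 1)")
  structure(list(r1 = as.integer(r1), r2 = as.integer(r2), alpha = alpha,
                 beta = beta, gamma = gamma, w = w, delta = delta,
                 max_iter = as.integer(max_iter), seed = as.integer(seed),
                 convergence = convergence, epsilon = epsilon),
            class = "anchor_nmf_params")
}

# Clamp a requested rank that exceeds the domain size to the 10% heuristic.
clamp_rank <- function(r, n, m, label) {
  lim <- min(n, m)
  if (r <= lim) return(r)
  r_new <- max(1L, as.integer(floor(0.1 * lim)))
  warn(sprintf("rank %s = %d exceeds min(n, m) = %d; clamped to %d (0.1 * min heuristic)",
               label, r, lim, r_new))
  r_new
}

# Strictly positive uniform initialization, scale-matched to the data so that
# E[(U V^T)_ij] is on the order of mean(X).
init_factor <- function(n, r, scale) {
  m <- matrix(runif(n * r), n, r) * scale
  pmax(m, 1e-10)
}

init_factors_domain <- function(x_dense, r, seed) {
  mx <- mean(x_dense)
  scale <- sqrt(max(mx, 1e-4) / r)
  withr::with_seed(seed, {
    u <- init_factor(nrow(x_dense), r, scale)
    v <- init_factor(ncol(x_dense), r, scale)
  })
  list(u = u, v = v)
}

#' Cross-network consistency of anchored drug factors
#'
#' The disagreement `|| S U1 (S U1)^T - U2 U2^T ||_F^2` between the Gram matrix
#' of the domain-1 drug factors projected onto domain 2 by the anchor map `S`
#' and the Gram matrix of the domain-2 drug factors.  Zero when anchored drugs
#' have identical latent profiles (and non-anchored domain-2 drugs have zero
#' Gram mass); always non-negative.
#'
#' @param u1 `n1 x r1` non-negative matrix.
#' @param u2 `n2 x r2` non-negative matrix.
#' @param s Anchor mapping: an `anchor_map` or an `n2 x n1` 0/1 matrix.
#' @return Scalar disagreement.
#' @export
cross_consistency <- function(u1, u2, s) {
  s <- if (inherits(s, "anchor_map")) s$matrix else s
  if (ncol(s) != nrow(u1) || nrow(s) != nrow(u2)) {
    abort("anchor map shape does not match the factor matrices")
  }
  su1 <- as.matrix(s %*% u1)
  d <- tcrossprod(su1) - tcrossprod(u2)
  sum(d * d)
}

# Internal fit state shared by the update rules.  Dense matrices throughout:
# the problems this package targets are desk-scale after similarity matrices
# are dense anyway.
make_state <- function(problem, params) {
  x1 <- as.matrix(problem$x1$values)
  x2 <- as.matrix(problem$x2$values)
  s <- as.matrix(problem$anchors$matrix)
  list(
    x1 = x1, x2 = x2,
    i1 = (x1 > 0) * 1, i2 = (x2 > 0) * 1,
    au1 = problem$lu1$adjacency, du1 = problem$lu1$degree,
    av1 = problem$lv1$adjacency, dv1 = problem$lv1$degree,
    au2 = problem$lu2$adjacency, du2 = problem$lu2$degree,
    av2 = problem$lv2$adjacency, dv2 = problem$lv2$degree,
    s = s,
    sts = crossprod(s)  # cached once: S^T S is constant across iterations
  )
}

#' Evaluate the coupled objective
#'
#' Sums the four terms of the model objective: weighted reconstruction error in
#' each domain, the cross-network consistency penalty, the graph smoothness
#' traces and the l1 penalties.
#'
#' @param problem A [cross_domain_problem()].
#' @param factors List with non-negative matrices `u1`, `v1`, `u2`, `v2`.
#' @param params An [anchor_nmf_params()].
#' @return Scalar objective value.
#' @export
anchor_nmf_objective <- function(problem, factors, params) {
  st <- make_state(problem, params)
  objective_state(st, factors, params)
}

objective_state <- function(st, f, params) {
  for (nm in c("u1", "v1", "u2", "v2")) {
    if (any(f[[nm]] < 0)) abort(sprintf("negative entries in factor `%s`", nm))
  }
  if (nrow(f$u1) != nrow(st$x1) || nrow(f$v1) != ncol(st$x1) ||
      nrow(f$u2) != nrow(st$x2) || nrow(f$v2) != ncol(st$x2) ||
      ncol(f$u1) != ncol(f$v1) || ncol(f$u2) != ncol(f$v2)) {
    abort("factor shapes inconsistent with the problem")
  }
  w <- params$w
  recon <- 0
  for (d in 1:2) {
    x <- st[[paste0("x", d)]]
    uvt <- tcrossprod(f[[paste0("u", d)]], f[[paste0("v", d)]])
    wm <- matrix(w, nrow(x), ncol(x)); wm[x > 0] <- 1
    r <- wm * (x - uvt)
    recon <- recon + sum(r * r)
  }
  cross <- cross_consistency(f$u1, f$u2, st$s)
  smooth <-
    sum(f$u1 * ((st$du1 - st$au1) %*% f$u1)) +
    sum(f$v1 * ((st$dv1 - st$av1) %*% f$v1)) +
    sum(f$u2 * ((st$du2 - st$au2) %*% f$u2)) +
    sum(f$v2 * ((st$dv2 - st$av2) %*% f$v2))
  l1 <- sum(f$u1) + sum(f$v1) + sum(f$u2) + sum(f$v2)
  recon + params$beta * cross + params$alpha * smooth + params$gamma * l1
}

# --- multiplicative update rules ------------------------------------------
# Notation follows the model: for domain i,
#   R_i = (1 - w^2) * I_i (.) (U_i V_i^T)
#   T_i = (R_i + w^2 * U_i V_i^T) V_i  =  (W_i^2 (.) (U_i V_i^T)) V_i
# and for the cross term (S the anchor matrix, StS cached)
#   Delta = S^T U2 U2^T S U1
#   Theta = S^T S U1 U1^T S^T S U1
#   Xi    = S U1 U1^T S^T U2
# Each rule multiplies the factor by the ratio of the negative to the positive
# part of the gradient, so non-negativity is preserved and stationary points
# are fixed points.  `relax` in (0, 1] damps the step as
# u * (1 - relax + relax * ratio): at relax = 1 this is the plain rule; as
# relax -> 0 the factor does not move.  The fit loop uses this to safeguard
# monotone descent, because the plain ratio step can overshoot the quartic
# cross-consistency term when beta is large.

damp <- function(ratio, relax) {
  if (relax == 1) ratio else 1 - relax + relax * ratio
}

update_u1 <- function(st, f, params, relax = 1) {
  w2 <- params$w^2
  uvt <- tcrossprod(f$u1, f$v1)
  r1 <- (1 - w2) * st$i1 * uvt
  t1 <- (r1 + w2 * uvt) %*% f$v1
  stu1 <- st$sts %*% f$u1
  delta <- crossprod(st$s, tcrossprod(f$u2) %*% (st$s %*% f$u1))
  theta <- stu1 %*% crossprod(f$u1, stu1)
  num <- st$x1 %*% f$v1 + params$alpha * (st$au1 %*% f$u1) + 2 * params$beta * delta
  den <- t1 + params$alpha * (st$du1 %*% f$u1) + 2 * params$beta * theta +
    0.5 * params$gamma + params$epsilon
  f$u1 * damp(as.matrix(num / den), relax)
}

update_u2 <- function(st, f, params, relax = 1) {
  w2 <- params$w^2
  uvt <- tcrossprod(f$u2, f$v2)
  r2 <- (1 - w2) * st$i2 * uvt
  t2 <- (r2 + w2 * uvt) %*% f$v2
  su1 <- st$s %*% f$u1
  xi <- su1 %*% crossprod(su1, f$u2)
  num <- st$x2 %*% f$v2 + params$alpha * (st$au2 %*% f$u2) + 2 * params$beta * xi
  den <- t2 + params$alpha * (st$du2 %*% f$u2) +
    2 * params$beta * (f$u2 %*% crossprod(f$u2)) +
    0.5 * params$gamma + params$epsilon
  f$u2 * damp(as.matrix(num / den), relax)
}

update_v <- function(st, f, params, domain, relax = 1) {
  w2 <- params$w^2
  u <- f[[paste0("u", domain)]]
  v <- f[[paste0("v", domain)]]
  x <- st[[paste0("x", domain)]]
  ind <- st[[paste0("i", domain)]]
  av <- st[[paste0("av", domain)]]
  dv <- st[[paste0("dv", domain)]]
  uvt <- tcrossprod(u, v)
  r <- (1 - w2) * ind * uvt
  num <- crossprod(x, u) + params$alpha * (av %*% v)
  den <- (t(r) + w2 * tcrossprod(v, u)) %*% u + params$alpha * (dv %*% v) +
    0.5 * params$gamma + params$epsilon
  v * damp(as.matrix(num / den), relax)
}

#' Fit the coupled factorization
#'
#' Alternates multiplicative updates of `U1`, `U2`, `V1`, `V2` until the
#' objective change falls below `delta` or `max_iter` sweeps are reached.  The
#' anchor Gram product `S^T S` is cached once before the loop.  Sweeps are
#' safeguarded: the plain multiplicative ratio step can overshoot the quartic
#' cross-consistency term when `beta` is large, so any sweep that would
#' increase the objective is retried with a step-halved damped update
#' (`u * (1 - lambda + lambda * ratio)`), which preserves fixed points and
#' non-negativity and guarantees a non-increasing objective trace.
#' Initialization
#' draws strictly positive uniform entries scaled by `sqrt(mean(X_i) / r_i)`,
#' from per-domain seeds derived from `params$seed`, so a `beta = 0` fit with
#' no anchors is numerically identical to two independent single-domain fits.
#'
#' @param problem A [cross_domain_problem()].
#' @param params An [anchor_nmf_params()].
#' @param init Optional list of starting factors `u1`, `v1`, `u2`, `v2`
#'   (overrides seeded initialization).
#' @return An object of class `anchor_nmf` with elements `u1`, `v1`, `u2`,
#'   `v2`, `objective_trace` (value before updates followed by the value after
#'   each sweep), `converged`, `iterations`, `params` and the entity ids.
#' @export
anchor_nmf <- function(problem, params = anchor_nmf_params(), init = NULL) {
  stopifnot(inherits(problem, "cross_domain_problem"),
            inherits(params, "anchor_nmf_params"))
  st <- make_state(problem, params)
  params$r1 <- clamp_rank(params$r1, nrow(st$x1), ncol(st$x1), "r1")
  params$r2 <- clamp_rank(params$r2, nrow(st$x2), ncol(st$x2), "r2")
  if (is.null(init)) {
    f1 <- init_factors_domain(st$x1, params$r1, derive_seed(params$seed, 1L))
    f2 <- init_factors_domain(st$x2, params$r2, derive_seed(params$seed, 2L))
    f <- list(u1 = f1$u, v1 = f1$v, u2 = f2$u, v2 = f2$v)
  } else {
    f <- init[c("u1", "v1", "u2", "v2")]
  }
  j_prev <- objective_state(st, f, params)
  trace <- j_prev
  converged <- FALSE
  iter <- 0L
  sweep_once <- function(f, relax) {
    f$u1 <- update_u1(st, f, params, relax)
    f$u2 <- update_u2(st, f, params, relax)
    f$v1 <- update_v(st, f, params, 1L, relax)
    f$v2 <- update_v(st, f, params, 2L, relax)
    f
  }
  while (iter < params$max_iter) {
    iter <- iter + 1L
    # plain multiplicative sweep, with step-halving fallback so the objective
    # never increases (the quartic cross term can overshoot at large beta)
    relax <- 1
    f_new <- sweep_once(f, relax)
    j <- objective_state(st, f_new, params)
    while (is.finite(j) && j > j_prev * (1 + 1e-12) && relax > 1e-8) {
      relax <- relax / 2
      f_new <- sweep_once(f, relax)
      j <- objective_state(st, f_new, params)
    }
    f <- f_new
    if (!is.finite(j)) {
      abort(sprintf("objective became non-finite at sweep %d (J = %g)", iter, j))
    }
    trace <- c(trace, j)
    dj <- abs(j - j_prev)
    if (params$convergence == "relative") dj <- dj / max(abs(j_prev), .Machine$double.eps)
    j_prev <- j
    if (dj <= params$delta) {
      converged <- TRUE
      break
    }
  }
  structure(list(
    u1 = f$u1, v1 = f$v1, u2 = f$u2, v2 = f$v2,
    objective_trace = trace, converged = converged, iterations = iter,
    params = params,
    ids = list(
      drugs1 = rownames(problem$x1$values), cols1 = colnames(problem$x1$values),
      drugs2 = rownames(problem$x2$values), cols2 = colnames(problem$x2$values)
    )
  ), class = "anchor_nmf")
}

#' @export
print.anchor_nmf <- function(x, ...) {
  cat(sprintf("<anchor_nmf> ranks (%d, %d); %d sweeps, %s (final J = %.6g)\n",
              ncol(x$u1), ncol(x$u2), x$iterations,
              if (x$converged) "converged" else "not converged",
              x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}

#' Predicted association scores
#'
#' Reconstructs the dense score matrix `U_i V_i^T` for one domain.  Training
#' positives are not masked here; exclusion of known interactions is the
#' evaluator's (or ranker's) concern.
#'
#' @param object A fitted `anchor_nmf` model.
#' @param domain 1 (drug-disease) or 2 (drug-target).
#' @param ... Unused.
#' @return Dense non-negative score matrix with identifier dimnames.
#' @export
predict.anchor_nmf <- function(object, domain = 1L, ...) {
  stopifnot(domain %in% c(1L, 2L))
  u <- object[[paste0("u", domain)]]
  v <- object[[paste0("v", domain)]]
  s <- tcrossprod(u, v)
  rn <- object$ids[[if (domain == 1L) "drugs1" else "drugs2"]]
  cn <- object$ids[[if (domain == 1L) "cols1" else "cols2"]]
  dimnames(s) <- list(rn, cn)
  s
}

#' Per-iteration objective trace as a tibble
#'
#' @param x A fitted `anchor_nmf` model.
#' @param ... Unused.
#' @return Tibble with `iteration` (0 = initial factors), `objective` and
#'   `delta` (change from the previous sweep).
#' @export
tidy.anchor_nmf <- function(x, ...) {
  tr <- x$objective_trace
  tibble(
    iteration = seq_along(tr) - 1L,
    objective = tr,
    delta = c(NA_real_, diff(tr))
  )
}

#' One-row model summary
#'
#' @param x A fitted `anchor_nmf` model.
#' @param ... Unused.
#' @return One-row tibble with ranks, hyperparameters, convergence status,
#'   sweeps run and the final objective.
#' @export
glance.anchor_nmf <- function(x, ...) {
  p <- x$params
  tibble(
    r1 = ncol(x$u1), r2 = ncol(x$u2),
    alpha = p$alpha, beta = p$beta, gamma = p$gamma, w = p$w,
    converged = x$converged, iterations = x$iterations,
    objective = x$objective_trace[length(x$objective_trace)]
  )
}

#' Objective-trace plot
#'
#' @param object A fitted `anchor_nmf` model.
#' @param ... Unused.
#' @return A ggplot of the objective value per sweep (log10 y scale).
#' @export
autoplot.anchor_nmf <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "sweep", y = "objective J",
                  title = "Coupled factorization objective trace")
}

#' Single-domain graph-regularized weighted NMF
#'
#' The uncoupled special case: completes one interaction matrix under the
#' one-class weighting scheme with graph smoothness and l1 penalties, using
#' the same multiplicative kernels as [anchor_nmf()] with the cross-network
#' term removed.  Used as the decoupling reference (a coupled fit with
#' `beta = 0` and no anchors must reproduce it exactly) and as a baseline.
#'
#' @param x An `interaction_matrix`.
#' @param au,av `similarity_matrix` objects over rows and columns of `x`.
#' @param r Rank.
#' @param alpha,gamma,w,delta,max_iter,epsilon,convergence As in
#'   [anchor_nmf_params()].
#' @param seed Integer seed for initialization.
#' @param include_diagonal Passed to [laplacian_pair()].
#' @return List of class `grnmf` with `u`, `v`, `objective_trace`,
#'   `converged`, `iterations`.
#' @export
grnmf <- function(x, au, av, r, alpha = 0.01, gamma = 0.01, w = 0.3,
                  delta = 1e-6, max_iter = 500L, seed = 1L, epsilon = 1e-12,
                  convergence = c("absolute", "relative"),
                  include_diagonal = TRUE) {
  convergence <- match.arg(convergence)
  xd <- as.matrix(x$values)
  lu <- laplacian_pair(au, include_diagonal)
  lv <- laplacian_pair(av, include_diagonal)
  r <- clamp_rank(as.integer(r), nrow(xd), ncol(xd), "r")
  f0 <- init_factors_domain(xd, r, seed)
  u <- f0$u; v <- f0$v
  ind <- (xd > 0) * 1
  w2 <- w^2
  obj <- function(u, v) {
    uvt <- tcrossprod(u, v)
    wm <- matrix(w, nrow(xd), ncol(xd)); wm[xd > 0] <- 1
    res <- wm * (xd - uvt)
    sum(res * res) +
      alpha * (sum(u * (lu$laplacian %*% u)) + sum(v * (lv$laplacian %*% v))) +
      gamma * (sum(u) + sum(v))
  }
  j_prev <- obj(u, v)
  trace <- j_prev
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    uvt <- tcrossprod(u, v)
    tmat <- (((1 - w2) * ind + w2) * uvt) %*% v
    u <- u * (xd %*% v + alpha * (lu$adjacency %*% u)) /
      (tmat + alpha * (lu$degree %*% u) + 0.5 * gamma + epsilon)
    uvt <- tcrossprod(u, v)
    rmat <- (1 - w2) * ind * uvt
    v <- v * (crossprod(xd, u) + alpha * (lv$adjacency %*% v)) /
      ((t(rmat) + w2 * tcrossprod(v, u)) %*% u + alpha * (lv$degree %*% v) +
         0.5 * gamma + epsilon)
    j <- obj(u, v)
    trace <- c(trace, j)
    dj <- abs(j - j_prev)
    if (convergence == "relative") dj <- dj / max(abs(j_prev), .Machine$double.eps)
    j_prev <- j
    if (dj <= delta) {
      converged <- TRUE
      break
    }
  }
  structure(list(u = u, v = v, objective_trace = trace,
                 converged = converged, iterations = iter),
            class = "grnmf")
}

#' Ranked candidate table for query entities
#'
#' Tidy interface over [predict.anchor_nmf()]: for each query drug (or each
#' query column entity with `direction = "by_column"`), the top-`k` candidates
#' by predicted score.  Ties are broken by candidate identifier so rankings
#' are deterministic across platforms.
#'
#' @param fit A fitted `anchor_nmf` model.
#' @param domain 1 or 2.
#' @param query_ids Identifiers to rank candidates for; default all.
#' @param top_k Candidates kept per query.  Default 20.
#' @param direction `"by_row"` ranks column entities for each drug;
#'   `"by_column"` ranks drugs for each disease/target.
#' @param exclude Optional `interaction_matrix` of known training positives to
#'   drop from the candidate lists before ranking.
#' @return Tibble with `query_id`, `candidate_id`, `score`, `rank`.
#' @export
rank_candidates <- function(fit, domain = 1L, query_ids = NULL, top_k = 20L,
                            direction = c("by_row", "by_column"),
                            exclude = NULL) {
  direction <- match.arg(direction)
  scores <- predict(fit, domain)
  if (direction == "by_column") scores <- t(scores)
  if (is.null(query_ids)) query_ids <- rownames(scores)
  missing_ids <- setdiff(query_ids, rownames(scores))
  if (length(missing_ids)) {
    abort(sprintf("unknown query id(s): %s", paste(head(missing_ids, 5), collapse = ", ")))
  }
  excl <- NULL
  if (!is.null(exclude)) {
    excl <- as.matrix(exclude$values) > 0
    if (direction == "by_column") excl <- t(excl)
  }
  purrr::map_dfr(query_ids, function(q) {
    s <- scores[q, ]
    if (!is.null(excl)) s <- s[!excl[q, ]]
    if (length(s) == 0L) {
      return(tibble(query_id = character(), candidate_id = character(),
                    score = numeric(), rank = integer()))
    }
    ord <- order(-s, names(s))
    kk <- min(top_k, length(s))
    tibble(query_id = q,
           candidate_id = names(s)[ord[seq_len(kk)]],
           score = unname(s[ord[seq_len(kk)]]),
           rank = seq_len(kk))
  })
}

#' Serialize / restore a fitted model
#'
#' Writes each factor matrix as a delimited text file with identifier headers
#' plus a YAML manifest holding hyperparameters, convergence information and
#' the objective trace.  `read_anchor_nmf()` restores an object whose
#' predictions are bit-identical to the original's.
#'
#' @param fit A fitted `anchor_nmf` model.
#' @param dir Output directory (created if missing).
#' @export
write_anchor_nmf <- function(fit, dir) {
  stopifnot(inherits(fit, "anchor_nmf"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mats <- list(u1 = fit$u1, v1 = fit$v1, u2 = fit$u2, v2 = fit$v2)
  ids <- list(u1 = fit$ids$drugs1, v1 = fit$ids$cols1,
              u2 = fit$ids$drugs2, v2 = fit$ids$cols2)
  for (nm in names(mats)) {
    m <- mats[[nm]]
    header <- paste(c("id", paste0("f", seq_len(ncol(m)))), collapse = "\t")
    # %.17g round-trips IEEE doubles exactly
    body <- vapply(seq_len(nrow(m)), function(i) {
      paste(c(ids[[nm]][i], sprintf("%.17g", m[i, ])), collapse = "\t")
    }, "")
    writeLines(c(header, body), file.path(dir, paste0(nm, ".tsv")))
  }
  manifest <- list(
    params = unclass(fit$params),
    converged = fit$converged,
    iterations = fit$iterations,
    objective_trace = fit$objective_trace
  )
  yaml::write_yaml(manifest, file.path(dir, "model.yaml"))
  invisible(dir)
}

#' @rdname write_anchor_nmf
#' @param dir Directory previously written by `write_anchor_nmf()`.
#' @export
read_anchor_nmf <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "model.yaml"))
  read_mat <- function(nm) {
    df <- utils::read.table(file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                            header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    m
  }
  u1 <- read_mat("u1"); v1 <- read_mat("v1")
  u2 <- read_mat("u2"); v2 <- read_mat("v2")
  params <- do.call(anchor_nmf_params, manifest$params)
  structure(list(
    u1 = unname_keep(u1), v1 = unname_keep(v1),
    u2 = unname_keep(u2), v2 = unname_keep(v2),
    objective_trace = as.numeric(manifest$objective_trace),
    converged = manifest$converged, iterations = manifest$iterations,
    params = params,
    ids = list(drugs1 = rownames(u1), cols1 = rownames(v1),
               drugs2 = rownames(u2), cols2 = rownames(v2))
  ), class = "anchor_nmf")
}

unname_keep <- function(m) {
  dimnames(m) <- NULL
  m
}
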