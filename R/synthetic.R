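# Synthetic coupled two-domain problems with planted low-rank structure.
#
# The generator emulates the structure of the real drug-disease / drug-target
# data: two sparse binary bipartite networks whose drug layers partially
# overlap, with intra-layer similarities derived from the same latent features
# that generate the interactions.  Anchored drugs share their latent factor
# rows across domains (up to small per-domain perturbation), so cross-network
# coupling has genuine signal to transfer.

#' Specification of a synthetic coupled problem
#'
#' @param n1,m1 Drugs and diseases in domain 1.  Defaults 100 and 80.
#' @param n2,m2 Drugs and targets in domain 2.  Defaults 80 and 60.
#' @param r_true Planted latent rank.  Default 6.
#' @param overlap_fraction Fraction of domain-2 drugs anchored into domain 1,
#'   in `[0, 1]`.  Default 0.5 (roughly the overlap regime of real
#'   drug-disease / drug-target collections).
#' @param density1,density2 Positive-interaction densities, in `(0, 0.5]`.
#'   Defaults 0.08.
#' @param noise_flip_rate Probability of flipping an interaction label.
#'   Default 0.01.
#' @param similarity_kernel `"cosine"` (bounded `[0, 1]` for non-negative
#'   features) or `"rbf"`.
#' @param similarity_noise_sd Standard deviation of the Gaussian noise added
#'   to the latent features before the similarity kernels are computed.
#'   Default 0.5: observed similarities (chemical fingerprints, sequence or
#'   semantic scores) are weak proxies for the interaction-relevant features,
#'   not oracles for them.
#' @param perturb_sd Standard deviation of the per-domain perturbation added
#'   to shared drug factors.  Default 0.05.
#' @param seed Integer seed.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n1 = 100L, m1 = 80L, n2 = 80L, m2 = 60L,
                           r_true = 6L, overlap_fraction = 0.5,
                           density1 = 0.08, density2 = 0.08,
                           noise_flip_rate = 0.01,
                           similarity_kernel = c("cosine", "rbf"),
                           similarity_noise_sd = 0.5,
                           perturb_sd = 0.05, seed = 1L) {
  similarity_kernel <- match.arg(similarity_kernel)
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1,
            density1 > 0, density1 <= 0.5, density2 > 0, density2 <= 0.5,
            r_true >= 1, noise_flip_rate >= 0, noise_flip_rate < 1,
            perturb_sd >= 0, similarity_noise_sd >= 0)
  if (r_true > min(n1, m1, n2, m2)) abort("`r_true` exceeds the smallest dimension")
  structure(list(n1 = as.integer(n1), m1 = as.integer(m1),
                 n2 = as.integer(n2), m2 = as.integer(m2),
                 r_true = as.integer(r_true),
                 overlap_fraction = overlap_fraction,
                 density1 = density1, density2 = density2,
                 noise_flip_rate = noise_flip_rate,
                 similarity_kernel = similarity_kernel,
                 similarity_noise_sd = similarity_noise_sd,
                 perturb_sd = perturb_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

cosine_kernel <- function(f) {
  nr <- sqrt(base::rowSums(f^2))
  nr[nr == 0] <- 1
  s <- tcrossprod(f / nr)
  s[s < 0] <- 0
  s[s > 1] <- 1
  s
}

rbf_kernel <- function(f) {
  d2 <- as.matrix(stats::dist(f))^2
  sigma2 <- stats::median(d2[upper.tri(d2)])
  if (!is.finite(sigma2) || sigma2 <= 0) sigma2 <- 1
  exp(-d2 / (2 * sigma2))
}

# Binarize a non-negative score matrix by keeping the top `n_pos` entries.
top_quantile_binarize <- function(scores, density) {
  n_pos <- max(1L, round(density * length(scores)))
  thr <- sort(scores, decreasing = TRUE)[n_pos]
  out <- (scores >= thr) * 1
  # ties at the threshold can overshoot; trim deterministically by index
  extra <- sum(out) - n_pos
  if (extra > 0) {
    at_thr <- which(scores == thr & out == 1)
    out[at_thr[seq_len(extra)]] <- 0
  }
  out
}

#' Generate a coupled synthetic problem
#'
#' Draws non-negative latent factors for drugs, diseases and targets; anchored
#' drugs reuse their domain-1 factor rows in domain 2 with a small
#' perturbation.  Interactions are the top-quantile binarization of the latent
#' score matrices `U V^T` (so the planted structure survives at low density),
#' similarities are kernel matrices over noise-corrupted copies of the latent
#' features (see `similarity_noise_sd`), and labels are
#' optionally flipped with probability `noise_flip_rate`.  Anchored drugs
#' carry the same identifier in both domains, so the anchor map falls out of
#' the identifier intersection exactly as with real data.
#'
#' @param spec A [synthetic_spec()].
#' @return List of class `synthetic_problem` with `problem` (a
#'   [cross_domain_problem()]), `truth` (latent factors, noiseless score and
#'   label matrices, anchored ids) and `spec`.
#' @export
simulate_problem <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed_out <- withr::with_seed(spec$seed, {
    # one-to-one anchors cannot exceed either drug layer
    n_anchor <- min(round(spec$overlap_fraction * spec$n2), spec$n1)
    drugs1 <- sprintf("DRUG%04d", seq_len(spec$n1))
    dis1 <- sprintf("DIS%04d", seq_len(spec$m1))
    tar2 <- sprintf("TAR%04d", seq_len(spec$m2))
    # domain-2 drug layer: n_anchor ids drawn from domain 1, rest are new
    anchored1 <- sort(sample(spec$n1, n_anchor))
    drugs2 <- c(drugs1[anchored1], sprintf("XDRUG%04d", seq_len(spec$n2 - n_anchor)))
    perm <- sample(spec$n2)
    drugs2 <- drugs2[perm]

    r <- spec$r_true
    u1 <- matrix(rexp(spec$n1 * r), spec$n1, r)
    v1 <- matrix(rexp(spec$m1 * r), spec$m1, r)
    v2 <- matrix(rexp(spec$m2 * r), spec$m2, r)
    u2 <- matrix(rexp(spec$n2 * r), spec$n2, r)
    # anchored drugs share factors (copied, then perturbed per domain)
    anchor_pos2 <- match(drugs1[anchored1], drugs2)
    u2[anchor_pos2, ] <- u1[anchored1, ]
    if (spec$perturb_sd > 0) {
      u2[anchor_pos2, ] <- pmax(
        u2[anchor_pos2, , drop = FALSE] +
          matrix(rnorm(length(anchor_pos2) * r, sd = spec$perturb_sd),
                 length(anchor_pos2), r),
        0
      )
    }

    s1 <- tcrossprod(u1, v1)
    s2 <- tcrossprod(u2, v2)
    x1 <- top_quantile_binarize(s1, spec$density1)
    x2 <- top_quantile_binarize(s2, spec$density2)
    truth_x1 <- x1
    truth_x2 <- x2
    if (spec$noise_flip_rate > 0) {
      flip1 <- matrix(runif(length(x1)) < spec$noise_flip_rate, nrow(x1))
      flip2 <- matrix(runif(length(x2)) < spec$noise_flip_rate, nrow(x2))
      x1 <- abs(x1 - flip1)
      x2 <- abs(x2 - flip2)
    }
    if (sum(x1) < spec$r_true || sum(x2) < spec$r_true) {
      abort("requested density leaves fewer interactions than the planted rank")
    }
    kern <- if (spec$similarity_kernel == "cosine") cosine_kernel else rbf_kernel
    corrupt <- function(f) {
      if (spec$similarity_noise_sd == 0) return(f)
      pmax(f + matrix(rnorm(length(f), sd = spec$similarity_noise_sd), nrow(f)), 0)
    }
    list(x1 = x1, x2 = x2, truth_x1 = truth_x1, truth_x2 = truth_x2,
         u1 = u1, v1 = v1, u2 = u2, v2 = v2, s1 = s1, s2 = s2,
         au1 = kern(corrupt(u1)), av1 = kern(corrupt(v1)),
         au2 = kern(corrupt(u2)), av2 = kern(corrupt(v2)),
         drugs1 = drugs1, dis1 = dis1, drugs2 = drugs2, tar2 = tar2,
         anchored_ids = drugs1[anchored1])
  })
  g <- with_seed_out
  dimnames(g$x1) <- list(g$drugs1, g$dis1)
  dimnames(g$x2) <- list(g$drugs2, g$tar2)
  xm1 <- structure(list(values = methods::as(methods::as(Matrix::Matrix(g$x1, sparse = TRUE), "generalMatrix"), "CsparseMatrix"),
                        domain = "drug_disease"), class = "interaction_matrix")
  xm2 <- structure(list(values = methods::as(methods::as(Matrix::Matrix(g$x2, sparse = TRUE), "generalMatrix"), "CsparseMatrix"),
                        domain = "drug_target"), class = "interaction_matrix")
  problem <- cross_domain_problem(
    xm1,
    similarity_matrix(g$au1, ids = g$drugs1),
    similarity_matrix(g$av1, ids = g$dis1),
    xm2,
    similarity_matrix(g$au2, ids = g$drugs2),
    similarity_matrix(g$av2, ids = g$tar2)
  )
  structure(list(
    problem = problem,
    truth = list(u1 = g$u1, v1 = g$v1, u2 = g$u2, v2 = g$v2,
                 scores1 = g$s1, scores2 = g$s2,
                 labels1 = g$truth_x1, labels2 = g$truth_x2,
                 anchored_ids = g$anchored_ids),
    spec = spec
  ), class = "synthetic_problem")
}

#' Write a synthetic problem in the standard file formats
#'
#' Emits the seven files the loaders consume: two edge lists, four similarity
#' matrices and the anchor map.
#'
#' @param sim A `synthetic_problem`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of file paths written.
#' @export
write_synthetic_problem <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_problem"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- sim$problem
  paths <- c(
    interactions_dd = file.path(dir, "drug_disease.tsv"),
    interactions_dt = file.path(dir, "drug_target.tsv"),
    sim_drug1 = file.path(dir, "sim_drug_domain1.tsv"),
    sim_disease = file.path(dir, "sim_disease.tsv"),
    sim_drug2 = file.path(dir, "sim_drug_domain2.tsv"),
    sim_target = file.path(dir, "sim_target.tsv"),
    anchors = file.path(dir, "anchors.tsv")
  )
  write_interactions(p$x1, paths[["interactions_dd"]])
  write_interactions(p$x2, paths[["interactions_dt"]])
  write_similarity(p$au1, paths[["sim_drug1"]])
  write_similarity(p$av1, paths[["sim_disease"]])
  write_similarity(p$au2, paths[["sim_drug2"]])
  write_similarity(p$av2, paths[["sim_target"]])
  write_anchor_map(p$anchors, paths[["anchors"]])
  invisible(paths)
}

#' Mask a held-out test set inside a problem
#'
#' Two masking designs for parameter-recovery experiments:
#' * `"pairs"` removes a random fraction of one domain's positives from the
#'   training matrix and samples an equal number of never-observed pairs as
#'   test negatives (the pair-prediction setting).
#' * `"cold_drugs"` zeroes *all* domain-1 interactions of `n_cold` randomly
#'   chosen anchored drugs, making them cold starts whose only route back to
#'   the data is the similarity graph and -- when the coupling is active --
#'   the anchor link to the other domain.  The test set is every pair
#'   involving a cold drug (its observed positives vs all its unknowns).
#'
#' @param problem A [cross_domain_problem()].
#' @param domain Domain to mask, 1 or 2 (`"cold_drugs"` masks the drug rows of
#'   the chosen domain).
#' @param fraction Fraction of positives held out in `"pairs"` mode.
#'   Default 0.2.
#' @param seed Integer seed.
#' @param mode `"pairs"` or `"cold_drugs"`.
#' @param n_cold Number of anchored drugs made cold in `"cold_drugs"` mode.
#'   Default 10.
#' @return List with `problem` (training copy), `test_positives`,
#'   `test_negatives`, `domain`, `mode` and (cold mode) `cold_rows`.
#' @export
mask_heldout <- function(problem, domain = 1L, fraction = 0.2, seed = 1L,
                         mode = c("pairs", "cold_drugs"), n_cold = 10L) {
  mode <- match.arg(mode)
  x <- if (domain == 1L) problem$x1 else problem$x2
  pos <- positive_pairs(x)
  if (mode == "pairs") {
    n_test <- max(1L, round(fraction * nrow(pos)))
    take <- withr::with_seed(derive_seed(seed, 7L), sample(nrow(pos), n_test))
    test_pos <- pos[take, ]
    neg <- sample_negatives(x, n_test, derive_seed(seed, 8L))
    train <- zero_interaction_copy(x, test_pos)
    return(list(problem = problem_with_train(problem, domain, train),
                test_positives = test_pos, test_negatives = neg,
                domain = domain, mode = mode))
  }
  anchored <- if (domain == 1L) problem$anchors$pairs$domain1_index
              else problem$anchors$pairs$domain2_index
  if (length(anchored) < n_cold) {
    abort(sprintf("only %d anchored drugs available; %d cold drugs requested",
                  length(anchored), n_cold))
  }
  cold <- withr::with_seed(derive_seed(seed, 7L), sort(sample(anchored, n_cold)))
  test_pos <- pos[pos$row %in% cold, ]
  all_pairs <- tidyr::expand_grid(row = cold, col = seq_len(ncol(x$values)))
  neg <- dplyr::anti_join(all_pairs, test_pos, by = c("row", "col"))
  train <- zero_interaction_copy(x, test_pos)
  list(problem = problem_with_train(problem, domain, train),
       test_positives = test_pos, test_negatives = neg,
       domain = domain, mode = mode, cold_rows = cold)
}

#' Held-out recovery metrics against the hidden truth
#'
#' Scores the masked test pairs with a fitted model (or any score matrix) and
#' computes AUROC/AUPR against the generator's noiseless labels.
#'
#' @param masked Output of [mask_heldout()].
#' @param sim The `synthetic_problem` the mask was built from.
#' @param scores Either a fitted `anchor_nmf` model or a dense score matrix
#'   for the masked domain.
#' @return Tibble with `auroc` and `aupr` on the held-out pairs.
#' @export
heldout_eval <- function(masked, sim, scores) {
  if (inherits(scores, "anchor_nmf")) scores <- predict(scores, masked$domain)
  labels_true <- sim$truth[[paste0("labels", masked$domain)]]
  pairs <- dplyr::bind_rows(masked$test_positives, masked$test_negatives)
  sc <- scores[cbind(pairs$row, pairs$col)]
  lb <- labels_true[cbind(pairs$row, pairs$col)] > 0
  tibble(auroc = auroc(sc, lb), aupr = aupr(sc, lb))
}

#' Paired transfer-benefit experiment
#'
#' For each seed: simulate a coupled problem, mask a held-out set in the
#' chosen domain, fit the model twice on identical data and initial factors --
#' once with the cross-network penalty active (`beta`) and once decoupled
#' (`beta = 0`) -- and compare held-out AUROC.  The paired differences measure
#' what anchoring the shared drugs transfers from the other domain.  The
#' default `"cold_drugs"` masking is where the coupling has work to do: a
#' cold anchored drug is invisible to the decoupled model except through its
#' (noisy) similarity row, while the coupled model can place it from the other
#' domain's evidence.
#'
#' @param spec A [synthetic_spec()]; each run reuses it with a different seed.
#' @param params An [anchor_nmf_params()]; `beta` is overridden per arm.
#' @param beta Coupling strength of the active arm.  Default 0.01.
#' @param n_seeds Number of paired runs.  Default 10.
#' @param domain Masked/evaluated domain.  Default 1.
#' @param fraction Held-out fraction (`"pairs"` mode).  Default 0.2.
#' @param mode,n_cold Passed to [mask_heldout()]; defaults `"cold_drugs"`, 10.
#' @param seed Base seed from which per-run seeds are derived.
#' @return Tibble with one row per run: `run_seed`, `auroc_coupled`,
#'   `auroc_decoupled`, `diff`, plus `aupr_*` columns.
#' @export
transfer_benefit <- function(spec, params, beta = 0.01, n_seeds = 10L,
                             domain = 1L, fraction = 0.2,
                             mode = c("cold_drugs", "pairs"), n_cold = 10L,
                             seed = 1L) {
  mode <- match.arg(mode)
  purrr::map_dfr(seq_len(n_seeds), function(i) {
    run_seed <- derive_seed(seed, i * 53L)
    sp <- spec
    sp$seed <- run_seed
    sim <- simulate_problem(sp)
    masked <- mask_heldout(sim$problem, domain, fraction, run_seed,
                           mode = mode, n_cold = n_cold)
    arms <- purrr::map(c(coupled = beta, decoupled = 0), function(b) {
      pp <- params
      pp$beta <- b
      pp$seed <- run_seed
      fit <- anchor_nmf(masked$problem, pp)
      heldout_eval(masked, sim, fit)
    })
    tibble(run_seed = run_seed,
           auroc_coupled = arms$coupled$auroc,
           auroc_decoupled = arms$decoupled$auroc,
           diff = arms$coupled$auroc - arms$decoupled$auroc,
           aupr_coupled = arms$coupled$aupr,
           aupr_decoupled = arms$decoupled$aupr)
  })
}
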