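# Evaluation protocol: five-fold cross-validation under three scenarios
# (pair prediction, cold-start new drug, cold-start new disease/target),
# balanced negative sampling, ranking metrics and hypergeometric enrichment.

positive_pairs <- function(x) {
  tm <- Matrix::summary(x$values)
  tibble(row = as.integer(tm$i), col = as.integer(tm$j))
}

zero_interaction_copy <- function(x, drop) {
  # returns an interaction_matrix equal to x with the pairs in `drop` removed
  m <- x$values
  m[cbind(drop$row, drop$col)] <- 0
  m <- Matrix::drop0(m)
  structure(list(values = m, domain = x$domain), class = "interaction_matrix")
}

#' Sample unknown pairs as negatives
#'
#' Uniformly samples `n` pairs with no observed interaction, for use as the
#' negative class of a balanced test set.
#'
#' @param x An `interaction_matrix`.
#' @param n Number of negatives to draw.
#' @param seed Integer seed.
#' @param exclude Optional tibble of `row`, `col` pairs additionally excluded
#'   from the sampling frame.
#' @return Tibble with `row`, `col` (1-based indices).
#' @export
sample_negatives <- function(x, n, seed, exclude = NULL) {
  m <- as.matrix(x$values) > 0
  if (!is.null(exclude)) m[cbind(exclude$row, exclude$col)] <- TRUE
  frame <- which(!m)  # linear indices of unknown pairs
  if (length(frame) < n) {
    abort(sprintf("only %d unknown pairs available; %d negatives requested",
                  length(frame), n))
  }
  idx <- withr::with_seed(seed, sample(frame, n))
  tibble(row = as.integer((idx - 1L) %% nrow(m)) + 1L,
         col = as.integer((idx - 1L) %/% nrow(m)) + 1L)
}

#' Five-fold cross-validation over interaction pairs
#'
#' Scenario 1 ("pair prediction"): the known interactions are partitioned into
#' `n_folds` folds.  For each fold, the held-out positives are zeroed in the
#' training matrix (they become unknowns with weight `w` during fitting) and an
#' equal number of never-observed pairs is sampled as test negatives.
#'
#' @param x An `interaction_matrix`.
#' @param n_folds Number of folds, default 5.
#' @param seed Integer seed controlling both the partition and the negative
#'   samples.
#' @return List of `n_folds` splits; each a list with `scenario`, `fold`,
#'   `train` (an `interaction_matrix`), `test_positives` and `test_negatives`
#'   (tibbles of `row`, `col`).
#' @export
cv_splits_pair <- function(x, n_folds = 5L, seed = 1L) {
  pos <- positive_pairs(x)
  if (nrow(pos) < n_folds) {
    abort(sprintf("%d positives cannot be split into %d folds", nrow(pos), n_folds))
  }
  fold_of <- withr::with_seed(derive_seed(seed, 0L), {
    sample(rep_len(seq_len(n_folds), nrow(pos)))
  })
  lapply(seq_len(n_folds), function(k) {
    test_pos <- pos[fold_of == k, ]
    neg <- sample_negatives(x, nrow(test_pos), derive_seed(seed, k))
    list(scenario = "pair", fold = k,
         train = zero_interaction_copy(x, test_pos),
         test_positives = test_pos, test_negatives = neg)
  })
}

#' Five-fold cold-start cross-validation over entities
#'
#' Scenarios 2 and 3: the entities along one axis (drugs for "new drug",
#' diseases/targets for "new disease"/"new target") are partitioned into
#' `n_folds` disjoint subsets.  All interactions of held-out entities form the
#' test positives and their rows (or columns) are fully zeroed in training, so
#' the held-out entities are genuine cold starts.
#'
#' @param x An `interaction_matrix`.
#' @param axis `"row"` (drugs) or `"col"` (diseases / targets).
#' @param n_folds Number of folds, default 5.
#' @param seed Integer seed.
#' @return List of splits as in [cv_splits_pair()], each additionally holding
#'   `held_out` (the held-out entity indices).
#' @export
cv_splits_entity <- function(x, axis = c("row", "col"), n_folds = 5L, seed = 1L) {
  axis <- match.arg(axis)
  n_ent <- if (axis == "row") nrow(x$values) else ncol(x$values)
  if (n_ent < n_folds) {
    abort(sprintf("%d entities cannot be split into %d folds", n_ent, n_folds))
  }
  fold_of <- withr::with_seed(derive_seed(seed, 0L), {
    sample(rep_len(seq_len(n_folds), n_ent))
  })
  pos <- positive_pairs(x)
  lapply(seq_len(n_folds), function(k) {
    held <- which(fold_of == k)
    in_test <- if (axis == "row") pos$row %in% held else pos$col %in% held
    test_pos <- pos[in_test, ]
    list(scenario = if (axis == "row") "new_row_entity" else "new_col_entity",
         axis = axis, fold = k, held_out = held,
         train = zero_interaction_copy(x, test_pos),
         test_positives = test_pos)
  })
}

#' Area under the ROC curve
#'
#' Rank-statistic AUROC (the normalized Mann-Whitney U): the probability that
#' a random positive outscores a random negative, with ties counting 1/2.
#'
#' @param score Numeric prediction scores.
#' @param label Logical or 0/1 class labels; both classes must be present.
#' @return Scalar in `[0, 1]`.
#' @export
auroc <- function(score, label) {
  label <- as.logical(label)
  np <- sum(label); nn <- sum(!label)
  if (np == 0L || nn == 0L) abort("both classes must be present to compute AUROC")
  r <- rank(score)  # midranks handle ties with the 1/2 convention
  (sum(r[label]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve
#'
#' Step-curve area computed by a descending-score sweep over distinct
#' thresholds (average-precision style; no trapezoidal interpolation, which
#' would inflate the area).  Tied scores enter the curve as a single block.
#'
#' @inheritParams auroc
#' @return Scalar in `(0, 1]`.
#' @export
aupr <- function(score, label) {
  label <- as.logical(label)
  np <- sum(label)
  if (np == 0L) abort("at least one positive is required to compute AUPR")
  thresholds <- sort(unique(score), decreasing = TRUE)
  tp_prev <- 0
  area <- 0
  n_taken <- 0
  for (th in thresholds) {
    in_block <- score == th
    n_taken <- n_taken + sum(in_block)
    tp <- tp_prev + sum(label[in_block])
    prec <- tp / n_taken
    area <- area + (tp - tp_prev) / np * prec
    tp_prev <- tp
  }
  area
}

#' Precision among the top-k ranked candidates
#'
#' Fraction of the `k` best-scoring candidates that are true associations.
#' Ties are broken by candidate identifier (stable, platform-independent).
#' If fewer than `k` candidates exist, precision is computed over the
#' available candidates with a warning.
#'
#' @param score Numeric scores of the candidates.
#' @param hit Logical (or 0/1): is the candidate a true association?
#' @param k Cutoff, `k >= 1`.
#' @param ids Candidate identifiers used for deterministic tie-breaks;
#'   defaults to position.
#' @return Scalar in `[0, 1]`.
#' @export
precision_at_k <- function(score, hit, k, ids = NULL) {
  stopifnot(k >= 1)
  hit <- as.logical(hit)
  if (is.null(ids)) ids <- seq_along(score)
  if (k > length(score)) {
    warn(sprintf("k = %d exceeds the %d available candidates; using all", k, length(score)))
    k <- length(score)
  }
  ord <- order(-score, ids)
  sum(hit[ord[seq_len(k)]]) / k
}

#' Points of the ROC and precision-recall curves
#'
#' Curve coordinates for plotting or export, using the same descending-score
#' sweep as [auroc()] and [aupr()].
#'
#' @inheritParams auroc
#' @return Tibble with `threshold`, `tpr`, `fpr`, `precision`, `recall`.
#' @export
curve_points <- function(score, label) {
  label <- as.logical(label)
  np <- sum(label); nn <- sum(!label)
  thresholds <- sort(unique(score), decreasing = TRUE)
  tp <- fp <- 0
  rows <- purrr::map_dfr(thresholds, function(th) {
    in_block <- score == th
    tp <<- tp + sum(label[in_block])
    fp <<- fp + sum(!label[in_block])
    tibble(threshold = th,
           tpr = tp / np, fpr = fp / max(nn, 1L),
           precision = tp / (tp + fp), recall = tp / np)
  })
  rows
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' P(X >= k) for a hypergeometric draw of `n` from a population of `N` with
#' `K` successes, evaluated in log space so that extreme tails (p-values far
#' below double underflow of intermediate terms) remain accurate.
#'
#' @param N Population size (all candidate pairs).
#' @param K Successes in the population (known interactions).
#' @param n Number of draws (pairs evaluated).
#' @param k Observed successes among the draws.
#' @return Tibble with `p_value` and `log10_p`.
#' @export
hyper_enrichment <- function(N, K, n, k) {
  if (!(k >= 0 && k <= n && n <= N && K <= N && K >= 0)) {
    abort("inconsistent counts: need 0 <= k <= n <= N and 0 <= K <= N")
  }
  if (k == 0) return(tibble(p_value = 1, log10_p = 0))
  log_p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  tibble(p_value = exp(log_p), log10_p = log_p / log(10))
}

# Replace one domain's interaction matrix inside a problem (training fold).
problem_with_train <- function(problem, domain, train_x) {
  if (domain == 1L) {
    cross_domain_problem(train_x, problem$au1, problem$av1,
                         problem$x2, problem$au2, problem$av2,
                         anchors = problem$anchors)
  } else {
    cross_domain_problem(problem$x1, problem$au1, problem$av1,
                         train_x, problem$au2, problem$av2,
                         anchors = problem$anchors)
  }
}

score_pairs <- function(scores, pairs) scores[cbind(pairs$row, pairs$col)]

fold_metrics_pair <- function(scores, split, ks) {
  sc <- c(score_pairs(scores, split$test_positives),
          score_pairs(scores, split$test_negatives))
  lb <- c(rep(TRUE, nrow(split$test_positives)), rep(FALSE, nrow(split$test_negatives)))
  out <- tibble(auroc = auroc(sc, lb), aupr = aupr(sc, lb))
  for (k in ks) out[[paste0("precision_at_", k)]] <- precision_at_k(sc, lb, min(k, length(sc)))
  out
}

fold_metrics_entity <- function(scores, split, x_full, ks) {
  x <- as.matrix(x_full$values) > 0
  by_row <- split$axis == "row"
  held <- split$held_out
  # pooled AUROC/AUPR over all pairs of held-out entities
  sc <- c(); lb <- c()
  per_entity_prec <- stats::setNames(rep(0, length(ks)), paste0("precision_at_", ks))
  n_scored <- 0L
  for (e in held) {
    s <- if (by_row) scores[e, ] else scores[, e]
    truth <- if (by_row) x[e, ] else x[, e]
    sc <- c(sc, s); lb <- c(lb, truth)
    if (any(truth)) {
      n_scored <- n_scored + 1L
      for (k in ks) {
        nm <- paste0("precision_at_", k)
        per_entity_prec[[nm]] <- per_entity_prec[[nm]] +
          precision_at_k(s, truth, min(k, length(s)), ids = names(s))
      }
    }
  }
  out <- tibble(auroc = auroc(sc, lb), aupr = aupr(sc, lb))
  for (nm in names(per_entity_prec)) {
    out[[nm]] <- if (n_scored > 0L) per_entity_prec[[nm]] / n_scored else NA_real_
  }
  out
}

#' Run a cross-validation experiment
#'
#' The full protocol for one scenario and one prediction domain: for each of
#' `n_repeats` independent repeats and each of `n_folds` folds, the evaluated
#' domain's training matrix is rebuilt with the fold's test interactions
#' removed, the *other* domain's network is kept whole (its knowledge is fully
#' incorporated), the coupled model is refitted and the held-out pairs are
#' scored.  Scenario `"pair"` reports AUROC/AUPR and precision\@k over the
#' balanced test set; the cold-start scenarios report pooled AUROC/AUPR over
#' all pairs of held-out entities and precision\@k averaged per held-out
#' entity.
#'
#' @param problem A [cross_domain_problem()].
#' @param params An [anchor_nmf_params()].
#' @param scenario `"pair"`, `"new_row_entity"` (new drug) or
#'   `"new_col_entity"` (new disease / new target).
#' @param domain Domain evaluated: 1 (drug-disease) or 2 (drug-target).
#' @param n_folds,n_repeats Protocol sizes; defaults 5 folds, 10 repeats.
#' @param ks Cutoffs for precision\@k.  Default `c(5, 10, 15)`.
#' @param seed Integer seed; repeats use seeds derived from it.
#' @return A tibble of class `cv_report` with one row per repeat x fold and
#'   columns `repeat_index`, `fold`, `auroc`, `aupr`, `precision_at_*`.
#'   `summary()` / [glance.cv_report()] average over repeats.
#' @export
run_cv_experiment <- function(problem, params, scenario = c("pair", "new_row_entity", "new_col_entity"),
                              domain = 1L, n_folds = 5L, n_repeats = 10L,
                              ks = c(5L, 10L, 15L), seed = 1L) {
  scenario <- match.arg(scenario)
  x_full <- if (domain == 1L) problem$x1 else problem$x2
  rows <- purrr::map_dfr(seq_len(n_repeats), function(rep_i) {
    rep_seed <- derive_seed(seed, rep_i * 131L)
    splits <- switch(scenario,
      pair = cv_splits_pair(x_full, n_folds, rep_seed),
      new_row_entity = cv_splits_entity(x_full, "row", n_folds, rep_seed),
      new_col_entity = cv_splits_entity(x_full, "col", n_folds, rep_seed)
    )
    purrr::map_dfr(splits, function(split) {
      p_train <- problem_with_train(problem, domain, split$train)
      fit_params <- params
      fit_params$seed <- derive_seed(rep_seed, split$fold)
      fit <- anchor_nmf(p_train, fit_params)
      scores <- predict(fit, domain)
      m <- if (scenario == "pair") fold_metrics_pair(scores, split, ks)
           else fold_metrics_entity(scores, split, x_full, ks)
      dplyr::bind_cols(tibble(repeat_index = rep_i, fold = split$fold), m)
    })
  })
  class(rows) <- c("cv_report", class(rows))
  attr(rows, "scenario") <- scenario
  attr(rows, "domain") <- domain
  rows
}

#' Mean metrics of a cross-validation report
#'
#' @param x A `cv_report` from [run_cv_experiment()].
#' @param ... Unused.
#' @return One-row tibble of metric means over all repeats and folds.
#' @export
glance.cv_report <- function(x, ...) {
  x |>
    dplyr::summarise(dplyr::across(-c("repeat_index", "fold"), mean))
}

#' Metric distributions across repeats
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return ggplot boxplot of per-fold metric values by metric.
#' @export
autoplot.cv_report <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -c("repeat_index", "fold"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "metric value",
                  title = sprintf("Cross-validation metrics (%s scenario)",
                                  attr(object, "scenario")))
}
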