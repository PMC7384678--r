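# Domain containers: bipartite interaction matrices, intra-layer similarity
# matrices, graph Laplacians, weight matrices and the anchor map that ties the
# drug layers of the two domains together.

#' Construct a bipartite interaction matrix
#'
#' Builds the sparse binary drug-by-disease (or drug-by-target) matrix that the
#' factorization consumes.  Rows are drugs, columns are the second entity layer
#' of the domain; entries are 1 for a known interaction and 0 otherwise.
#'
#' @param edges A data frame (or tibble) with at least two columns: row
#'   identifier and column identifier.  An optional third column holding 0/1
#'   values marks edges to keep (`1`) or drop (`0`); any other third column is
#'   ignored.  Repeated edges collapse to a single interaction.
#' @param domain One of `"drug_disease"` or `"drug_target"`.
#' @param row_ids,col_ids Optional character vectors fixing the identifier
#'   universe and order.  Defaults to first-appearance order in `edges`.
#' @return An object of class `interaction_matrix`: a list with `values` (a
#'   sparse 0/1 `Matrix` with identifier dimnames) and `domain`.
#' @examples
#' edges <- tibble::tibble(drug = c("d1", "d1", "d2"), disease = c("s1", "s2", "s1"))
#' x <- interaction_matrix(edges, "drug_disease")
#' dim(x$values)
#' @export
interaction_matrix <- function(edges, domain = c("drug_disease", "drug_target"),
                               row_ids = NULL, col_ids = NULL) {
  domain <- match.arg(domain)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L || nrow(edges) == 0L) {
    abort("`edges` must have at least two columns and one row.")
  }
  ri <- as.character(edges[[1L]])
  ci <- as.character(edges[[2L]])
  keep <- rep(TRUE, nrow(edges))
  if (ncol(edges) >= 3L) {
    v <- suppressWarnings(as.numeric(edges[[3L]]))
    if (!anyNA(v) && all(v %in% c(0, 1))) keep <- v == 1
  }
  ri <- ri[keep]; ci <- ci[keep]
  if (is.null(row_ids)) row_ids <- unique(ri)
  if (is.null(col_ids)) col_ids <- unique(ci)
  if (anyDuplicated(row_ids)) abort("duplicate row identifiers")
  if (anyDuplicated(col_ids)) abort("duplicate column identifiers")
  i <- match(ri, row_ids)
  j <- match(ci, col_ids)
  if (anyNA(i) || anyNA(j)) abort("edge refers to an identifier absent from the supplied id universe")
  values <- sparseMatrix(
    i = i, j = j, x = 1,
    dims = c(length(row_ids), length(col_ids)),
    dimnames = list(row_ids, col_ids)
  )
  values@x[] <- 1  # collapse duplicate edges to a single 1
  structure(list(values = values, domain = domain), class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf(
    "<interaction_matrix [%s]> %d x %d, %d interactions (density %.4f)\n",
    x$domain, nrow(x$values), ncol(x$values), length(x$values@x),
    length(x$values@x) / prod(dim(x$values))
  ))
  invisible(x)
}

#' @export
as_tibble.interaction_matrix <- function(x, ...) {
  tm <- Matrix::summary(x$values)
  tibble(
    row_id = rownames(x$values)[tm$i],
    col_id = colnames(x$values)[tm$j]
  )
}

#' Read a bipartite edge list
#'
#' Parses a plain-text edge list (one interaction per line,
#' `row_id<sep>col_id`, optional 0/1 value column) into an
#' [interaction_matrix()].  The separator (tab or comma) is autodetected from
#' the first line; header handling is explicit, never guessed.
#'
#' @param path File path.
#' @param domain Domain tag, see [interaction_matrix()].
#' @param header Does the first line hold column names?  Default `FALSE`.
#' @param sep Field separator; `NULL` (default) autodetects tab vs comma.
#' @return An `interaction_matrix`.
#' @export
read_interactions <- function(path, domain = c("drug_disease", "drug_target"),
                              header = FALSE, sep = NULL) {
  domain <- match.arg(domain)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(sprintf("empty edge-list file: %s", path))
  if (is.null(sep)) sep <- if (grepl("\t", lines[[1L]], fixed = TRUE)) "\t" else ","
  first_data <- if (header) 2L else 1L
  if (header && length(lines) < 2L) abort(sprintf("no data lines after header in %s", path))
  parts <- strsplit(lines, sep, fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 2L)
  bad <- bad[bad >= first_data]
  if (length(bad)) {
    abort(sprintf("malformed line %d in %s: expected at least 2 fields", bad[[1L]], path))
  }
  parts <- parts[seq(first_data, length(parts))]
  edges <- data.frame(
    row_id = trimws(vapply(parts, `[[`, "", 1L)),
    col_id = trimws(vapply(parts, `[[`, "", 2L)),
    stringsAsFactors = FALSE
  )
  if (any(nf[seq(first_data, length(nf))] >= 3L)) {
    edges$value <- trimws(vapply(parts, function(p) if (length(p) >= 3L) p[[3L]] else "1", ""))
  }
  interaction_matrix(edges, domain)
}

#' Write a bipartite edge list
#'
#' Inverse of [read_interactions()]: one `row_id<TAB>col_id` line per stored
#' interaction, in column-major order of the sparse matrix.
#'
#' @param x An `interaction_matrix`.
#' @param path Output file path.
#' @param sep Field separator, default tab.
#' @export
write_interactions <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "interaction_matrix"))
  edges <- as_tibble(x)
  writeLines(paste(edges$row_id, edges$col_id, sep = sep), path)
  invisible(path)
}

#' Construct an intra-layer similarity matrix
#'
#' Validates and symmetrizes a square non-negative similarity matrix (drug-drug,
#' disease-disease or target-target).  Asymmetry up to `1e-6` is silently
#' symmetrized as `(A + t(A)) / 2`; larger asymmetry is symmetrized with a
#' warning.  Negative or non-finite entries are rejected.  Disease semantic
#' similarities are unbounded non-negative scores and are used as provided;
#' `normalize = TRUE` optionally rescales by the maximum entry.
#'
#' @param values Square numeric matrix with identifier dimnames (or supply
#'   `ids`).
#' @param ids Optional identifier vector overriding dimnames.
#' @param normalize Divide by `max(values)` so the scale is bounded by 1.
#'   Default `FALSE`.
#' @return Object of class `similarity_matrix`: list with `values` (dense,
#'   symmetric) and `scale` (`"bounded_01"` or `"unbounded_nonneg"`).
#' @export
similarity_matrix <- function(values, ids = NULL, normalize = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) abort("similarity matrix must be square")
  if (any(!is.finite(values))) abort("similarity matrix contains non-finite entries")
  if (any(values < 0)) abort("similarity matrix contains negative entries")
  if (!is.null(ids)) {
    if (length(ids) != nrow(values)) abort("`ids` length must match matrix dimension")
    dimnames(values) <- list(ids, ids)
  }
  if (is.null(rownames(values))) abort("similarity matrix needs identifier dimnames or `ids`")
  if (anyDuplicated(rownames(values))) abort("duplicate identifiers in similarity matrix")
  asym <- max(abs(values - t(values)))
  if (asym > 1e-6) {
    warn(sprintf("similarity matrix asymmetric (max deviation %.3g); symmetrizing", asym))
  }
  values <- (values + t(values)) / 2
  if (normalize && max(values) > 0) values <- values / max(values)
  scale <- if (max(values) <= 1 + 1e-12) "bounded_01" else "unbounded_nonneg"
  if (scale == "unbounded_nonneg") {
    inform(sprintf("similarity scale is unbounded (max %.3g); using values as provided", max(values)))
  }
  structure(list(values = values, scale = scale), class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d x %d, scale: %s\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' Read a similarity matrix
#'
#' Reads a delimited square numeric matrix whose first row and first column
#' are entity identifiers.
#'
#' @param path File path.
#' @param sep Field separator; `NULL` autodetects tab vs comma.
#' @inheritParams similarity_matrix
#' @return A `similarity_matrix`.
#' @export
read_similarity <- function(path, sep = NULL, normalize = FALSE) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) abort(sprintf("empty similarity file: %s", path))
  if (is.null(sep)) sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) abort(sprintf("non-numeric entries in similarity file %s", path))
  similarity_matrix(m, normalize = normalize)
}

#' Write a similarity matrix
#'
#' @param x A `similarity_matrix`.
#' @param path Output path.
#' @param sep Field separator, default tab.
#' @export
write_similarity <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "similarity_matrix"))
  m <- x$values
  header <- paste(c("id", colnames(m)), collapse = sep)
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], format(m[i, ], digits = 17, trim = TRUE, scientific = FALSE)),
          collapse = sep)
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Degree matrix and graph Laplacian of a similarity matrix
#'
#' Computes the diagonal degree matrix `D` with `D[i,i] = sum_j A[i,j]` and the
#' combinatorial Laplacian `L = D - A` used by the smoothness penalty.  By
#' default the self-similarity diagonal contributes to the degrees; set
#' `include_diagonal = FALSE` to zero the diagonal first.
#'
#' @param a A `similarity_matrix` or plain symmetric non-negative matrix.
#' @param include_diagonal Keep the diagonal when computing degrees.  Default
#'   `TRUE`.
#' @return List of class `laplacian_pair` with dense `degree` and `laplacian`
#'   matrices and the `adjacency` actually used.
#' @export
laplacian_pair <- function(a, include_diagonal = TRUE) {
  m <- if (inherits(a, "similarity_matrix")) a$values else as.matrix(a)
  if (!include_diagonal) diag(m) <- 0
  d <- diag(base::rowSums(m), nrow = nrow(m))
  dimnames(d) <- dimnames(m)
  structure(list(adjacency = m, degree = d, laplacian = d - m),
            class = "laplacian_pair")
}

#' One-class confidence weights for an interaction matrix
#'
#' Observed interactions receive weight 1; unobserved pairs receive the reduced
#' confidence weight `w` in `[0, 1)`, reflecting that an absent edge is an
#' unlabeled pair, not a confirmed negative.
#'
#' @param x An `interaction_matrix` (or plain 0/1 matrix).
#' @param w Weight for unobserved entries, in `[0, 1)`.  Default 0.3.
#' @return Dense numeric matrix of the same shape with entries in `{1, w}`.
#' @export
weight_matrix <- function(x, w = 0.3) {
  if (!is.numeric(w) || length(w) != 1L || is.na(w) || w < 0 || w >= 1) {
    abort("`w` must be a single number in [0, 1)")
  }
  m <- if (inherits(x, "interaction_matrix")) as.matrix(x$values) else as.matrix(x)
  out <- matrix(w, nrow(m), ncol(m), dimnames = dimnames(m))
  out[m > 0] <- 1
  out
}

#' Anchor map between the drug layers of two domains
#'
#' Drugs present in both domains (matched by exact, case-sensitive identifier
#' equality) are anchor nodes; the map is one-to-one by construction.  The
#' matrix form is the sparse `n2 x n1` 0/1 mapping matrix with at most one 1
#' per row (and per column), which projects domain-1 drug factors onto the
#' domain-2 drug index.
#'
#' @param ids1 Domain-1 drug identifiers (duplicate-free).
#' @param ids2 Domain-2 drug identifiers (duplicate-free).
#' @return Object of class `anchor_map`: list with `pairs` (tibble of
#'   `domain2_id`, `domain1_id` and 1-based indices) and `matrix` (sparse
#'   `n2 x n1`).
#' @export
anchor_map <- function(ids1, ids2) {
  ids1 <- as.character(ids1); ids2 <- as.character(ids2)
  if (anyDuplicated(ids1)) abort("duplicate identifiers in `ids1`")
  if (anyDuplicated(ids2)) abort("duplicate identifiers in `ids2`")
  shared <- intersect(ids2, ids1)
  i2 <- match(shared, ids2)
  i1 <- match(shared, ids1)
  s <- sparseMatrix(i = i2, j = i1, x = rep(1, length(shared)),
                    dims = c(length(ids2), length(ids1)),
                    dimnames = list(ids2, ids1))
  pairs <- tibble(domain2_id = shared, domain1_id = shared,
                  domain2_index = i2, domain1_index = i1)
  structure(list(pairs = pairs, matrix = s), class = "anchor_map")
}

#' @export
print.anchor_map <- function(x, ...) {
  cat(sprintf("<anchor_map> %d anchors between %d domain-2 and %d domain-1 drugs\n",
              nrow(x$pairs), nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Write / read an anchor map as a two-column id file
#'
#' @param x An `anchor_map`.
#' @param path Output path.
#' @param sep Separator, default tab.
#' @export
write_anchor_map <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "anchor_map"))
  writeLines(paste(x$pairs$domain2_id, x$pairs$domain1_id, sep = sep), path)
  invisible(path)
}

#' Assemble a coupled two-domain problem
#'
#' Bundles the drug-disease domain (interaction matrix plus drug and disease
#' similarities), the drug-target domain (interaction matrix plus drug and
#' target similarities) and the anchor map linking shared drugs.  Laplacian
#' pairs and dimension checks are derived here once so the optimizer can trust
#' its inputs.
#'
#' @param x1,x2 `interaction_matrix` objects for domain 1 (drug-disease) and
#'   domain 2 (drug-target).
#' @param au1,av1 `similarity_matrix` objects over the rows (drugs) and
#'   columns (diseases) of `x1`.
#' @param au2,av2 `similarity_matrix` objects over the rows (drugs) and
#'   columns (targets) of `x2`.
#' @param anchors Optional `anchor_map`; defaults to the identifier
#'   intersection of the two drug layers.
#' @param include_diagonal Passed to [laplacian_pair()].
#' @return Object of class `cross_domain_problem`.
#' @export
cross_domain_problem <- function(x1, au1, av1, x2, au2, av2, anchors = NULL,
                                 include_diagonal = TRUE) {
  stopifnot(inherits(x1, "interaction_matrix"), inherits(x2, "interaction_matrix"))
  doms <- list(
    list(x = x1, au = au1, av = av1, tag = "domain1"),
    list(x = x2, au = au2, av = av2, tag = "domain2")
  )
  for (d in doms) {
    stopifnot(inherits(d$au, "similarity_matrix"), inherits(d$av, "similarity_matrix"))
    if (!identical(rownames(d$au$values), rownames(d$x$values))) {
      abort(sprintf("%s: drug similarity ids do not match interaction row ids", d$tag))
    }
    if (!identical(rownames(d$av$values), colnames(d$x$values))) {
      abort(sprintf("%s: column-entity similarity ids do not match interaction column ids", d$tag))
    }
  }
  if (is.null(anchors)) {
    anchors <- anchor_map(rownames(x1$values), rownames(x2$values))
  }
  stopifnot(inherits(anchors, "anchor_map"))
  if (!identical(dim(anchors$matrix), c(nrow(x2$values), nrow(x1$values)))) {
    abort("anchor map shape does not match the two drug layers")
  }
  structure(list(
    x1 = x1, x2 = x2,
    au1 = au1, av1 = av1, au2 = au2, av2 = av2,
    lu1 = laplacian_pair(au1, include_diagonal),
    lv1 = laplacian_pair(av1, include_diagonal),
    lu2 = laplacian_pair(au2, include_diagonal),
    lv2 = laplacian_pair(av2, include_diagonal),
    anchors = anchors
  ), class = "cross_domain_problem")
}

#' @export
print.cross_domain_problem <- function(x, ...) {
  cat("<cross_domain_problem>\n")
  cat(sprintf("  domain 1 (%s): %d drugs x %d entities, %d interactions\n",
              x$x1$domain, nrow(x$x1$values), ncol(x$x1$values), length(x$x1$values@x)))
  cat(sprintf("  domain 2 (%s): %d drugs x %d entities, %d interactions\n",
              x$x2$domain, nrow(x$x2$values), ncol(x$x2$values), length(x$x2$values@x)))
  cat(sprintf("  anchors: %d shared drugs\n", nrow(x$anchors$pairs)))
  invisible(x)
}
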