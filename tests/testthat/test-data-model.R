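# Containers and file I/O: interaction matrices, similarities, Laplacians,
# weights and the anchor map.

test_that("interaction matrices are built from edge lists with idempotent edges", {
  edges <- data.frame(d = c("d1", "d1", "d2"), t = c("t1", "t2", "t1"))
  x <- interaction_matrix(edges, "drug_target")
  expect_identical(dim(x$values), c(2L, 2L))
  expect_equal(sum(x$values), 3)
  expect_identical(rownames(x$values), c("d1", "d2"))
  expect_identical(colnames(x$values), c("t1", "t2"))

  dup <- interaction_matrix(data.frame(d = c("d1", "d1"), t = c("t1", "t1")), "drug_target")
  expect_equal(as.numeric(dup$values[1, 1]), 1)
  expect_equal(sum(dup$values), 1)

  # third 0/1 column filters edges
  val <- interaction_matrix(
    data.frame(d = c("d1", "d2"), t = c("t1", "t1"), v = c(1, 0)),
    "drug_target", row_ids = c("d1", "d2"), col_ids = "t1"
  )
  expect_equal(sum(val$values), 1)
})

test_that("edge-list reading handles separators, headers and malformed input", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("d1\tt1", "d1\tt2", "d2\tt1"), tmp)
  x <- read_interactions(tmp, "drug_target")
  expect_equal(sum(x$values), 3)

  # comma dialect autodetected
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("d1,t1", "d2,t2"), tmp2)
  expect_equal(sum(read_interactions(tmp2, "drug_target")$values), 2)

  # explicit header flag: first line skipped, 3 data lines -> 3 edges
  tmp3 <- withr::local_tempfile()
  writeLines(c("drug\tdisease", "d1\ts1", "d1\ts2", "d2\ts1"), tmp3)
  xh <- read_interactions(tmp3, "drug_disease", header = TRUE)
  expect_equal(sum(xh$values), 3)
  expect_false("drug" %in% rownames(xh$values))

  tmp4 <- withr::local_tempfile()
  writeLines(c("d1\tt1", "oops"), tmp4)
  expect_error(read_interactions(tmp4, "drug_target"), "line 2")

  tmp5 <- withr::local_tempfile()
  writeLines(character(), tmp5)
  expect_error(read_interactions(tmp5, "drug_target"), "empty")
})

test_that("interaction matrices round-trip through files exactly", {
  sim <- random_problem(seed = 4)
  x <- sim$problem$x1
  tmp <- withr::local_tempfile()
  write_interactions(x, tmp)
  x2 <- read_interactions(tmp, x$domain)
  # ids present in edges round-trip in first-appearance order; matrices agree
  common_r <- rownames(x2$values)
  common_c <- colnames(x2$values)
  expect_true(all(as.matrix(x$values[common_r, common_c]) == as.matrix(x2$values)))
})

test_that("similarity matrices are validated and symmetrized on load", {
  a <- matrix(c(1, 0.4, 0.4, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  s <- similarity_matrix(a)
  expect_equal(s$values, a)
  expect_identical(s$scale, "bounded_01")

  asym <- matrix(c(1, 0.2, 0.4, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_warning(s2 <- similarity_matrix(asym), "asymmetric")
  expect_equal(s2$values[1, 2], 0.3)
  expect_equal(s2$values[2, 1], 0.3)

  neg <- matrix(c(1, -0.1, -0.1, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(similarity_matrix(neg), "negative")
  nan <- matrix(c(1, NaN, 0.1, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(similarity_matrix(nan), "non-finite")
  expect_error(similarity_matrix(matrix(1, 2, 3)), "square")

  # unbounded scales pass through as provided (with a note), optional max-normalization
  ub <- matrix(c(5, 2, 2, 8), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_message(su <- similarity_matrix(ub), "unbounded")
  expect_equal(max(su$values), 8)
  sn <- suppressMessages(similarity_matrix(ub, normalize = TRUE))
  expect_equal(max(sn$values), 1)
})

test_that("similarity files round-trip bit-exactly", {
  sim <- random_problem(seed = 9)
  s <- sim$problem$au1
  tmp <- withr::local_tempfile()
  write_similarity(s, tmp)
  s2 <- read_similarity(tmp)
  expect_identical(rownames(s2$values), rownames(s$values))
  expect_equal(s2$values, s$values, tolerance = 0)
})

test_that("Laplacian pairs match hand computation and are PSD with zero row sums", {
  a <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  lp <- laplacian_pair(a)
  expect_equal(unname(lp$degree), diag(c(1, 1)))
  expect_equal(unname(lp$laplacian), matrix(c(1, -1, -1, 1), 2))

  a2 <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(unname(laplacian_pair(a2)$laplacian), matrix(c(2, -2, -2, 2), 2))

  z <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(unname(laplacian_pair(z)$laplacian), matrix(0, 2, 2))

  # properties on a generated similarity matrix
  sim <- random_problem(n1 = 10, seed = 2)
  for (s in list(sim$problem$au1, sim$problem$av1)) {
    lp <- laplacian_pair(s)
    expect_lt(max(abs(base::rowSums(lp$laplacian))), 1e-8)
    expect_gt(min(eigen(lp$laplacian, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }

  # diagonal handling is switchable
  d <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(diag(laplacian_pair(d, include_diagonal = TRUE)$degree), c(1.5, 1.5),
               ignore_attr = TRUE)
  expect_equal(diag(laplacian_pair(d, include_diagonal = FALSE)$degree), c(0.5, 0.5),
               ignore_attr = TRUE)
})

test_that("weight matrices assign 1 to observed and w to unobserved entries", {
  x <- interaction_matrix(data.frame(d = "d1", t = "t1"),
                          "drug_target", row_ids = c("d1", "d2"), col_ids = c("t1", "t2"))
  w <- weight_matrix(x, 0.3)
  expect_equal(w[1, 1], 1)
  expect_equal(w[2, 2], 0.3)
  expect_setequal(unique(as.vector(w)), c(1, 0.3))

  w0 <- weight_matrix(x, 0)
  expect_equal(w0, (as.matrix(x$values) > 0) * 1, ignore_attr = TRUE)

  expect_error(weight_matrix(x, 1), "\\[0, 1\\)")
  expect_error(weight_matrix(x, -0.1), "\\[0, 1\\)")
})

test_that("anchor maps are the exact id intersection and one-to-one", {
  am <- anchor_map(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(nrow(am$pairs), 2)
  expect_setequal(am$pairs$domain1_id, c("b", "c"))

  empty <- anchor_map(c("a", "b"), c("x", "y"))
  expect_equal(nrow(empty$pairs), 0)
  expect_equal(sum(empty$matrix), 0)

  full <- anchor_map(c("a", "b", "c"), c("c", "a", "b"))
  expect_equal(nrow(full$pairs), 3)
  expect_true(all(Matrix::rowSums(full$matrix) == 1))

  # one-to-one: S^T S diagonal with entries in {0, 1}
  for (am_i in list(am, empty, full)) {
    sts <- as.matrix(Matrix::crossprod(am_i$matrix))
    expect_true(all(sts[row(sts) != col(sts)] == 0))
    expect_true(all(diag(sts) %in% c(0, 1)))
    expect_true(all(Matrix::rowSums(am_i$matrix) <= 1))
  }

  expect_error(anchor_map(c("a", "a"), "b"), "duplicate")
})

test_that("anchor maps round-trip through two-column files", {
  am <- anchor_map(c("a", "b", "c"), c("b", "c", "d"))
  tmp <- withr::local_tempfile()
  write_anchor_map(am, tmp)
  txt <- readLines(tmp)
  expect_equal(length(txt), 2)
  expect_true(all(grepl("\t", txt)))
})

test_that("cross-domain problems validate id alignment", {
  sim <- random_problem(seed = 3)
  p <- sim$problem
  expect_s3_class(p, "cross_domain_problem")
  # mismatched similarity ids are rejected
  bad <- similarity_matrix(diag(3), ids = c("z1", "z2", "z3"))
  expect_error(
    cross_domain_problem(p$x1, bad, p$av1, p$x2, p$au2, p$av2),
    "do not match"
  )
})
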