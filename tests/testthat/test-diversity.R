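mock_bank <- function(n_bcts = 4, per_bct = 5, seed = 21) {
  make_synthetic_bank(synthetic_bank_spec(n_bcts = n_bcts,
                                          messages_per_bct = per_bct,
                                          seed = seed))
}

test_that("embed_bank is deterministic and honors the backend contract", {
  bank <- mock_bank(3, 4)
  be <- mock_embedding_backend(dim = 16, seed = 1)
  E1 <- embed_bank(bank, be)
  E2 <- embed_bank(bank, be)
  expect_equal(dim(E1$vectors), c(12L, 16L))
  expect_identical(E1$vectors, E2$vectors)
  expect_identical(E1$ids$bct_number, tibble::as_tibble(bank)$bct_number)
  # unit-norm backends return points on the unit sphere
  Eu <- embed_bank(bank, mock_embedding_backend(dim = 24, seed = 2,
                                                unit_norm = TRUE))
  expect_true(all(abs(sqrt(rowSums(Eu$vectors^2)) - 1) < 1e-6))
  # a lying backend is caught
  liar <- embedding_backend("liar", 8,
                            function(texts) matrix(2, length(texts), 8),
                            unit_norm = TRUE)
  expect_error(embed_bank(bank, liar), class = "bctmsg_backend_error")
})

test_that("centering subtracts the dataset mean exactly", {
  bank <- mock_bank(2, 3)
  E <- embed_bank(bank, mock_embedding_backend(dim = 8, seed = 3))
  R <- center_embeddings(E)
  n <- nrow(R$vectors)
  expect_lt(max(abs(colSums(R$vectors))), 1e-8 * n)
  expect_equal(R$vectors, sweep(E$vectors, 2, colMeans(E$vectors)))
  # single row centers to zero, mean is the row
  E1 <- embed_bank(tiny_bank("solo message"),
                   mock_embedding_backend(dim = 6))
  R1 <- center_embeddings(E1)
  expect_equal(unname(R1$vectors[1, ]), rep(0, 6))
  expect_equal(unname(R1$source_mean), unname(E1$vectors[1, ]))
  # antipodal rows have zero mean and are unchanged
  Ev <- structure(list(ids = tibble::tibble(bct_number = c("1.1", "1.2"),
                                            message_index = c(1L, 1L)),
                       vectors = rbind(c(1, -2, 3), c(-1, 2, -3)),
                       backend_name = "manual", dim = 3L, unit_norm = FALSE),
                  class = "embedding_matrix")
  Rv <- center_embeddings(Ev)
  expect_equal(Rv$vectors, Ev$vectors)
})

test_that("bct_relevance equals a naive double-loop oracle", {
  bankA <- mock_bank(4, 5, seed = 31)
  bankB <- mock_bank(4, 4, seed = 32)
  Ra <- center_embeddings(embed_bank(bankA, mock_embedding_backend(dim = 12)))
  Rb <- center_embeddings(embed_bank(bankB, mock_embedding_backend(dim = 12)))
  M <- bct_relevance(Ra, Rb)
  for (i in seq_along(M$row_bcts)) {
    for (j in seq_along(M$col_bcts)) {
      ma <- colMeans(Ra$vectors[Ra$ids$bct_number == M$row_bcts[i], ,
                                drop = FALSE])
      mb <- colMeans(Rb$vectors[Rb$ids$bct_number == M$col_bcts[j], ,
                                drop = FALSE])
      expect_equal(M$values[i, j], sum(ma * mb))
    }
  }
})

test_that("relevance of hand-set vectors matches hand arithmetic", {
  mk <- function(bcts, vecs) {
    structure(list(ids = tibble::tibble(bct_number = bcts,
                                        message_index = seq_along(bcts)),
                   vectors = vecs, source_mean = rep(0, ncol(vecs)),
                   backend_name = "manual"),
              class = "centered_representation")
  }
  R1 <- mk(c("1.1", "1.1", "1.2", "1.2"),
           rbind(c(1, 0), c(3, 0), c(0, 2), c(0, 4)))
  R2 <- mk(c("1.1", "1.2"), rbind(c(1, 1), c(-1, 1)))
  M <- bct_relevance(R1, R2)
  # means: b1.1 = (2,0), b1.2 = (0,3); inner products by hand
  expect_equal(M$values, rbind(c(2, -2), c(3, 3)))
  # diagonal of a self-comparison is a squared norm
  Mself <- bct_relevance(R1, R1)
  expect_equal(diag(Mself$values), c(4, 9))
  # orthogonal per-BCT means give off-diagonal zeros
  expect_equal(Mself$values[1, 2], 0)
  # invariant to message order within groups
  R1shuf <- mk(c("1.2", "1.1", "1.2", "1.1"),
               rbind(c(0, 4), c(3, 0), c(0, 2), c(1, 0)))
  expect_equal(bct_relevance(R1shuf, R2)$values, M$values)
})

test_that("relevance errors on empty groups", {
  bank <- mock_bank(2, 2)
  R <- center_embeddings(embed_bank(bank, mock_embedding_backend(dim = 4)))
  expect_error(bct_relevance(R, R, groups1 = list(`9.9` = integer())),
               "9.9", class = "bctmsg_grouping_error")
})

test_that("top-k accuracy ranks rows with deterministic tie-breaks", {
  M <- structure(list(row_bcts = c("1.1", "1.2", "2.1", "10.1"),
                      col_bcts = c("1.1", "1.2", "2.1", "10.1"),
                      values = rbind(c(9, 1, 1, 1),   # hit at k=1
                                     c(2, 8, 1, 1),   # hit at k=1
                                     c(5, 4, 3, 1),   # miss until k=3
                                     c(7, 6, 5, 4))), # miss until k=4
                 class = "relevance_matrix")
  expect_equal(topk_alignment_accuracy(M, 1), 0.5)
  expect_equal(topk_alignment_accuracy(M, 3), 0.75)
  expect_equal(topk_alignment_accuracy(M, 4), 1.0)
  accs <- vapply(1:4, function(k) topk_alignment_accuracy(M, k), numeric(1))
  expect_true(all(diff(accs) >= 0))
  # ties break by ascending taxonomy number
  Mtie <- structure(list(row_bcts = c("1.1", "10.1"),
                         col_bcts = c("1.1", "10.1"),
                         values = rbind(c(1, 1), c(1, 1))),
                    class = "relevance_matrix")
  expect_equal(topk_alignment_accuracy(Mtie, 1), 0.5) # only "1.1" wins its tie
  expect_error(topk_alignment_accuracy(M, 5), class = "bctmsg_argument_error")
  expect_error(topk_alignment_accuracy(M, 0), class = "bctmsg_argument_error")
})

test_that("multilabel expansion duplicates messages per code", {
  bank <- tibble::tibble(
    message_id = 1:3,
    text = c("msg one", "msg two", "msg three"),
    bct_codes = list(c("1.1", "1.2"), "1.1", "2.3")
  )
  out <- expand_multilabel(bank)
  expect_equal(nrow(out), 4L)
  expect_equal(sum(out$text == "msg one"), 2L)
  expect_identical(sort(unique(out$bct_number)), c("1.1", "1.2", "2.3"))
  # all-single-coded input is an identity on rows
  single <- tibble::tibble(text = c("a", "b"), bct_codes = list("1.1", "1.2"))
  expect_equal(nrow(expand_multilabel(single)), 2L)
  bad <- tibble::tibble(text = "x", bct_codes = list(character()))
  expect_error(expand_multilabel(bad), class = "bctmsg_validation_error")
})

test_that("match_distribution equalizes per-technique counts", {
  bankA <- mock_bank(5, 6, seed = 41)
  # bankB: fewer messages, only 3 overlapping techniques plus one foreign
  tblB <- tibble::as_tibble(mock_bank(3, 2, seed = 42))
  tblB$bct_number[1] <- "99.1"
  bankB <- message_bank(tblB)
  m <- match_distribution(bankA, bankB)
  ta <- table(tibble::as_tibble(m$a)$bct_number)
  tb <- table(tibble::as_tibble(m$b)$bct_number)
  expect_identical(ta, tb)
  expect_false("99.1" %in% names(ta))
  # min rule: A has 6 per technique, B has at most 2
  expect_true(all(ta <= 2))
  # identical banks pass through unchanged
  same <- match_distribution(bankA, bankA)
  expect_equal(nrow(same$a), nrow(bankA))
  expect_identical(tibble::as_tibble(same$a)$text,
                   tibble::as_tibble(bankA)$text)
  # random strategy is seeded and reproducible
  r1 <- match_distribution(bankA, bankB, strategy = "random", seed = 7)
  r2 <- match_distribution(bankA, bankB, strategy = "random", seed = 7)
  expect_identical(tibble::as_tibble(r1$a), tibble::as_tibble(r2$a))
  expect_error(match_distribution(bankA, message_bank(tibble::tibble(
    bct_number = "77.7", bct_label = "x", message_index = 1L, text = "t"))),
    class = "bctmsg_comparison_error")
})

test_that("PCA projection matches an eigen-decomposition oracle", {
  X <- rbind(c(1, 2, 0.5), c(2, 1, 0.2), c(4, 5, 0.9))
  got <- pca_project(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ed <- eigen(crossprod(Xc) / (nrow(X) - 1))
  expected <- Xc %*% ed$vectors[, 1:2]
  for (j in 1:2) { # apply the same sign convention as the implementation
    v <- ed$vectors[, j]
    if (sign(v[which.max(abs(v))]) < 0) expected[, j] <- -expected[, j]
  }
  expect_equal(unname(got), unname(expected), tolerance = 1e-8)
  # centroid projects to the origin
  expect_equal(unname(colMeans(got)), c(0, 0))
  # collinear points have a null second axis
  line <- outer(1:5, c(1, 2, 3))
  expect_lt(max(abs(pca_project(line)[, 2])), 1e-8)
  expect_error(pca_project(line[1, , drop = FALSE]),
               class = "bctmsg_argument_error")
})

test_that("t-SNE is seeded, 2-D, and separates well-separated clusters", {
  n <- 40
  centers <- rbind(rep(0, 8), rep(6, 8))
  X <- withr::with_seed(13, {
    rbind(matrix(rnorm(n * 8), n, 8) + rep(centers[1, ], each = n),
          matrix(rnorm(n * 8), n, 8) + rep(centers[2, ], each = n))
  })
  a <- tsne_project(X, seed = 5, perplexity = 10)
  b <- tsne_project(X, seed = 5, perplexity = 10)
  expect_identical(a, b)
  expect_equal(dim(a), c(2L * n, 2L))
  labels <- rep(c(1, 2), each = n)
  # nearest-centroid separability in the 2-D embedding
  c1 <- colMeans(a[labels == 1, ]); c2 <- colMeans(a[labels == 2, ])
  d1 <- rowSums(sweep(a, 2, c1)^2); d2 <- rowSums(sweep(a, 2, c2)^2)
  acc <- mean((d1 < d2) == (labels == 1))
  expect_gt(acc, 0.95)
  expect_error(tsne_project(X[1:10, ], perplexity = 10),
               class = "bctmsg_argument_error")
})

test_that("relevance matrices serialize with technique labels", {
  bank <- mock_bank(3, 3)
  R <- center_embeddings(embed_bank(bank, mock_embedding_backend(dim = 6)))
  M <- bct_relevance(R, R)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_relevance_matrix(M, csv)
  tbl <- readr::read_csv(csv, col_types = readr::cols(
    bct = readr::col_character(), .default = readr::col_double()))
  expect_identical(tbl$bct, M$row_bcts)
  expect_identical(names(tbl)[-1], M$col_bcts)
  expect_equal(as.matrix(tbl[, -1]), M$values, ignore_attr = TRUE)
  expect_s3_class(plot_relevance_heatmap(M), "ggplot")
})
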