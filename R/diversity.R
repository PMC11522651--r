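#' Embedding matrices and backends
#'
#' An embedding matrix holds one numeric row per message (`ids` keeps the
#' `(bct_number, message_index)` keys in bank order) plus backend metadata.
#' An embedding backend is a list with `name`, `dim`, `unit_norm` and
#' `embed`, a `function(texts)` returning an `n x dim` numeric matrix. The
#' packaged [mock_embedding_backend()] derives each row deterministically
#' from a stable hash of the text, so every downstream operation is testable
#' offline; live BERT-style (768-d) or ADA-style (1536-d, unit-norm) backends
#' satisfy the same contract.
#'
#' @name embeddings
NULL

new_embedding_matrix <- function(ids, vectors, backend_name, unit_norm) {
  stopifnot(is.matrix(vectors), nrow(vectors) == nrow(ids))
  structure(list(ids = ids, vectors = vectors, backend_name = backend_name,
                 dim = ncol(vectors), unit_norm = isTRUE(unit_norm)),
            class = "embedding_matrix")
}

#' @param name backend identifier.
#' @param dim embedding dimension.
#' @param unit_norm whether rows are scaled to unit Euclidean norm (ADA-style
#'   backends return points on the unit sphere of the latent space).
#' @param embed `function(texts) -> n x dim matrix`.
#' @rdname embeddings
#' @export
embedding_backend <- function(name, dim, embed, unit_norm = FALSE) {
  stopifnot(is_string(name), is.function(embed), dim >= 1)
  structure(list(name = name, dim = as.integer(dim), unit_norm = unit_norm,
                 embed = embed),
            class = "embedding_backend")
}

#' @param seed integer seed mixed into the per-text hash.
#' @rdname embeddings
#' @export
mock_embedding_backend <- function(dim = 32L, seed = 1L, unit_norm = FALSE) {
  dim <- as.integer(dim)
  embedding_backend(
    name = sprintf("mock-%dd%s", dim, if (unit_norm) "-unit" else ""),
    dim = dim, unit_norm = unit_norm,
    embed = function(texts) {
      out <- matrix(0, nrow = length(texts), ncol = dim)
      for (i in seq_along(texts)) {
        stream <- lehmer_stream(sprintf("emb|%d|%s", seed, texts[[i]]))
        v <- stream_norm(stream, dim)
        if (unit_norm) v <- v / sqrt(sum(v^2))
        out[i, ] <- v
      }
      out
    }
  )
}

#' Embed every message of a bank
#'
#' @param bank a [message_bank()] (non-empty).
#' @param backend an [embedding_backend()].
#' @return An `embedding_matrix` with one row per message, in bank order.
#' @export
embed_bank <- function(bank, backend = mock_embedding_backend()) {
  tbl <- tibble::as_tibble(bank)
  if (!nrow(tbl)) {
    abort("embed_bank() requires a non-empty bank", class = "bctmsg_argument_error")
  }
  vectors <- backend$embed(tbl$text)
  if (!is.matrix(vectors) || nrow(vectors) != nrow(tbl) ||
      ncol(vectors) != backend$dim) {
    abort(sprintf("Backend '%s' returned a %s matrix, expected %d x %d",
                  backend$name, paste(dim(vectors), collapse = " x "),
                  nrow(tbl), backend$dim),
          class = "bctmsg_backend_error")
  }
  if (backend$unit_norm) {
    norms <- sqrt(rowSums(vectors^2))
    if (any(abs(norms - 1) > 1e-6)) {
      abort(sprintf("Backend '%s' declares unit_norm but returned rows with norm != 1",
                    backend$name),
            class = "bctmsg_backend_error")
    }
  }
  new_embedding_matrix(
    ids = tibble::tibble(bct_number = tbl$bct_number,
                         message_index = tbl$message_index),
    vectors = vectors, backend_name = backend$name,
    unit_norm = backend$unit_norm
  )
}

#' Center embeddings to per-dataset representations
#'
#' The representation of a message is its embedding minus the mean embedding
#' of its own data set: `r(x) = emb(x) - (1/|X|) * sum over X of emb(x')`.
#' Subtracting the data-set mean removes the signal shared by all messages
#' (the common objective they were written for) and keeps what is specific to
#' each message — its semantic structure and its technique. Each data set is
#' centered by its own mean, never a pooled one.
#'
#' @param E an `embedding_matrix` (n >= 1).
#' @return A `centered_representation`: list with `ids`, `vectors` (column
#'   sums zero to numerical precision) and `source_mean` (the subtracted
#'   mean vector).
#' @export
center_embeddings <- function(E) {
  stopifnot(inherits(E, "embedding_matrix"))
  mu <- colMeans(E$vectors)
  structure(list(ids = E$ids,
                 vectors = sweep(E$vectors, 2, mu),
                 source_mean = mu,
                 backend_name = E$backend_name),
            class = "centered_representation")
}

group_means <- function(R, groups = NULL) {
  if (is.null(groups)) {
    groups <- split(seq_len(nrow(R$ids)), R$ids$bct_number)
  }
  empty <- names(groups)[lengths(groups) == 0L]
  if (length(empty)) {
    abort(paste0("BCT group(s) with zero messages: ",
                 paste(empty, collapse = ", ")),
          class = "bctmsg_grouping_error")
  }
  bad <- unlist(groups)[unlist(groups) > nrow(R$vectors) | unlist(groups) < 1]
  if (length(bad)) {
    abort("Grouping refers to rows outside the representation",
          class = "bctmsg_grouping_error")
  }
  means <- t(vapply(groups, function(idx) {
    colMeans(R$vectors[idx, , drop = FALSE])
  }, numeric(ncol(R$vectors))))
  means[bct_number_order(rownames(means)), , drop = FALSE]
}

#' Cross-dataset BCT relevance matrix
#'
#' For each technique in each data set, the centered representations of its
#' messages are averaged; relevance between technique `b1` of data set 1 and
#' `b2` of data set 2 is the inner product of those per-technique means.
#' Rows index data-set-1 techniques, columns data-set-2 techniques.
#'
#' @param R1,R2 `centered_representation`s of the two data sets.
#' @param groups1,groups2 optional named lists mapping BCT number to row
#'   indices; by default groups are derived from each representation's ids.
#' @return A `relevance_matrix`: list with `row_bcts`, `col_bcts` (ordered by
#'   taxonomy number) and `values`.
#' @export
bct_relevance <- function(R1, R2, groups1 = NULL, groups2 = NULL) {
  m1 <- group_means(R1, groups1)
  m2 <- group_means(R2, groups2)
  values <- m1 %*% t(m2)
  structure(list(row_bcts = rownames(m1), col_bcts = rownames(m2),
                 values = unname(values)),
            class = "relevance_matrix")
}

#' Top-k BCT alignment accuracy
#'
#' Fraction of data-set-1 techniques whose matching technique in data set 2
#' ranks among the `k` largest entries of its relevance row (descending by
#' value; ties broken by ascending taxonomy number). Requires the two BCT
#' sets to be identical.
#'
#' @param M a `relevance_matrix` from [bct_relevance()].
#' @param k positive integer, at most the number of column techniques.
#' @return Accuracy in `[0, 1]`.
#' @export
topk_alignment_accuracy <- function(M, k) {
  stopifnot(inherits(M, "relevance_matrix"))
  if (!setequal(M$row_bcts, M$col_bcts)) {
    abort("Row and column BCT sets differ; alignment accuracy is undefined",
          class = "bctmsg_argument_error")
  }
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > length(M$col_bcts)) {
    abort(sprintf("k must be in 1..%d", length(M$col_bcts)),
          class = "bctmsg_argument_error")
  }
  col_rank_key <- seq_along(M$col_bcts)[bct_number_order(M$col_bcts)]
  # tie_rank[j]: position of column j in ascending-BCT-number order
  tie_rank <- match(seq_along(M$col_bcts), col_rank_key)
  hits <- vapply(seq_along(M$row_bcts), function(i) {
    ord <- order(-M$values[i, ], tie_rank)
    target <- which(M$col_bcts == M$row_bcts[i])
    match(target, ord) <= k
  }, logical(1))
  mean(hits)
}

#' Expand multi-BCT-coded messages to single-technique copies
#'
#' Comparison banks may code one message for several techniques. To align
#' with the single-technique-per-message convention, each message with `m`
#' codes is duplicated into `m` single-code messages.
#'
#' @param bank a tibble/data frame with a `text` column and a `bct_codes`
#'   list-column (each element a non-empty character vector of BCT numbers);
#'   an optional `bct_label` column is carried through.
#' @return A [message_bank()] of single-coded messages; `message_index`
#'   numbers messages within each technique in input order.
#' @export
expand_multilabel <- function(bank) {
  tbl <- tibble::as_tibble(bank)
  if (!"bct_codes" %in% names(tbl)) {
    abort("expand_multilabel() requires a 'bct_codes' list-column",
          class = "bctmsg_argument_error")
  }
  zero <- which(lengths(tbl$bct_codes) == 0L)
  if (length(zero)) {
    abort(sprintf("Message(s) with zero BCT codes at row(s): %s",
                  paste(zero, collapse = ", ")),
          class = "bctmsg_validation_error")
  }
  labels <- if ("bct_label" %in% names(tbl)) tbl$bct_label else
    rep(NA_character_, nrow(tbl))
  out <- tibble::tibble(
    bct_number = unlist(tbl$bct_codes),
    bct_label = rep(labels, lengths(tbl$bct_codes)),
    text = rep(tbl$text, lengths(tbl$bct_codes))
  )
  out <- dplyr::group_by(out, .data$bct_number)
  out <- dplyr::mutate(out, message_index = dplyr::row_number())
  out <- dplyr::ungroup(out)
  message_bank(out[c("bct_number", "bct_label", "message_index", "text")],
               provenance = list(expanded_from = nrow(tbl),
                                 expanded_to = nrow(out)))
}

#' Match per-technique message counts across two banks
#'
#' Restricts both banks to the techniques present in both; for each shared
#' technique keeps `min(count_A, count_B)` messages from each bank, either
#' the first in stored order (`"first_n"`, the reproducible default) or a
#' seeded random subset (`"random"`). The two outputs have identical
#' per-technique counts and technique sets.
#'
#' @param bankA,bankB [message_bank()]s.
#' @param strategy `"first_n"` or `"random"`.
#' @param seed seed for the `"random"` strategy.
#' @return A list with elements `a` and `b`, the two matched banks.
#' @export
match_distribution <- function(bankA, bankB, strategy = c("first_n", "random"),
                               seed = 1L) {
  strategy <- match.arg(strategy)
  ta <- tibble::as_tibble(bankA)
  tb <- tibble::as_tibble(bankB)
  shared <- intersect(unique(ta$bct_number), unique(tb$bct_number))
  if (!length(shared)) {
    abort("The two banks share no BCTs; nothing to compare",
          class = "bctmsg_comparison_error")
  }
  shared <- shared[bct_number_order(shared)]
  take <- function(tbl, bct, n) {
    idx <- which(tbl$bct_number == bct)
    sel <- if (strategy == "first_n") idx[seq_len(n)] else {
      sort(with_local_seed(seed + str_hash(bct) %% 10000L,
                           sample(idx, n)))
    }
    tbl[sel, , drop = FALSE]
  }
  outa <- list(); outb <- list()
  for (bct in shared) {
    n <- min(sum(ta$bct_number == bct), sum(tb$bct_number == bct))
    outa[[bct]] <- take(ta, bct, n)
    outb[[bct]] <- take(tb, bct, n)
  }
  list(a = message_bank(dplyr::bind_rows(outa),
                        provenance = c(attr(bankA, "provenance") %||% list(),
                                       list(matched = TRUE))),
       b = message_bank(dplyr::bind_rows(outb),
                        provenance = c(attr(bankB, "provenance") %||% list(),
                                       list(matched = TRUE))))
}

#' PCA projection onto the top two principal axes
#'
#' Projects mean-centered vectors onto their first two principal components
#' (via singular value decomposition). Sign convention for determinism: each
#' axis is oriented so that its largest-magnitude loading is positive.
#'
#' @param E an `embedding_matrix`, `centered_representation`, or numeric
#'   matrix with at least two rows.
#' @return An `n x 2` matrix of coordinates (columns `PC1`, `PC2`).
#' @export
pca_project <- function(E) {
  X <- if (inherits(E, "embedding_matrix") ||
           inherits(E, "centered_representation")) E$vectors else as.matrix(E)
  if (nrow(X) < 2) {
    abort("PCA projection requires at least 2 points",
          class = "bctmsg_argument_error")
  }
  p <- prcomp(X, center = TRUE, scale. = FALSE, rank. = 2)
  rot <- p$rotation
  scores <- p$x
  if (ncol(scores) < 2) { # rank-deficient inputs: pad a zero second axis
    scores <- cbind(scores, 0)
    rot <- cbind(rot, 0)
  }
  for (j in 1:2) {
    flip <- sign(rot[which.max(abs(rot[, j])), j])
    if (flip < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- c("PC1", "PC2")
  scores[, 1:2, drop = FALSE]
}

#' t-SNE projection
#'
#' Seeded nonlinear 2-D embedding, appropriate for unit-sphere embeddings
#' where a linear projector discards the curvature of the latent space. The
#' same seed reproduces the same coordinates within one environment
#' (library-version-dependent, as recorded in run metadata).
#'
#' @param E an `embedding_matrix`, `centered_representation`, or numeric
#'   matrix; requires `n > 3 * perplexity`.
#' @param seed integer seed.
#' @param perplexity t-SNE perplexity (default 30).
#' @param ... passed to [Rtsne::Rtsne()].
#' @return An `n x 2` matrix of coordinates (columns `TSNE1`, `TSNE2`).
#' @export
tsne_project <- function(E, seed = 1L, perplexity = 30, ...) {
  X <- if (inherits(E, "embedding_matrix") ||
           inherits(E, "centered_representation")) E$vectors else as.matrix(E)
  if (nrow(X) <= 3 * perplexity) {
    abort(sprintf("perplexity %.1f too large for n = %d (need n > 3*perplexity)",
                  perplexity, nrow(X)),
          class = "bctmsg_argument_error")
  }
  fit <- with_local_seed(seed, Rtsne::Rtsne(
    X, dims = 2, perplexity = perplexity, pca = FALSE,
    check_duplicates = FALSE, verbose = FALSE, ...
  ))
  coords <- fit$Y
  colnames(coords) <- c("TSNE1", "TSNE2")
  coords
}

#' Write a relevance matrix as labelled CSV
#'
#' @param M a `relevance_matrix`.
#' @param path output CSV path (first column `bct`, one column per
#'   data-set-2 technique).
#' @return `path`, invisibly.
#' @export
write_relevance_matrix <- function(M, path) {
  tbl <- tibble::as_tibble(as.data.frame(M$values))
  names(tbl) <- M$col_bcts
  tbl <- dplyr::bind_cols(tibble::tibble(bct = M$row_bcts), tbl)
  readr::write_csv(tbl, path)
  invisible(path)
}

#' Heatmap of a relevance matrix
#'
#' @param M a `relevance_matrix`.
#' @return A ggplot tile plot (rows/columns in taxonomy order).
#' @export
plot_relevance_heatmap <- function(M) {
  df <- expand.grid(row = M$row_bcts, col = M$col_bcts,
                    stringsAsFactors = FALSE)
  df$value <- as.vector(M$values)
  df$row <- factor(df$row, levels = rev(M$row_bcts))
  df$col <- factor(df$col, levels = M$col_bcts)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Comparison data set BCT", y = "Generated data set BCT",
                  fill = "Relevance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
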