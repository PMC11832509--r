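#' Cosine similarity matrix of item embeddings
#'
#' Computes the pairwise cosine similarity of item embedding vectors. The
#' result is the Gram matrix of the row-normalized embeddings: symmetric,
#' unit diagonal, entries in \[-1, 1\], and positive semidefinite, which is
#' what lets it stand in for a correlation matrix in downstream CFA.
#' Negative similarities are retained (a CFA handles negative correlations).
#'
#' @param E Numeric matrix, one embedding vector per row, rows named by
#'   item id (rows aligned to the item set order).
#' @return Symmetric numeric matrix with unit diagonal and the same row
#'   names on both axes.
#' @examples
#' E <- rbind(a = c(1, 0), b = c(1, 1), c = c(0, 1))
#' cosine_similarity_matrix(E)
#' @export
cosine_similarity_matrix <- function(E) {
  if (!is.matrix(E) || !is.numeric(E)) abort("E must be a numeric matrix")
  norms <- sqrt(rowSums(E^2))
  zero <- which(norms == 0)
  if (length(zero) > 0) {
    ids <- if (!is.null(rownames(E))) rownames(E)[zero] else as.character(zero)
    abort(paste0(
      "zero-norm embedding row(s): ", paste(ids, collapse = ", "),
      " (cosine similarity undefined)"
    ))
  }
  U <- E / norms
  S <- tcrossprod(U)
  S <- (S + t(S)) / 2
  S[S > 1] <- 1
  S[S < -1] <- -1
  diag(S) <- 1
  dimnames(S) <- list(rownames(E), rownames(E))
  S
}

#' Embed item texts through a provider function
#'
#' The provider contract keeps real embedding models (network, weights)
#' outside the package: any function mapping a character vector of item
#' texts to a numeric matrix (one fixed-length row per text) can be used,
#' from a deterministic mock up to a sentence-transformer wrapper.
#'
#' @param items A `sembed_items` tibble.
#' @param provider Function `function(texts) -> numeric matrix` with one row
#'   per text; all rows must have the same length.
#' @return Numeric embedding matrix, rows named by item id in canonical
#'   order.
#' @export
embed_items <- function(items, provider) {
  stopifnot(inherits(items, "sembed_items"), is.function(provider))
  E <- tryCatch(provider(items$text), error = function(e) {
    abort(paste0("embedding provider failed (items ",
                 paste(head(items$item_id, 3), collapse = ", "),
                 " ...): ", conditionMessage(e)))
  })
  E <- as.matrix(E)
  if (!is.numeric(E) || nrow(E) != nrow(items)) {
    abort("provider must return a numeric matrix with one row per item")
  }
  rownames(E) <- items$item_id
  E
}

#' Screen items for cross-scale similarity
#'
#' For every item, compares its mean similarity to the other items of its
#' own scale against its mean similarity to each foreign scale. An item is
#' flagged when some foreign scale is at least as similar as its own — the
#' descriptive jingle-jangle check performed on the similarity matrix before
#' any model fitting.
#'
#' @param S Symmetric similarity matrix with item-id dimnames.
#' @param items A `sembed_items` tibble; every scale needs at least two
#'   items. Ties between foreign scales are broken by canonical scale order.
#' @return A tibble with one row per item: `item_id`, `scale_id`,
#'   `own_scale_mean`, `best_other_scale`, `best_other_mean`, `flagged`.
#' @export
cross_loading_screen <- function(S, items) {
  stopifnot(inherits(items, "sembed_items"))
  check_square(S, "similarity matrix")
  check_axis_ids(rownames(S), colnames(S), items)
  S <- sub_matrix(S, items$item_id)
  sc <- scales(items)
  if (length(sc) < 2) abort("cross-loading screen needs at least 2 scales")
  sizes <- table(items$scale_id)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    abort(paste0(
      "own-scale mean undefined for single-item scale(s): ",
      paste(small, collapse = ", ")
    ))
  }
  by_scale <- lapply(sc, function(s) items$item_id[items$scale_id == s])
  names(by_scale) <- sc
  rows <- purrr::map(seq_len(nrow(items)), function(i) {
    id <- items$item_id[i]
    own <- items$scale_id[i]
    own_mean <- mean(S[id, setdiff(by_scale[[own]], id)])
    others <- setdiff(sc, own)
    other_means <- vapply(others, function(s) mean(S[id, by_scale[[s]]]), numeric(1))
    best <- which.max(other_means) # first max wins: canonical scale order
    tibble::tibble(
      item_id = id, scale_id = own,
      own_scale_mean = own_mean,
      best_other_scale = others[best],
      best_other_mean = unname(other_means[best]),
      flagged = unname(other_means[best]) >= own_mean
    )
  })
  dplyr::bind_rows(rows)
}
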