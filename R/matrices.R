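#' Read a square item-by-item matrix
#'
#' Reads a comma-delimited numeric square matrix whose first column and
#' header row hold item ids, checks it against an item set, symmetrizes
#' numerically negligible asymmetry, and reorders rows/columns to the
#' canonical item order.
#'
#' @param path Path to the CSV file. First column must be named `item_id`.
#' @param items A `sembed_items` tibble defining the canonical axis.
#' @param tol Maximum tolerated absolute asymmetry before erroring
#'   (default `1e-8`); smaller asymmetries are averaged out.
#' @return A symmetric numeric matrix with `dimnames` equal to the item ids
#'   in canonical order.
#' @export
read_matrix <- function(path, items, tol = 1e-8) {
  if (!file.exists(path)) abort(paste0("matrix file not found: ", path))
  raw <- readr::read_csv(path, progress = FALSE, show_col_types = FALSE)
  if (names(raw)[1] != "item_id") {
    abort("matrix file must have a first column named 'item_id'")
  }
  ids <- as.character(raw$item_id)
  M <- as.matrix(raw[-1])
  if (!is.numeric(M)) abort("matrix file contains non-numeric cells")
  rownames(M) <- ids
  check_axis_ids(ids, colnames(M), items)
  M <- M[items$item_id, items$item_id, drop = FALSE]
  asym <- max(abs(M - t(M)))
  if (asym > tol) {
    abort(sprintf("matrix asymmetry %.3g exceeds tolerance %.3g", asym, tol))
  }
  (M + t(M)) / 2
}

check_axis_ids <- function(row_ids, col_ids, items) {
  p <- nrow(items)
  if (length(row_ids) != p || length(col_ids) != p) {
    abort(sprintf(
      "matrix dimension (%d x %d) does not match item set size %d",
      length(row_ids), length(col_ids), p
    ))
  }
  if (!setequal(row_ids, items$item_id) || !setequal(col_ids, items$item_id)) {
    abort("matrix axis ids do not match the item set")
  }
  if (!identical(row_ids[order(row_ids)], col_ids[order(col_ids)])) {
    abort("matrix row and column ids differ")
  }
  invisible(TRUE)
}

#' Write a square matrix with item-id axes
#'
#' Full p x p values are written (not a triangle) so files are
#' self-describing; [read_matrix()] restores them within 1e-12.
#'
#' @param M Symmetric numeric matrix with item-id dimnames.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(M, path) {
  stopifnot(is.matrix(M), !is.null(rownames(M)))
  df <- tibble::as_tibble(M)
  df <- dplyr::bind_cols(tibble::tibble(item_id = rownames(M)), df)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

# shared validation for matrices used as pseudo-correlation input
check_square <- function(M, what = "matrix", sym_tol = 1e-10) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) {
    abort(paste0(what, " must be a square matrix"))
  }
  if (max(abs(M - t(M))) > sym_tol) {
    abort(paste0(what, " must be symmetric"))
  }
  invisible(TRUE)
}

# subset a named square matrix by item ids, keeping order
sub_matrix <- function(S, ids) {
  S[ids, ids, drop = FALSE]
}

lower_tri_values <- function(M) M[lower.tri(M)]
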