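#' Build an item set from a data frame
#'
#' An item set is the canonical axis for every matrix in the screening
#' pipeline: the i-th row/column of an embedding, similarity or correlation
#' matrix always refers to the i-th item of the item set. Items are grouped
#' into scales (one scale = one intended latent factor); scale order is
#' first-appearance order.
#'
#' @param data A data frame with columns `item_id`, `scale_id` and `text`.
#'   Additional columns are dropped. Item text is kept verbatim apart from
#'   Unicode NFC normalization.
#' @return A tibble of class `sembed_items` with columns `item_id`,
#'   `scale_id`, `text` and `position` (1-based canonical position), carrying
#'   the scale order in attribute `scales`.
#' @examples
#' items <- item_set(data.frame(
#'   item_id = c("q1", "q2", "q3", "q4"),
#'   scale_id = c("hope", "hope", "zest", "zest"),
#'   text = c("I expect the best", "My future looks bright",
#'            "I feel full of energy", "I approach life with excitement")
#' ))
#' scales(items)
#' @export
item_set <- function(data) {
  required <- c("item_id", "scale_id", "text")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "item table is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  items <- tibble::as_tibble(data[required])
  items$item_id <- as.character(items$item_id)
  items$scale_id <- as.character(items$scale_id)
  items$text <- enc2utf8(as.character(items$text))
  # NFC so that byte-identical ids/texts compare equal across sources
  items$text <- stringi_nfc(items$text)
  dup <- unique(items$item_id[duplicated(items$item_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicated item_id: ", paste(dup, collapse = ", ")))
  }
  if (any(is.na(items$item_id) | items$item_id == "")) {
    abort("item_id must be non-empty")
  }
  items$position <- seq_len(nrow(items))
  structure(
    items,
    scales = unique(items$scale_id),
    class = c("sembed_items", class(tibble::tibble()))
  )
}

# base-R NFC (avoids a stringi dependency); iconv keeps already-NFC ASCII intact
stringi_nfc <- function(x) {
  out <- iconv(x, from = "UTF-8", to = "UTF-8")
  ifelse(is.na(out), x, out)
}

#' Read an item table from a delimited file
#'
#' The file must be comma-delimited UTF-8 with a header containing at least
#' `item_id`, `scale_id` and `text`; item texts may be quoted fields.
#'
#' @param path Path to the CSV file.
#' @return A `sembed_items` tibble (see [item_set()]).
#' @export
read_items <- function(path) {
  if (!file.exists(path)) abort(paste0("item file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  item_set(raw)
}

#' Write an item table
#'
#' @param items A `sembed_items` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_items <- function(items, path) {
  stopifnot(inherits(items, "sembed_items"))
  readr::write_csv(items[c("item_id", "scale_id", "text")], path, progress = FALSE)
  invisible(path)
}

#' Scale ids of an item set, in canonical (first-appearance) order
#' @param items A `sembed_items` tibble.
#' @return Character vector of scale ids.
#' @export
scales <- function(items) {
  attr(items, "scales") %||% unique(items$scale_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sembed_items <- function(x, ...) {
  cat(sprintf("<item set: %d items, %d scales>\n", nrow(x), length(scales(x))))
  NextMethod()
}

# item ids belonging to one scale, canonical order
scale_items <- function(items, scale_id) {
  items$item_id[items$scale_id == scale_id]
}
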