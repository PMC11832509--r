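#' Run the full pre-data screening pipeline
#'
#' Wires the end-to-end workflow: read items, obtain the similarity matrix
#' (from an embedding file or precomputed), run the cross-loading screen,
#' the per-scale unidimensionality screen and (optionally) the wrong-model
#' battery, and render the text report. Every produced file is listed in a
#' manifest with its MD5 content hash together with the effective
#' configuration, so a rerun with identical inputs is verifiably
#' identical.
#'
#' @param config A named list or a path to a YAML file with fields:
#'   `items` (path, required), one of `embeddings` (CSV: `item_id` column +
#'   numeric columns) or `similarity` (matrix CSV), `outdir` (required),
#'   `n_pseudo` (default 10000), `cutoffs` (list `incremental`, `absolute`;
#'   defaults 0.90 / 0.08), `mi_method` (`"score"`/`"refit"`), `run_battery`
#'   (default `TRUE`), `seed` (default 1, recorded; the screening itself is
#'   deterministic).
#' @return The manifest as a list (also written to `manifest.json`),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- resolve_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  produced <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  items <- stage("items", read_items(cfg$items))
  S <- stage("similarity", {
    if (!is.null(cfg$embeddings)) {
      E <- read_embeddings(cfg$embeddings, items)
      cosine_similarity_matrix(E)
    } else {
      read_matrix(cfg$similarity, items)
    }
  })
  sim_path <- file.path(cfg$outdir, "similarity.csv")
  write_matrix(S, sim_path)
  produced <- c(produced, sim_path)

  cl <- stage("crossload", cross_loading_screen(S, items))
  cl_path <- file.path(cfg$outdir, "crossload.csv")
  write_report(cl, cl_path, "csv")
  produced <- c(produced, cl_path)

  cutoffs <- c(incremental = cfg$cutoffs$incremental, absolute = cfg$cutoffs$absolute)
  screen <- stage("screen", suppressWarnings(
    unidimensional_screen(S, items, n_pseudo = cfg$n_pseudo,
                          cutoffs = cutoffs, mi_method = cfg$mi_method)
  ))
  screen_path <- file.path(cfg$outdir, "screen.json")
  write_report(screen, screen_path, "json")
  produced <- c(produced, screen_path)

  if (isTRUE(cfg$run_battery) && length(scales(items)) >= 2) {
    battery <- stage("battery", suppressWarnings(
      wrong_model_battery(S, items, n_pseudo = cfg$n_pseudo, cutoffs = cutoffs)
    ))
    battery_path <- file.path(cfg$outdir, "battery.json")
    write_report(battery, battery_path, "json")
    produced <- c(produced, battery_path)
  }

  report <- stage("report", screen_report(screen, items))
  report_path <- file.path(cfg$outdir, "report.txt")
  write_report(report, report_path, "text")
  produced <- c(produced, report_path)

  manifest <- list(
    config = cfg[setdiff(names(cfg), "outdir_abs")],
    files = lapply(produced, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  manifest_path <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a list or a YAML path")
  defaults <- list(
    n_pseudo = 10000,
    cutoffs = list(incremental = 0.90, absolute = 0.08),
    mi_method = "score",
    run_battery = TRUE,
    seed = 1
  )
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$items)) abort("config is missing 'items'")
  if (is.null(cfg$outdir)) abort("config is missing 'outdir'")
  if (is.null(cfg$embeddings) && is.null(cfg$similarity)) {
    abort("config needs 'embeddings' or 'similarity'")
  }
  if (cfg$n_pseudo < 2) abort("n_pseudo must be at least 2")
  if (!(cfg$cutoffs$incremental > 0 && cfg$cutoffs$incremental < 1)) {
    abort("cutoffs$incremental must be in (0, 1)")
  }
  if (!(cfg$cutoffs$absolute > 0)) abort("cutoffs$absolute must be positive")
  cfg
}

#' Read an embedding matrix aligned to an item set
#'
#' @param path CSV with an `item_id` column and one numeric column per
#'   embedding dimension.
#' @param items A `sembed_items` tibble.
#' @return Numeric matrix, one row per item in canonical order.
#' @export
read_embeddings <- function(path, items) {
  if (!file.exists(path)) abort(paste0("embedding file not found: ", path))
  raw <- readr::read_csv(path, progress = FALSE, show_col_types = FALSE)
  if (names(raw)[1] != "item_id") abort("embedding file must start with an item_id column")
  ids <- as.character(raw$item_id)
  if (!setequal(ids, items$item_id) || length(ids) != nrow(items)) {
    abort("embedding file ids do not match the item set")
  }
  E <- as.matrix(raw[-1])
  if (!is.numeric(E)) abort("embedding file contains non-numeric cells")
  rownames(E) <- ids
  E[items$item_id, , drop = FALSE]
}

#' Write an embedding matrix
#' @param E Numeric matrix with item-id rownames.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(E, path) {
  df <- dplyr::bind_cols(tibble::tibble(item_id = rownames(E)),
                         tibble::as_tibble(E, .name_repair = "unique_quiet"))
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Write all artifacts of a simulated instrument
#'
#' Emits `items.csv`, `population_R.csv`, `sample_R.csv` and
#' `pseudo_sim.csv` in the package's file formats, so every pipeline stage
#' can be exercised from files alone.
#'
#' @param sim A `sembed_instrument`.
#' @param outdir Output directory (created if needed).
#' @param n Sample size for the response draw.
#' @param target_agreement Fidelity of the pseudo-similarity matrix.
#' @param seed Integer seed for the sampling and noise stages.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, outdir, n = 1000, target_agreement = 0.67,
                             seed = 1) {
  stopifnot(inherits(sim, "sembed_instrument"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    items = file.path(outdir, "items.csv"),
    population_R = file.path(outdir, "population_R.csv"),
    sample_R = file.path(outdir, "sample_R.csv"),
    pseudo_sim = file.path(outdir, "pseudo_sim.csv")
  )
  write_items(sim$items, paths["items"])
  write_matrix(sim$population_R, paths["population_R"])
  resp <- sample_responses(sim, n = n, seed = seed)
  write_matrix(resp$sample_R, paths["sample_R"])
  ps <- pseudo_similarity(sim$population_R, target_agreement, seed = seed)
  write_matrix(ps$matrix, paths["pseudo_sim"])
  invisible(paths)
}
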