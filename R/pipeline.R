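# End-to-end pipeline: design -> CATS ranking -> scaffold statistics ->
# target prediction, with a reproducibility manifest. Configuration is plain
# `key: value` text (or an R list); all randomness flows from the single
# `seed` key.

#' Read a key:value configuration file
#'
#' Lines of `key: value`; `#` comments and blank lines ignored. Values are
#' returned as strings; numeric coercion happens at use.
#'
#' @param path config file path
#' @return named list
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read config: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z0-9_.]+)\\s*:\\s*(.*?)\\s*$",
                                  lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) abort(paste0("malformed config line: ", lines[bad][[1]]))
  stats::setNames(lapply(kv, `[[`, 3L), vapply(kv, `[[`, "", 2L))
}

.cfg_get <- function(cfg, key, default = NULL) {
  v <- cfg[[key]]
  if (is.null(v)) return(default)
  v
}
.cfg_num <- function(cfg, key, default) {
  as.numeric(.cfg_get(cfg, key, default))
}

#' Run the full design-and-analysis pipeline
#'
#' Stages: load inputs, breadth-first design, CATS-ranked selection,
#' scaffold statistics, cascaded-SOM target prediction for the top designs.
#' Writes `candidates.csv`, `routes.json`, `scaffolds.csv`,
#' `predictions.csv` and `manifest.json` into `out_dir`. The manifest
#' records the configuration, stage counts, per-file md5 sums and a combined
#' run hash; reruns of an identical configuration produce an identical run
#' hash.
#'
#' @param config named list or path to a `key: value` config file. Keys:
#'   `template` (structure string or file with one structure), `blocks`
#'   (library file), `schemes` (registry file; default bundled), `refs`
#'   (reference library file; omit to skip target prediction), `n_start`,
#'   `max_steps`, `beam_width`, `seed`, `top_k`, `distance_cutoff`, `grid`
#'   (`WxH`), `epochs`, `n_background`, `p_max`, `n_predict`
#' @param out_dir output directory (created if needed)
#' @return invisibly, the manifest list
#' @export
pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config) && length(config) == 1L)
    read_config(config) else config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  tpl_raw <- .cfg_get(cfg, "template") %||%
    abort("config needs a 'template' key")
  template <- if (file.exists(tpl_raw))
    parse_structure(trimws(readLines(tpl_raw, warn = FALSE)[[1]]))
  else parse_structure(tpl_raw)
  blocks_path <- .cfg_get(cfg, "blocks") %||% abort("config needs 'blocks'")
  blocks <- read_library(blocks_path)
  schemes <- load_scheme_registry(.cfg_get(cfg, "schemes",
                                           default_scheme_registry()))
  seed <- as.integer(.cfg_num(cfg, "seed", 7))

  dcfg <- design_config(
    template, blocks, schemes,
    n_start = as.integer(.cfg_num(cfg, "n_start", 200)),
    max_steps = as.integer(.cfg_num(cfg, "max_steps", 3)),
    beam_width = .cfg_num(cfg, "beam_width", 50),
    seed = seed)
  designs <- run_design(dcfg)
  cutoff <- .cfg_get(cfg, "distance_cutoff")
  top <- select_top(designs, k = as.integer(.cfg_num(cfg, "top_k", 100)),
                    distance_cutoff = if (is.null(cutoff)) NULL
                    else as.numeric(cutoff))

  # outputs
  cand_path <- file.path(out_dir, "candidates.csv")
  utils::write.csv(
    dplyr::select(as_tibble(designs), "rank", "canonical_key", "fitness",
                  "cats_distance", "n_steps"),
    cand_path, row.names = FALSE)
  routes_path <- file.path(out_dir, "routes.json")
  jsonlite::write_json(
    lapply(seq_len(nrow(designs)), function(i) list(
      canonical_key = designs$canonical_key[[i]],
      n_steps = designs$n_steps[[i]],
      steps = designs$route[[i]])),
    routes_path, auto_unbox = TRUE, pretty = TRUE)

  scaff <- if (nrow(top) > 0L) scaffold_stats(top) else
    tibble(scaffold_key = character(), framework_key = character(),
           n = integer(), fraction = numeric())
  scaff_path <- file.path(out_dir, "scaffolds.csv")
  utils::write.csv(scaff, scaff_path, row.names = FALSE)

  pred_path <- file.path(out_dir, "predictions.csv")
  refs_path <- .cfg_get(cfg, "refs")
  n_predict <- as.integer(.cfg_num(cfg, "n_predict", 3))
  preds <- NULL
  if (!is.null(refs_path) && nrow(top) > 0L) {
    refs <- read_reference_library(refs_path)
    grid <- as.integer(strsplit(.cfg_get(cfg, "grid", "8x8"), "x")[[1]])
    predictor <- build_target_predictor(
      refs, grid = grid,
      epochs = as.integer(.cfg_num(cfg, "epochs", 50)),
      seed = seed)
    qn <- utils::head(top, n_predict)
    preds <- dplyr::bind_rows(lapply(seq_len(nrow(qn)), function(i) {
      p <- predict_targets(predictor, qn$mol[[i]],
                           n_background = as.integer(
                             .cfg_num(cfg, "n_background", 1000)),
                           p_max = .cfg_num(cfg, "p_max", 0.05),
                           seed = seed + i)
      if (nrow(p) > 0L) dplyr::mutate(p, canonical_key = qn$canonical_key[[i]],
                                      .before = 1) else NULL
    }))
    if (is.null(preds) || nrow(preds) == 0L)
      preds <- tibble(canonical_key = character(), target = character(),
                      score = numeric(), p_value = numeric())
  } else {
    preds <- tibble(canonical_key = character(), target = character(),
                    score = numeric(), p_value = numeric())
  }
  utils::write.csv(preds, pred_path, row.names = FALSE)

  files <- c(cand_path, routes_path, scaff_path, pred_path)
  md5 <- tools::md5sum(files)
  manifest <- list(
    package = "npdesign",
    version = as.character(utils::packageVersion("npdesign")),
    config = cfg[order(names(cfg))],
    seed = seed,
    counts = list(
      blocks_loaded = nrow(blocks),
      blocks_skipped = attr(blocks, "n_skipped") %||% 0L,
      schemes = length(schemes),
      candidates = nrow(designs),
      top_selected = nrow(top),
      unique_scaffolds = attr(scaff, "n_unique_scaffolds") %||% 0L,
      predictions = nrow(preds)
    ),
    files = as.list(stats::setNames(unname(md5), basename(files))),
    run_hash = unname(tools::md5sum(
      .write_temp(paste(basename(files), unname(md5), collapse = "\n"))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

.write_temp <- function(text) {
  f <- tempfile()
  writeLines(text, f)
  f
}

#' Run the bundled end-to-end demo
#'
#' Generates a seeded building-block library and reference library, then
#' runs the full pipeline with Marinopyrrole A as template.
#'
#' @param out_dir output directory
#' @param seed integer seed
#' @param n_blocks building-block library size
#' @return invisibly, the pipeline manifest
#' @export
npdesign_demo <- function(out_dir, seed = 7L, n_blocks = 24L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- fixture_spec(seed = seed, n_building_blocks = n_blocks,
                       n_reference_targets = 4L, compounds_per_target = 15L)
  blocks_path <- file.path(out_dir, "blocks.tsv")
  refs_path <- file.path(out_dir, "refs.tsv")
  generate_blocks(spec, blocks_path)
  generate_reference_library(spec, refs_path)
  cpds <- marinopyrrole_compounds()
  cfg <- list(
    template = cpds$input[cpds$id == "marinopyrrole_A"],
    blocks = blocks_path, refs = refs_path,
    n_start = as.character(n_blocks), max_steps = "3", beam_width = "20",
    seed = as.character(seed), top_k = "100", grid = "4x4", epochs = "20",
    n_background = "200", n_predict = "2")
  pipeline(cfg, out_dir)
}
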