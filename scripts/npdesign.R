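#!/usr/bin/env Rscript
# Thin command-line front end over the npdesign package.
#
# Usage:
#   Rscript scripts/npdesign.R run -c config.txt --out-dir DIR
#   Rscript scripts/npdesign.R demo --out-dir DIR [--seed N]
#   Rscript scripts/npdesign.R rank --template SMILES|FILE --candidates FILE
#       [--scaling occurrence] [--metric euclidean] [--out CSV]
#   Rscript scripts/npdesign.R react --scheme ID --reactants "SMI.SMI"
#       [--schemes FILE]
#   Rscript scripts/npdesign.R scaffolds --in FILE [--out CSV]
#   Rscript scripts/npdesign.R subsearch --query SMILES --library FILE
#   Rscript scripts/npdesign.R predict --query SMILES --refs FILE
#       [--grid 8x8] [--epochs 50] [--seed 7] [--pmax 0.05]
#   Rscript scripts/npdesign.R fixtures --out-dir DIR [--seed N] [--n-blocks N]

suppressPackageStartupMessages(library(npdesign))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L) {
  message("usage: npdesign.R <run|demo|rank|react|scaffolds|subsearch|predict|fixtures> [options]")
  quit(status = 2)
}
cmd <- args[[1]]
opts <- list()
i <- 2L
while (i <= length(args)) {
  key <- sub("^--?", "", args[[i]])
  if (i + 1L <= length(args) && !startsWith(args[[i + 1L]], "--")) {
    opts[[key]] <- args[[i + 1L]]; i <- i + 2L
  } else {
    opts[[key]] <- TRUE; i <- i + 1L
  }
}
opt <- function(key, default = NULL) {
  v <- opts[[key]]
  if (is.null(v)) default else v
}

template_arg <- function(x) {
  if (!is.null(x) && file.exists(x)) trimws(readLines(x, warn = FALSE)[[1]])
  else x
}

switch(cmd,
  run = {
    cfg <- opt("c", opt("config"))
    if (is.null(cfg)) stop("run needs -c CONFIG")
    out <- opt("out-dir", "npdesign_run")
    manifest <- pipeline(cfg, out)
    cat("run complete:", out, "run_hash:", manifest$run_hash, "\n")
  },
  demo = {
    out <- opt("out-dir", "npdesign_demo")
    manifest <- npdesign_demo(out, seed = as.integer(opt("seed", 7)))
    cat("demo complete:", out, "run_hash:", manifest$run_hash, "\n")
  },
  rank = {
    tpl <- template_arg(opt("template"))
    if (is.null(tpl)) stop("rank needs --template")
    cand <- read_library(opt("candidates"))
    res <- rank_by_cats(cand, tpl, scaling = opt("scaling", "occurrence"),
                        metric = opt("metric", "euclidean"))
    res <- res[, c("rank", "id", "canonical_key", "cats_distance")]
    out <- opt("out")
    if (is.null(out)) print(as.data.frame(res)) else {
      utils::write.csv(res, out, row.names = FALSE)
      cat("wrote", out, "\n")
    }
  },
  react = {
    reg <- load_scheme_registry(opt("schemes", default_scheme_registry()))
    s <- reg[[opt("scheme")]]
    if (is.null(s)) stop("unknown scheme id: ", opt("scheme"))
    rs <- strsplit(opt("reactants"), ".", fixed = TRUE)[[1]]
    prods <- apply_scheme(s, lapply(rs, parse_structure))
    for (p in prods) cat(mol_key(p), "\n")
  },
  scaffolds = {
    lib <- read_library(opt("in"))
    st <- scaffold_stats(lib)
    out <- opt("out")
    if (is.null(out)) print(as.data.frame(st)) else {
      utils::write.csv(st, out, row.names = FALSE)
      cat("wrote", out, "\n")
    }
    cat("unique scaffolds:", attr(st, "n_unique_scaffolds"),
        "frameworks:", attr(st, "n_unique_frameworks"), "\n")
  },
  subsearch = {
    lib <- read_library(opt("library"))
    res <- substructure_count(lib, opt("query"))
    cat("count:", res$count, "\n")
    if (res$count > 0) cat(paste(res$ids, collapse = "\n"), "\n")
  },
  predict = {
    refs <- read_reference_library(opt("refs"))
    grid <- as.integer(strsplit(opt("grid", "8x8"), "x")[[1]])
    pr <- build_target_predictor(refs, grid = grid,
                                 epochs = as.integer(opt("epochs", 50)),
                                 seed = as.integer(opt("seed", 7)))
    res <- predict_targets(pr, template_arg(opt("query")),
                           n_background = as.integer(opt("n-background", 1000)),
                           p_max = as.numeric(opt("pmax", 0.05)),
                           seed = as.integer(opt("seed", 7)))
    print(as.data.frame(res))
  },
  fixtures = {
    out <- opt("out-dir", ".")
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    spec <- fixture_spec(seed = as.integer(opt("seed", 1)),
                         n_building_blocks = as.integer(opt("n-blocks", 40)))
    generate_blocks(spec, file.path(out, "blocks.tsv"))
    generate_reference_library(spec, file.path(out, "refs.tsv"))
    cat("wrote", file.path(out, "blocks.tsv"), "and",
        file.path(out, "refs.tsv"), "\n")
  },
  stop("unknown command: ", cmd)
)
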