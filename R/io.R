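## File I/O, pipeline configuration, run manifest, and the end-to-end driver.
##
## Conventions: coordinates are micrometers, image orientation (origin
## top-left, y increasing downward); tables are comma-separated UTF-8 CSV
## with a header and "." decimal; polygons travel as GeoJSON with CCW outer
## rings; configs as YAML or JSON.

#' Read and validate a single-cell feature table
#'
#' Requires \code{cell_id}, \code{x}, \code{y} and at least one marker
#' column; rejects non-numeric coordinates and duplicated cell ids.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_cell_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("cell_id", "x", "y"))
    if (!col %in% names(tab))
      stop("cell table is missing mandatory column '", col, "'")
  if (!is.numeric(tab$x) || !is.numeric(tab$y) || anyNA(tab$x) || anyNA(tab$y))
    stop("cell table columns 'x'/'y' must be numeric micrometre coordinates")
  dup <- unique(tab$cell_id[duplicated(tab$cell_id)])
  if (length(dup))
    stop("duplicated cell_id(s): ", paste(utils::head(dup, 5), collapse = ", "))
  extra <- setdiff(names(tab), c("cell_id", "x", "y"))
  markers <- extra[vapply(extra, function(c) is.numeric(tab[[c]]), TRUE)]
  markers <- markers[!startsWith(markers, "true_") &
                     !startsWith(markers, "scaled_") &
                     !startsWith(markers, "pos_")]
  if (!length(markers))
    stop("cell table needs at least one numeric marker column")
  tab
}

#' Write a cell table as CSV
#' @param cells data.frame.
#' @param path output path.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' Write polygons as GeoJSON
#'
#' One Polygon feature per list element; outer rings are written
#' counter-clockwise and closed.  Coordinates are micrometers.
#'
#' @param polygons named list of vertex matrices (open rings).
#' @param path output path.
#' @export
write_geojson_polygons <- function(polygons, path) {
  nms <- names(polygons) %||% sprintf("polygon_%d", seq_along(polygons))
  feats <- lapply(seq_along(polygons), function(i) {
    p <- as_coords(polygons[[i]])
    if (polygon_area(p, signed = TRUE) < 0) p <- p[rev(seq_len(nrow(p))), ]
    ring <- rbind(p, p[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(name = nms[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(r) ring[r, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read polygons from GeoJSON
#'
#' @param path GeoJSON file with Polygon features (outer ring only).
#' @return named list of open-ring vertex matrices.
#' @export
read_geojson_polygons <- function(path) {
  g <- jsonlite::read_json(path)
  feats <- if (identical(g$type, "FeatureCollection")) g$features else list(g)
  polys <- list()
  for (f in feats) {
    geom <- f$geometry %||% f
    if (!identical(geom$type, "Polygon")) next
    ring <- geom$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
    if (all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    nm <- f$properties$name %||% sprintf("polygon_%d", length(polys) + 1L)
    polys[[nm]] <- m
  }
  polys
}

#' Write a density map as TSV grid plus JSON metadata
#' @param map a [kde_map()] result.
#' @param prefix output path prefix; writes \code{<prefix>.tsv} and
#'   \code{<prefix>.json}.
#' @export
write_density_map <- function(map, prefix) {
  z <- map$z
  z[map$mask] <- NA
  utils::write.table(z, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(origin = map$origin, spacing = map$spacing,
                            clip_value = map$clip_value,
                            mask_value = map$mask_value,
                            bandwidth = map$bandwidth,
                            clip_percentile = map$clip_percentile,
                            mask_percentile = map$mask_percentile),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a pipeline configuration (YAML or JSON)
#'
#' Recognized blocks: \code{paths} (cell_table, gates, rules, annotations,
#' counts, mr_meta, gene_sets, output_dir), \code{region_model},
#' \code{spatial}, \code{signatures}, \code{simulate}, \code{seed},
#' \code{log_level}.
#'
#' @param path config file path.
#' @return list of class \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  as_pipeline_config(cfg, dir = dirname(path))
}

as_pipeline_config <- function(cfg, dir = ".") {
  cfg$paths <- cfg$paths %||% list()
  # resolve relative paths against the config location
  cfg$paths <- lapply(cfg$paths, function(p)
    if (is.character(p) && !grepl("^(/|[A-Za-z]:)", p)) file.path(dir, p) else p)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$log_level <- cfg$log_level %||% "info"
  for (p in cfg$paths[setdiff(names(cfg$paths), "output_dir")])
    if (!file.exists(p)) stop("configured input does not exist: ", p)
  structure(cfg, class = "pipeline_config")
}

log_msg <- function(level, ..., min_level = "info") {
  ranks <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (ranks[[level]] >= ranks[[min_level]])
    message(sprintf("[%s] %s", toupper(level), paste0(...)))
}

file_checksum <- function(path) digest::digest(file = path, algo = "sha256")

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: simulate (or read the configured cell
#' table), gate, phenotype, regions, cell state, spatial statistics, and —
#' when count inputs are configured or simulation is requested — signature
#' scoring.  All outputs land in the configured output directory together
#' with a run manifest (tool version, config hash, input checksums,
#' per-stage row counts, timestamps).  Rerunning with identical config and
#' inputs reproduces byte-identical stage outputs.
#'
#' @param config a \code{pipeline_config} (see [read_pipeline_config()]) or
#'   a plain list with the same fields.
#' @param stages subset of stages to run (default all).
#' @return the manifest, invisibly; stage outputs are written to disk.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "gate", "phenotype",
                                    "regions", "state", "spatial",
                                    "signatures")) {
  if (!inherits(config, "pipeline_config")) config <- as_pipeline_config(config)
  lvl <- config$log_level
  out_dir <- config$paths$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(tool = "tumorscape",
                   version = as.character(utils::packageVersion("tumorscape")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   seed = config$seed,
                   config_hash = digest::digest(unclass(config)),
                   inputs = list(), stages = list())
  for (nm in setdiff(names(config$paths), "output_dir"))
    manifest$inputs[[nm]] <- file_checksum(config$paths[[nm]])

  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible(NULL))
    log_msg("info", "stage: ", name, min_level = lvl)
    res <- tryCatch(fun(), error = function(e)
      stop("pipeline aborted at stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
    res
  }

  truth <- NULL
  cells <- run_stage("simulate", function() {
    if (!is.null(config$paths$cell_table)) {
      tab <- read_cell_table(config$paths$cell_table)
      manifest$stages$simulate <<- list(n_cells = nrow(tab), source = "file")
      tab
    } else {
      sim_cfg <- config$simulate %||% list()
      tc <- tissue_config(n_cells = sim_cfg$n_cells %||% 5000,
                          seed = config$seed)
      sim <- generate_tissue(tc)
      truth <<- sim$truth
      manifest$stages$simulate <<- list(n_cells = nrow(sim$cells),
                                        source = "synthetic")
      write_cell_table(sim$cells, file.path(out_dir, "cells.csv"))
      sim$cells
    }
  })
  if (is.null(cells)) stop("no cell table: provide paths$cell_table or keep the simulate stage")

  gates <- if (!is.null(config$paths$gates)) read_gate_config(config$paths$gates)
           else if (!is.null(truth)) truth$gates
           else stop_config("no gate configuration available")
  cells <- run_stage("gate", function() {
    g <- apply_gates(cells, gates)
    manifest$stages$gate <<- list(n_markers = nrow(gates))
    g
  }) %||% cells

  rules <- if (!is.null(config$paths$rules)) read_phenotype_rules(config$paths$rules)
           else default_phenotype_rules()
  cells <- run_stage("phenotype", function() {
    cells$phenotype <- classify_cells(cells, rules)
    manifest$stages$phenotype <<-
      list(n_labels = length(unique(cells$phenotype)))
    utils::write.csv(as.data.frame(table(phenotype = cells$phenotype)),
                     file.path(out_dir, "phenotype_counts.csv"),
                     row.names = FALSE)
    cells
  }) %||% cells

  model <- do.call(region_model, config$region_model %||% list())
  polygons <- NULL
  cells <- run_stage("regions", function() {
    tum <- cells[cells$phenotype == "Tumor", c("x", "y")]
    polygons <<- reconstruct_tumor_boundaries(tum, model)
    ves <- cells[cells$phenotype == "Endothelial", c("x", "y")]
    debris <- if ("debris" %in% names(cells)) cells$debris else NULL
    lab <- assign_regions(cells, polygons, model,
                          vessel_cells = if (nrow(ves)) ves else NULL,
                          debris_flags = debris)
    if (!is.null(config$paths$annotations))
      lab$domain <- assign_domains(lab, read_geojson_polygons(config$paths$annotations))
    else if ("true_domain" %in% names(lab)) lab$domain <- lab$true_domain
    if (length(polygons))
      write_geojson_polygons(polygons, file.path(out_dir, "tumor_boundaries.geojson"))
    manifest$stages$regions <<- list(n_polygons = length(polygons),
                                     regions = as.list(table(lab$region)))
    lab
  }) %||% cells

  cells <- run_stage("state", function() {
    st <- add_state_calls(cells)
    grp <- st$domain %||% rep("all", nrow(st))
    comp <- state_composition(st[st$phenotype == "Tumor", , drop = FALSE],
                              grp[st$phenotype == "Tumor"])
    utils::write.csv(comp, file.path(out_dir, "state_composition.csv"),
                     row.names = FALSE)
    manifest$stages$state <<- list(n_tumor = sum(st$phenotype == "Tumor"))
    st
  }) %||% cells

  run_stage("spatial", function() {
    sp_cfg <- config$spatial %||% list()
    tum <- as.matrix(cells[cells$phenotype == "Tumor", c("x", "y")])
    if (nrow(tum) >= 50) {
      map <- kde_map(tum, grid_spacing = sp_cfg$grid_spacing %||% NULL)
      write_density_map(map, file.path(out_dir, "tumor_kde"))
    }
    if (nrow(tum) >= 3) {
      g <- delaunay_filtered(tum, sp_cfg$filter_factor %||% 3)
      utils::write.csv(g$edges, file.path(out_dir, "tumor_graph_edges.csv"),
                       row.names = FALSE)
    }
    others <- cells[cells$phenotype != "Tumor", ]
    if (nrow(tum) && nrow(others)) {
      nc <- neighborhood_composition(tum, others[, c("x", "y")],
                                     others$phenotype,
                                     radius = sp_cfg$radius %||% 50)
      utils::write.csv(nc, file.path(out_dir, "tumor_neighborhood.csv"),
                       row.names = FALSE)
    }
    manifest$stages$spatial <<- list(n_targets = nrow(tum))
    NULL
  })

  if ("region" %in% names(cells)) {
    comp <- regional_composition(cells$region, cells$phenotype)
    utils::write.csv(as.data.frame(comp),
                     file.path(out_dir, "regional_composition.csv"))
  }
  write_cell_table(cells, file.path(out_dir, "cells_annotated.csv"))

  run_stage("signatures", function() {
    sg <- config$signatures %||% list()
    if (!is.null(config$paths$counts)) {
      counts <- as.matrix(utils::read.table(config$paths$counts, sep = "\t",
                                            header = TRUE, row.names = 1,
                                            check.names = FALSE))
      meta <- utils::read.table(config$paths$mr_meta, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
      sets <- read_gmt(config$paths$gene_sets)
    } else {
      specs <- make_correlated_mr_specs(seed = config$seed)
      mr <- generate_mr_counts(mr_specs = specs, seed = config$seed + 1L)
      counts <- mr$counts; meta <- mr$meta; sets <- mr$truth$gene_sets
      utils::write.table(counts, file.path(out_dir, "mr_counts.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
      utils::write.table(meta, file.path(out_dir, "mr_meta.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    norm <- size_factor_normalize(counts)
    expr <- log_transform(norm$normalized)
    scores <- ssgsea(expr, sets, alpha = sg$alpha %||% 0.25)
    scaled <- scale_scores(scores, method = sg$scale %||% "minmax")
    utils::write.table(scores, file.path(out_dir, "signature_scores.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    utils::write.table(scaled, file.path(out_dir, "signature_scores_scaled.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    if (nrow(scores) >= 2 && "compartment" %in% names(meta)) {
      sc <- stratified_correlation(scores[1, ], scores[2, ], meta$compartment)
      utils::write.csv(sc, file.path(out_dir, "stratified_correlation.csv"),
                       row.names = FALSE)
    }
    manifest$stages$signatures <<- list(n_mr = ncol(counts),
                                        n_sets = nrow(scores))
    NULL
  })

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log_msg("info", "pipeline complete: ", out_dir, min_level = lvl)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Subcommands: \code{simulate}, \code{gate}, \code{phenotype},
#' \code{regions}, \code{state}, \code{spatial}, \code{signatures} (run the
#' pipeline up to and including that stage) and \code{run} (end to end).
#' Flags: \code{--config <path>}, \code{--seed <int>}, \code{--out <dir>}.
#'
#' @param args character vector of command-line arguments (default:
#'   \code{commandArgs(trailingOnly = TRUE)}).
#' @return exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  all_stages <- c("simulate", "gate", "phenotype", "regions", "state",
                  "spatial", "signatures")
  usage <- paste0("usage: tumorscape <", paste(c(all_stages, "run"),
                  collapse = "|"), "> [--config <path>] [--seed <int>] ",
                  "[--out <dir>]")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[[1]]
  if (!cmd %in% c(all_stages, "run")) {
    message("unknown subcommand: ", cmd, "\n", usage)
    return(invisible(1L))
  }
  opt <- list(config = NULL, seed = NULL, out = NULL)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[[i]])
    if (!key %in% names(opt) || i == length(args)) {
      message("bad flag: ", args[[i]], "\n", usage)
      return(invisible(1L))
    }
    opt[[key]] <- args[[i + 1L]]
    i <- i + 2L
  }
  cfg <- if (!is.null(opt$config)) read_pipeline_config(opt$config)
         else as_pipeline_config(list())
  if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
  if (!is.null(opt$out)) cfg$paths$output_dir <- opt$out
  stages <- if (cmd == "run") all_stages
            else all_stages[seq_len(match(cmd, all_stages))]
  run_pipeline(cfg, stages = stages)
  invisible(0L)
}
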