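# End-to-end orchestration: shading-correct tiles, stitch per channel,
# rolling-ball subtract, assemble per-cycle stacks, concatenate the
# hyperstack, register on the nuclear reference, optional autofluorescence
# subtraction, retention QC, optional phenotyping. Configuration is a single
# YAML/JSON file; every stage writes its output plus a provenance record,
# and runs are fully deterministic (the pipeline itself draws no random
# numbers).

pipeline_defaults <- function() {
  list(
    shading = list(enabled = TRUE, dir = "shading", floor_quantile = 0.01),
    stitching = list(min_correlation = 0.3, upsample = 10),
    background = list(enabled = TRUE, radius_px = 50, method = "auto"),
    registration = list(reference_cycle = NULL, upsample = 10,
                        max_shift_frac = 0.1),
    autofluorescence = list(enabled = FALSE, scale = "auto",
                            channels = list()),
    qc = list(dice_threshold = 0.7),
    phenotyping = list(enabled = TRUE, smooth_sigma = 1.5, min_area = 30,
                       max_area = 2000, overlap_threshold = 0.6,
                       exclusive = TRUE, mask_method = "otsu"),
    log_level = "info"
  )
}

#' Validate and resolve a pipeline configuration
#'
#' Reads a YAML or JSON configuration (or takes a list), fills defaults,
#' and reports every violation at once. Required fields: `input_dir`,
#' `manifest` (path, relative to `input_dir` if not absolute), `output_dir`
#' and `grid` (`rows`, `cols`, `overlap_fraction`, `acquisition_order`,
#' `tile_shape`).
#'
#' @param config Path to a `.yaml`/`.yml`/`.json` file, or a list.
#' @return A resolved `RunConfig` list with defaults filled and the
#'   [tile_grid()] constructed.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) config <- list()
  problems <- character()
  need <- function(field) {
    if (is.null(config[[field]])) {
      problems <<- c(problems, paste0("missing required field: ", field))
      FALSE
    } else {
      TRUE
    }
  }
  has_input <- need("input_dir"); need("manifest"); need("output_dir")
  if (has_input && !dir.exists(config$input_dir)) {
    problems <- c(problems, paste0("input_dir does not exist: ",
                                   config$input_dir))
  }
  grid <- NULL
  if (need("grid")) {
    g <- config$grid
    for (f in c("rows", "cols", "tile_shape")) {
      if (is.null(g[[f]])) {
        problems <- c(problems, paste0("grid: missing ", f))
      }
    }
    ov <- g$overlap_fraction %||% 0.1
    if (!is.numeric(ov) || ov < 0 || ov >= 0.5) {
      problems <- c(problems,
                    sprintf("grid: overlap_fraction %s outside [0, 0.5)",
                            format(ov)))
    }
    if (!length(problems)) {
      grid <- tryCatch(
        tile_grid(g$rows, g$cols, ov,
                  g$acquisition_order %||% "row_major",
                  tile_shape = unlist(g$tile_shape)),
        error = function(e) {
          problems <<- c(problems, paste0("grid: ", conditionMessage(e)))
          NULL
        })
    }
  }
  manifest_path <- NULL
  if (!length(problems)) {
    manifest_path <- config$manifest
    if (!file.exists(manifest_path) && has_input) {
      manifest_path <- file.path(config$input_dir, config$manifest)
    }
    if (!file.exists(manifest_path)) {
      problems <- c(problems, paste0("manifest not found: ", config$manifest))
    }
  }
  defaults <- pipeline_defaults()
  for (blk in names(defaults)) {
    merged <- defaults[[blk]]
    if (is.list(merged) && is.list(config[[blk]])) {
      merged[names(config[[blk]])] <- config[[blk]]
    } else if (!is.null(config[[blk]])) {
      merged <- config[[blk]]
    }
    config[[blk]] <- merged
  }
  if (config$background$enabled && config$background$radius_px < 1) {
    problems <- c(problems, "background: radius_px must be >= 1")
  }
  th <- config$phenotyping$overlap_threshold
  if (!is.numeric(th) || th <= 0 || th > 1) {
    problems <- c(problems,
                  "phenotyping: overlap_threshold outside (0, 1]")
  }
  if (length(problems)) {
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  config$grid <- grid
  config$manifest_path <- manifest_path
  class(config) <- c("RunConfig", "list")
  config
}

# Append a structured (JSON-lines) log entry.
log_event <- function(log_path, stage, message, ...) {
  entry <- list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage, message = message, ...)
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA), "\n",
      file = log_path, append = TRUE, sep = "")
}

#' Run the full preprocessing pipeline
#'
#' Executes, per cycle: read tiles, shading-correct each channel with its
#' reference (`shading/<channel_name>.tif`), refine tile placements on the
#' cycle's nuclear channel (all channels of a cycle share the stage
#' positions), blend each channel's mosaic, rolling-ball subtract the
#' fluorescence mosaics ([brightfield_flatten()] is applied to brightfield
#' planes instead). Mosaics are cropped to a common frame, assembled into a
#' hyperstack, registered on the nuclear reference, optionally
#' autofluorescence-subtracted, quality-controlled, and (optionally)
#' quantified into a cell table.
#'
#' Tile files are looked up as
#' `<input_dir>/tiles/c<cycle>_<channel_name>_t<k>.tif` in acquisition
#' order, the layout written by [write_fixture()].
#'
#' @param config A `RunConfig` from [validate_config()], or a path/list
#'   accepted by it.
#' @return Invisibly, a list with the registered `hyperstack`, `shifts`,
#'   `qc` report, `cell_table` (or `NULL`) and the output paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "RunConfig")) config <- validate_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.jsonl")
  if (file.exists(log_path)) unlink(log_path)
  provenance <- list(config_hash = content_hash(
    config[setdiff(names(config), c("grid"))]))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    ts <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      log_event(log_path, name, paste("FAILED:", conditionMessage(e)))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    log_event(log_path, name, "done",
              seconds = round(proc.time()[["elapsed"]] - ts, 3))
    res
  }
  manifest <- stage("manifest", read_manifest(config$manifest_path))
  grid <- config$grid
  n_tiles <- grid$rows * grid$cols
  cycles <- sort(unique(manifest$cycle))

  mosaics <- stage("preprocess+stitch", {
    lapply(cycles, function(cy) {
      recs <- manifest[manifest$cycle == cy, , drop = FALSE]
      chans <- lapply(seq_len(nrow(recs)), function(k) {
        rec <- recs[k, ]
        tiles <- lapply(seq_len(n_tiles), function(t) {
          read_plane(file.path(config$input_dir, "tiles",
                               sprintf("c%d_%s_t%02d.tif", cy,
                                       rec$channel_name, t)))
        })
        if (isTRUE(config$shading$enabled)) {
          ref_path <- file.path(config$input_dir, config$shading$dir,
                                paste0(rec$channel_name, ".tif"))
          if (file.exists(ref_path)) {
            field <- build_shading_field(
              read_plane(ref_path),
              floor_quantile = config$shading$floor_quantile)
            tiles <- lapply(tiles, correct_shading, field = field)
          }
        }
        list(record = rec, tiles = tiles)
      })
      nuc_k <- which(recs$role == "nuclear")
      pl <- refine_offsets(chans[[nuc_k]]$tiles, grid,
                           min_correlation = config$stitching$min_correlation,
                           upsample = config$stitching$upsample)
      lapply(chans, function(ch) {
        mosaic <- blend_mosaic(ch$tiles, pl)
        if (ch$record$role == "brightfield") {
          mosaic <- brightfield_flatten(mosaic)
        } else if (isTRUE(config$background$enabled)) {
          mosaic <- subtract_background(
            mosaic, radius_px = config$background$radius_px,
            method = config$background$method)
        }
        list(record = ch$record, mosaic = mosaic)
      })
    })
  })

  stack <- stage("assemble", {
    shapes <- do.call(rbind, lapply(mosaics, function(cyc) {
      do.call(rbind, lapply(cyc, function(ch) dim(ch$mosaic$pixels)))
    }))
    common <- c(min(shapes[, 1]), min(shapes[, 2]))
    per_cycle <- lapply(seq_along(cycles), function(i) {
      planes <- lapply(mosaics[[i]], function(ch) {
        image_plane(ch$mosaic$pixels[seq_len(common[1]),
                                     seq_len(common[2])])
      })
      list(cycle = cycles[i], planes = planes)
    })
    assemble_hyperstack(per_cycle, manifest)
  })

  reg <- stage("register", {
    register_cycles(stack,
                    reference_cycle = config$registration$reference_cycle,
                    upsample = config$registration$upsample,
                    max_shift_frac = config$registration$max_shift_frac)
  })
  stack <- reg$stack

  if (isTRUE(config$autofluorescence$enabled)) {
    stack <- stage("autofluorescence", {
      af_i <- which(stack$records$role == "autofluorescence")
      if (!length(af_i)) stop("no autofluorescence plane in the hyperstack")
      targets <- unlist(config$autofluorescence$channels)
      for (m in targets) {
        mi <- which(stack$records$marker == m &
                    stack$records$role == "marker")
        if (!length(mi)) stop("autofluorescence target not found: ", m)
        # use the AF plane of the marker's own cycle when present
        ai <- af_i[match(stack$records$cycle[mi[1]],
                         stack$records$cycle[af_i])]
        if (is.na(ai)) ai <- af_i[1]
        corrected <- subtract_autofluorescence(
          stack$planes[[mi[1]]], stack$planes[[ai]],
          scale = config$autofluorescence$scale)
        log_event(log_path, "autofluorescence",
                  sprintf("marker %s: scale %.3f", m,
                          attr(corrected, "scale")))
        stack$planes[[mi[1]]] <- corrected
      }
      stack
    })
  }

  hs_path <- file.path(out_dir, "hyperstack.tif")
  stage("write-hyperstack", write_hyperstack(stack, hs_path))

  qc <- stage("qc", dapi_retention_qc(
    stack, threshold_dice = config$qc$dice_threshold,
    reference_cycle = config$registration$reference_cycle))
  jsonlite::write_json(qc, file.path(out_dir, "qc.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  cell_table <- NULL
  if (isTRUE(config$phenotyping$enabled)) {
    cell_table <- stage("phenotype", {
      ref_cycle <- config$registration$reference_cycle %||%
        min(stack$records$cycle)
      nuclear <- stack$planes[[nuclear_row(stack$records, ref_cycle)]]
      labels <- segment_nuclei(
        nuclear, smooth_sigma = config$phenotyping$smooth_sigma,
        min_area = config$phenotyping$min_area,
        max_area = config$phenotyping$max_area)
      markers <- unique(stack$records$marker[stack$records$role == "marker"])
      masks <- lapply(markers, function(m) {
        mi <- which(stack$records$marker == m &
                    stack$records$role == "marker")[1]
        marker_mask(stack$planes[[mi]],
                    method = config$phenotyping$mask_method)
      })
      names(masks) <- markers
      quantify(stack, labels, masks,
               threshold = config$phenotyping$overlap_threshold,
               exclusive = isTRUE(config$phenotyping$exclusive),
               sample_id = basename(config$input_dir))
    })
    write_cell_table(cell_table, file.path(out_dir, "cell_table.csv"))
  }

  provenance$stages <- list(
    manifest = content_hash(config$manifest_path),
    hyperstack = content_hash(hs_path),
    registered_shifts = lapply(reg$shifts, function(s) {
      list(cycle = s$cycle, dy = s$dy, dx = s$dx,
           peak_correlation = s$peak_correlation, flagged = s$flagged)
    }),
    elapsed_seconds = round(proc.time()[["elapsed"]] - t0, 3))
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  log_event(log_path, "pipeline", "complete")
  invisible(list(hyperstack = stack, shifts = reg$shifts, qc = qc,
                 cell_table = cell_table,
                 paths = list(hyperstack = hs_path,
                              qc = file.path(out_dir, "qc.json"),
                              cell_table = if (is.null(cell_table)) NULL
                                           else file.path(out_dir,
                                                          "cell_table.csv"),
                              log = log_path)))
}
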