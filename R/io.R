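# Readers/writers: TIFF movies with JSON sidecar metadata, ROI sets,
# evidence tables, CSV reports and run manifests.

#' Write a movie as multi-page TIFF plus JSON sidecar
#'
#' Pages are ordered frame-major (frame, then z, then channel); pixel
#' values are stored as 32-bit floats normalised by a `scale` recorded in
#' the sidecar, which also carries channel names, pixel size (um), frame
#' interval (s) and array dimensions. Ground truth, when present, is
#' serialised alongside so fixtures round-trip.
#'
#' @param movie A `synthetic_movie` (or loaded movie).
#' @param path Output TIFF path; the sidecar is written at
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  d <- dim(movie$data)
  scale <- max(movie$data, 1e-12)
  pages <- vector("list", d[1] * d[2] * d[5])
  i <- 0L
  for (f in seq_len(d[1])) for (z in seq_len(d[2])) for (ch in seq_len(d[5])) {
    i <- i + 1L
    pages[[i]] <- matrix(movie$data[f, z, , , ch], d[3], d[4]) / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(
    dims = as.integer(d), channels = movie$channels,
    pixel_size_um = movie$pixel_size,
    frame_interval_s = movie$frame_interval,
    scale = scale,
    page_order = "frame,z,channel"
  )
  if (!is.null(movie$truth$graph)) {
    g <- movie$truth$graph
    meta$truth <- list(
      nodes = cbind(g$nodes, as.data.frame(g$init)),
      edges = g$edges, species = g$species
    )
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' Load a movie written by [write_movie_tiff()]
#'
#' Physical metadata (pixel size, frame interval) must come from the
#' sidecar or be supplied as overrides; loading fails otherwise, naming
#' the missing field.
#'
#' @param path TIFF path.
#' @param pixel_size,frame_interval Optional overrides (um, s).
#' @param channel_map Optional character vector: the desired channel
#'   order (a permutation of the stored channel names).
#' @return A `synthetic_movie`.
#' @export
load_movie <- function(path, pixel_size = NULL, frame_interval = NULL,
                       channel_map = NULL) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  pixel_size <- pixel_size %||% meta$pixel_size_um
  frame_interval <- frame_interval %||% meta$frame_interval_s
  if (is.null(pixel_size)) {
    abort("Missing physical metadata: pixel_size (um); supply an override.")
  }
  if (is.null(frame_interval)) {
    abort("Missing physical metadata: frame_interval (s); supply an override.")
  }
  d <- if (!is.null(meta$dims)) as.integer(unlist(meta$dims)) else {
    c(length(pages), 1L, dim(pages[[1]]), 1L)
  }
  channels <- if (!is.null(meta$channels)) {
    as.character(unlist(meta$channels))
  } else {
    paste0("ch", seq_len(d[5]))
  }
  scale <- meta$scale %||% 1
  data <- array(0, dim = d)
  i <- 0L
  for (f in seq_len(d[1])) for (z in seq_len(d[2])) for (ch in seq_len(d[5])) {
    i <- i + 1L
    data[f, z, , , ch] <- pages[[i]] * scale
  }
  if (!is.null(channel_map)) {
    idx <- match(channel_map, channels)
    if (anyNA(idx)) abort("`channel_map` names channels not in the file.")
    data <- data[, , , , idx, drop = FALSE]
    channels <- channels[idx]
  }
  truth <- NULL
  if (!is.null(meta$truth)) {
    nodes <- as_tibble(lapply(meta$truth$nodes, unlist))
    edges <- if (length(meta$truth$edges$from)) {
      as_tibble(lapply(meta$truth$edges, unlist))
    } else {
      NULL
    }
    truth <- list(graph = compartment_graph(
      nodes, edges, species = as.character(unlist(meta$truth$species))))
  }
  structure(
    list(data = data, channels = channels, pixel_size = pixel_size,
         frame_interval = frame_interval, geometry = NULL, truth = truth),
    class = "synthetic_movie"
  )
}

#' Read and write ROI sets as JSON
#'
#' ROIs are stored as a list of objects with `shape`, `plane`, and either
#' rectangle bounds or a pixel vertex list.
#'
#' @param rois List of [roi_rect()] / [roi_polygon()] objects.
#' @param path JSON path.
#' @export
write_rois <- function(rois, path) {
  ser <- lapply(rois, function(r) {
    if (r$shape == "rectangle") {
      list(shape = "rectangle", id = r$id, plane = r$plane,
           y0 = r$y0, y1 = r$y1, x0 = r$x0, x1 = r$x1)
    } else {
      list(shape = "polygon", id = r$id, plane = r$plane,
           vertices = unname(as.matrix(r$vertices)))
    }
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(r) {
    if (r$shape == "rectangle") {
      roi_rect(r$y0, r$y1, r$x0, r$x1, plane = r$plane, id = r$id)
    } else {
      v <- do.call(rbind, lapply(r$vertices, unlist))
      roi_polygon(v, plane = r$plane, id = r$id)
    }
  })
}

#' Write a stage report: CSV tables plus a run manifest
#'
#' Each element of `results` that is a data frame becomes
#' `<name>.csv` under `dir`; the manifest (`manifest.json`) records the
#' inputs, seed, parameters and package version so a run can be
#' reproduced bit-identically.
#'
#' @param results Named list of data frames (and scalars, folded into
#'   the manifest).
#' @param dir Output directory, created if needed.
#' @param manifest Named list of run parameters (inputs, seed, ...).
#' @return Paths of the written files, invisibly.
#' @export
write_report <- function(results, dir, manifest = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x)) {
      p <- file.path(dir, paste0(nm, ".csv"))
      df <- as.data.frame(x)
      is_list <- vapply(df, is.list, logical(1))
      df[is_list] <- lapply(df[is_list], function(col) {
        vapply(col, function(v) paste(unlist(v), collapse = ";"), "")
      })
      write.csv(df, p, row.names = FALSE)
      written <- c(written, p)
    } else {
      manifest[[nm]] <- x
    }
  }
  manifest$tool <- "nicheflip"
  manifest$version <- as.character(utils::packageVersion("nicheflip"))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(written, mp))
}

#' Read a flat run configuration file
#'
#' YAML with keys mirroring the simulator and analysis parameters
#' (subcommand, input paths, channel map, physical metadata overrides,
#' seed, output directory, confidence level, square counts and sizes).
#'
#' @param path YAML path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed) && isTRUE(cfg$stochastic)) {
    abort("Config for a stochastic stage must carry a seed.")
  }
  cfg
}
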