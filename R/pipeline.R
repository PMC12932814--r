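#' Pipeline run configuration
#'
#' @param mode `"synthetic-direct"` (feature table drawn from the linear
#'   model), `"synthetic-image"` (images rendered then measured) or
#'   `"from-images"` (a directory of scans plus a metadata CSV).
#' @param seed Master seed (mandatory in the synthetic modes).
#' @param effects An [effect_spec()] for the synthetic modes.
#' @param n_days Number of experimental days.
#' @param image_dir,metadata Path of the image directory and its metadata
#'   CSV (from-images mode).
#' @param texture,structure,stats Parameter lists for the three stages
#'   (`levels`, `offsets`, `roi`; `roi`, `window`, `offset`, `prune`;
#'   `alpha`, `ss_type`).
#' @param base_params [growth_params()] for synthetic-image mode.
#' @return A list of class `ccc_run_config`.
#' @export
run_config <- function(mode = c("synthetic-direct", "synthetic-image",
                                "from-images"),
                       seed = NULL, effects = effect_spec(seed = seed %||% 1L),
                       n_days = 6L, image_dir = NULL, metadata = NULL,
                       texture = list(levels = 32L, roi = c(0, 100)),
                       structure = list(roi = c(0, 90), prune = 2),
                       stats = list(alpha = 0.01, ss_type = "II"),
                       base_params = growth_params()) {
  mode <- match.arg(mode)
  if (mode != "from-images" && is.null(seed)) {
    stop("seed is mandatory in the synthetic modes")
  }
  if (mode == "from-images") {
    if (is.null(image_dir) || !dir.exists(image_dir)) {
      stop("from-images mode requires an existing image_dir")
    }
    if (is.null(metadata)) stop("from-images mode requires metadata")
  }
  # note: the 'structure' argument shadows base::structure here
  out <- list(mode = mode, seed = seed, effects = effects,
              n_days = as.integer(n_days), image_dir = image_dir,
              metadata = metadata, texture = texture,
              structure = structure, stats = stats,
              base_params = base_params)
  class(out) <- "ccc_run_config"
  out
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Ingest scanned fingerprint images
#'
#' Reads 8-bit greyscale PNG/TIFF images listed in a metadata table (one
#' row per plate, with a `file` column and the design columns). RGB input
#' is converted by luminance with a warning; a metadata row without its
#' image file is skipped and recorded; an image file in the directory
#' without a metadata row is an error. The plate centre and radius are
#' taken from `centre_row`/`centre_col`/`plate_radius` columns when
#' present, otherwise from the image geometry.
#'
#' @param dir Directory of images.
#' @param metadata Data frame or CSV path with `plate_id`, `file` and the
#'   design factor columns.
#' @return List: `images` (named list of [ccc_image()]), `design` (a
#'   `ccc_design` restricted to ingested plates), `skipped` (character).
#' @export
ingest_images <- function(dir, metadata) {
  if (is.character(metadata)) {
    metadata <- utils::read.csv(metadata, stringsAsFactors = FALSE,
                                colClasses = c(batch = "character"))
  }
  stopifnot(is.data.frame(metadata), "file" %in% names(metadata),
            "plate_id" %in% names(metadata))
  on_disk <- list.files(dir, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE)
  orphans <- setdiff(on_disk, metadata$file)
  if (length(orphans)) {
    stop("image file(s) without a metadata row: ",
         paste(orphans, collapse = ", "))
  }
  images <- list(); skipped <- character(0); kept <- logical(nrow(metadata))
  for (i in seq_len(nrow(metadata))) {
    path <- file.path(dir, metadata$file[i])
    if (!file.exists(path)) {
      skipped <- c(skipped, metadata$file[i])
      next
    }
    px <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
      png::readPNG(path)
    } else {
      tiff::readTIFF(path)
    }
    if (length(dim(px)) == 3L) {
      warning("RGB image '", metadata$file[i], "' converted by luminance")
      px <- 0.2126 * px[, , 1] + 0.7152 * px[, , 2] + 0.0722 * px[, , 3]
    }
    px <- round(px * 255)
    centre <- if (all(c("centre_row", "centre_col") %in% names(metadata))) {
      c(metadata$centre_row[i], metadata$centre_col[i])
    } else {
      (dim(px) + 1) / 2
    }
    radius <- if ("plate_radius" %in% names(metadata)) {
      metadata$plate_radius[i]
    } else {
      floor(min(dim(px)) / 2)
    }
    images[[metadata$plate_id[i]]] <- ccc_image(px, centre = centre,
                                                plate_radius = radius)
    kept[i] <- TRUE
  }
  design <- metadata[kept, setdiff(names(metadata),
                                   c("file", "centre_row", "centre_col")),
                     drop = FALSE]
  if (!"subspecies" %in% names(design) && "host_tree" %in% names(design)) {
    design$subspecies <- derive_subspecies(design$host_tree)
  }
  class(design) <- c("ccc_design", "data.frame")
  list(images = images, design = design, skipped = skipped)
}

# measure texture + structure features for a list of images
.measure_images <- function(images, texture_par, structure_par) {
  rows <- lapply(names(images), function(id) {
    img <- images[[id]]
    tx <- compute_texture_features(
      img, roi = texture_par$roi %||% c(0, 100),
      levels = texture_par$levels %||% 32L,
      offsets = texture_par$offsets %||% list(c(0L, 1L), c(1L, 0L)))
    st <- compute_structure_features(
      img, roi = structure_par$roi %||% c(0, 90),
      window = structure_par$window, offset = structure_par$offset %||% 10,
      length_edges = structure_par$length_edges %||% default_length_edges(),
      width_edges = structure_par$width_edges %||% default_width_edges(),
      prune = structure_par$prune %||% 2)
    cbind(data.frame(plate_id = id, stringsAsFactors = FALSE),
          as.data.frame(t(tx)), as.data.frame(t(st)))
  })
  do.call(rbind, rows)
}

#' Run the complete evaluation pipeline
#'
#' Design enumeration, feature synthesis/ingestion, and the three
#' sensitivity tests, with every tabular artefact written to `out_dir`
#' (design.csv, features.csv, sensitivity_*.csv, manifest.json). Runs are
#' idempotent per seed: identical configurations write byte-identical
#' CSVs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if absent).
#' @return The run manifest (invisibly also written as JSON): config
#'   hash, package version, per-stage row counts, wall-clock seconds and
#'   collected warnings.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "ccc_run_config"))
  t0 <- Sys.time()
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  warnings_seen <- character(0)
  note <- function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  withCallingHandlers({
    if (config$mode == "from-images") {
      ing <- ingest_images(config$image_dir, config$metadata)
      design <- ing$design
      features <- .measure_images(ing$images, config$texture, config$structure)
      skipped <- ing$skipped
    } else {
      design <- build_verum_design(n_days = config$n_days)
      skipped <- character(0)
      if (config$mode == "synthetic-direct") {
        features <- generate_feature_table(design, config$effects)
      } else {
        set_ <- generate_image_set(design, config$effects, seed = config$seed,
                                   base_params = config$base_params)
        features <- .measure_images(set_$images, config$texture,
                                    config$structure)
        utils::write.csv(set_$metadata, file.path(out_dir, "latent.csv"),
                         row.names = FALSE)
      }
    }
    write_design_csv(design, file.path(out_dir, "design.csv"))
    utils::write.csv(features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    if (config$mode != "synthetic-direct") {
      # provenance sidecar: the histogram conventions behind the l/w columns
      jsonlite::write_json(
        list(length_edges = config$structure$length_edges %||%
               default_length_edges(),
             width_edges = config$structure$width_edges %||%
               default_width_edges(),
             prune = config$structure$prune %||% 2),
        file.path(out_dir, "bin_edges.json"), digits = NA)
    }
    tests <- c("subspecies", "deciduous", "blending")
    counts <- list(design = nrow(design), features = nrow(features))
    for (tid in tests) {
      res <- run_sensitivity_test(features, design, tid,
                                  alpha = config$stats$alpha %||% 0.01,
                                  ss_type = config$stats$ss_type %||% "II")
      write_sensitivity_csv(res, file.path(out_dir,
                                           paste0("sensitivity_", tid, ".csv")))
      counts[[paste0("sensitivity_", tid)]] <- attr(res, "n")
    }
  }, warning = note)
  manifest <- list(
    config_hash = .config_hash(config),
    package_version = as.character(utils::packageVersion("cccfp")),
    mode = config$mode, seed = config$seed,
    row_counts = counts, skipped = skipped,
    wall_clock_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    warnings = warnings_seen)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
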