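# File formats: multi-page TIFF (one page per channel per z) with a JSON
# sidecar for layout and intensity scale, PNG/TIFF masks, 2-column CSV
# traces with a JSON sidecar, YAML configs, TSV tables.

sidecar_path <- function(path) paste0(path, ".json")

#' Write an image stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are ordered channel-fastest within z. TIFF stores values in
#' `[0, 1]`, so intensities are divided by a power-of-two `scale_divisor`
#' (recorded in the sidecar) and written as 32-bit floats; integer-valued
#' intensities below the divisor round-trip exactly.
#'
#' @param stack An [image_stack()].
#' @param path Output `.tif` path; the sidecar lands at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack)
  divisor <- 2^max(0, ceiling(log2(max(stack) + 1)))
  pages <- list()
  for (z in seq_len(d[4])) for (ch in seq_len(d[3]))
    pages[[length(pages) + 1L]] <- unclass(stack)[, , ch, z] / divisor
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(
    channels = channel_roles(stack), n_z = d[4],
    pixel_size_um = pixel_size(stack), scale_divisor = divisor,
    page_order = "channel_fastest"),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image into an image stack
#'
#' TIFF (multi-page) or PNG. Layout (channel count, z count) and pixel
#' scale come from the JSON sidecar written by [write_image_stack()] when
#' present; otherwise they must be supplied. When both the file metadata
#' and the configuration provide a pixel size, the configured value wins
#' and a warning records the override.
#'
#' @param path Image path.
#' @param channels,n_z Layout override (required for multi-page TIFFs
#'   without a sidecar).
#' @param pixel_size_um Configured pixel size; overrides file metadata.
#' @return An [image_stack()].
#' @export
read_image <- function(path, channels = NULL, n_z = NULL,
                       pixel_size_um = NULL) {
  if (!file.exists(path)) abort(sprintf("cannot read '%s'.", path))
  meta <- NULL
  if (file.exists(sidecar_path(path)))
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      abort("reading PNG requires the 'png' package.")
    pages <- list(png::readPNG(path))
    if (length(dim(pages[[1]])) == 3) pages[[1]] <- pages[[1]][, , 1]
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  }
  divisor <- meta$scale_divisor %||% 1
  ch_names <- channels %||% meta$channels %||%
    if (length(pages) == 1) "ch1" else
      abort("ambiguous axes: multi-page image without sidecar needs `channels`/`n_z`.")
  nz <- n_z %||% meta$n_z %||% (length(pages) / length(ch_names))
  if (length(ch_names) * nz != length(pages))
    abort("page count does not match channels x z.")
  px_meta <- meta$pixel_size_um
  px <- pixel_size_um %||% px_meta
  if (!is.null(pixel_size_um) && !is.null(px_meta) &&
      pixel_size_um != px_meta)
    warn(sprintf("pixel size: configured %g um/px overrides file metadata %g um/px.",
                 pixel_size_um, px_meta))
  if (is.null(px)) abort("pixel size unknown: supply `pixel_size_um`.")
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  arr <- array(0, c(h, w, length(ch_names), nz))
  i <- 0L
  for (z in seq_len(nz)) for (ch in seq_along(ch_names)) {
    i <- i + 1L
    arr[, , ch, z] <- pages[[i]] * divisor
  }
  image_stack(arr, px, ch_names)
}

#' Read a binary mask from TIFF or PNG
#'
#' Non-zero pixels become foreground.
#'
#' @param path Mask path.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
  st <- read_image(path, channels = "mask", n_z = 1, pixel_size_um = 1)
  binary_mask(get_plane(st, 1) > 0, provenance = list(source = path))
}

#' Write / read a current trace (CSV + JSON sidecar)
#'
#' The CSV holds `time_s` and `current_pa`; the sidecar records
#' `sample_rate_hz` and optional `group` / `cell_id` labels.
#'
#' @param trace An `epsc_trace` tibble.
#' @param path Output `.csv` path.
#' @param group,cell_id Optional labels stored in the sidecar.
#' @return `write_trace` returns `path` invisibly; `read_trace` an
#'   `epsc_trace`.
#' @export
write_trace <- function(trace, path, group = NULL, cell_id = NULL) {
  readr::write_csv(tibble::tibble(time_s = trace$time_s,
                                  current_pa = trace$current_pa), path)
  jsonlite::write_json(list(sample_rate_hz = attr(trace, "sample_rate_hz"),
                            group = group, cell_id = cell_id),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("time_s", "current_pa") %in% names(df)))
    abort("trace CSV must have columns time_s, current_pa.")
  fs <- NULL; grp <- NULL; cid <- NULL
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    fs <- meta$sample_rate_hz; grp <- meta$group; cid <- meta$cell_id
  }
  if (is.null(fs)) {
    dt <- diff(df$time_s[1:2])
    fs <- 1 / dt
  }
  out <- tibble::as_tibble(df)
  attr(out, "sample_rate_hz") <- fs
  attr(out, "group") <- grp
  attr(out, "cell_id") <- cid
  class(out) <- c("epsc_trace", class(out))
  out
}

#' Run the inclusion pipeline over a batch of fields
#'
#' Executes [quantify_inclusions()] per field, aggregates per-group
#' summaries, and emits a run manifest. Per-field failures are caught,
#' recorded in the manifest and messaged; they never abort the batch.
#' Given identical inputs, configuration and seed the emitted tables are
#' byte-identical (timestamps are confined to the manifest).
#'
#' @param fields Named list of [image_stack()] objects (or file paths), or
#'   the result of [generate_scenario()] (its fields and manifest are used).
#' @param config A [pipeline_config()].
#' @param groups Optional named character vector mapping field id to group
#'   label; defaults to the scenario manifest or `"all"`.
#' @return A list of class `batch_result`: `per_field` (tibble),
#'   `group_summary` (tibble of mean/median/min/max per metric), and
#'   `manifest` (inputs with content hashes, config snapshot, package
#'   version, per-field status, warnings, timestamp). When `config$out_dir`
#'   is set, `per_field.tsv`, `group_summary.tsv` and `manifest.json` are
#'   written there.
#' @export
run_batch <- function(fields, config, groups = NULL) {
  if (is.list(fields) && !is.null(fields$fields) && !is.null(fields$manifest)) {
    if (is.null(groups))
      groups <- setNames(fields$manifest$group, fields$manifest$field_id)
    fields <- lapply(fields$fields, `[[`, "stack")
  }
  if (is.null(names(fields)) || any(names(fields) == ""))
    abort("`fields` must be a named list.")
  if (length(fields) < 1) abort("at least one field is required.")
  if (is.null(groups)) groups <- setNames(rep("all", length(fields)),
                                          names(fields))
  rows <- list(); status <- list(); warnings <- character(0)
  for (fid in names(fields)) {
    f <- fields[[fid]]
    res <- tryCatch({
      st <- if (is.character(f)) read_image(f,
        pixel_size_um = config$pixel_size_um) else f
      out <- withCallingHandlers(
        quantify_inclusions(st, config, field_id = fid),
        warning = function(w) {
          warnings <<- c(warnings, sprintf("%s: %s", fid, conditionMessage(w)))
          invokeRestart("muffleWarning")
        })
      status[[fid]] <- "ok"
      dplyr::mutate(out$summary, group = groups[[fid]], .after = "field_id")
    }, error = function(e) {
      status[[fid]] <<- paste0("failed: ", conditionMessage(e))
      message(sprintf("field '%s' failed and was skipped: %s", fid,
                      conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[fid]] <- res
  }
  per_field <- dplyr::bind_rows(rows)
  group_summary <- tibble::tibble()
  if (nrow(per_field) > 0) {
    metrics <- c("n_particles", "total_area_px", "sum_int_den",
                 "n_live_nuclei", "particles_per_live", "int_den_per_live")
    group_summary <- per_field |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(
        n_fields = dplyr::n(),
        dplyr::across(dplyr::all_of(metrics),
                      list(mean = ~mean(.x), median = ~median(.x),
                           min = ~min(.x), max = ~max(.x)),
                      .names = "{.col}_{.fn}"),
        .groups = "drop")
  }
  manifest <- list(
    package_version = as.character(packageVersion("tauscope")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = unclass_config(config),
    inputs = lapply(fields, function(f)
      if (is.character(f)) unname(tools::md5sum(f)) else rlang::hash(unclass(f))),
    status = status,
    warnings = warnings)
  out <- structure(list(per_field = per_field, group_summary = group_summary,
                        manifest = manifest), class = "batch_result")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(per_field, file.path(config$out_dir, "per_field.tsv"))
    readr::write_tsv(group_summary, file.path(config$out_dir, "group_summary.tsv"))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  out
}

unclass_config <- function(config) {
  x <- unclass(config)
  x$cutoffs <- unclass(x$cutoffs)
  x$channels <- as.list(x$channels)
  x
}

#' @export
print.batch_result <- function(x, ...) {
  cat(sprintf("<batch_result> %d field(s), %d group(s); %d failure(s)\n",
              nrow(x$per_field),
              length(unique(x$per_field$group)),
              sum(vapply(x$manifest$status, function(s) s != "ok", logical(1)))))
  invisible(x)
}
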