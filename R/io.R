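#' Write a phantom as multi-page TIFF with a ground-truth sidecar
#'
#' Writes the two channels of a phantom cross-section as a 2-page grayscale
#' TIFF (page 1 autofluorescence, page 2 SHG) at the configured bit depth,
#' plus a sidecar JSON carrying the physical pixel sizes, channel order,
#' generator parameters and ground truth. Intensities are stored on the
#' native 0-255 scale; both 8- and 16-bit encodings round-trip integer
#' intensities exactly.
#'
#' @param phantom An `ecti_phantom` from [render_phantom()].
#' @param prefix Output path prefix; writes `<prefix>.tif` and
#'   `<prefix>.json`.
#' @return Invisibly, the two paths written.
#' @export
write_phantom <- function(phantom, prefix) {
  stopifnot(inherits(phantom, "ecti_phantom"))
  s <- phantom$section
  tif <- paste0(prefix, ".tif")
  json <- paste0(prefix, ".json")
  tiff::writeTIFF(list(s$channel_af / 255, s$channel_shg / 255), tif,
                  bits.per.sample = phantom$params$bit_depth,
                  compression = "none")
  tr <- phantom$truth
  meta <- list(
    schema = "ectishape-phantom/1",
    px_lateral_um = s$px_lateral,
    px_axial_um = s$px_axial,
    channels = c("autofluorescence", "shg"),
    bit_depth = phantom$params$bit_depth,
    rng_seed = phantom$params$rng_seed,
    ground_truth = list(
      true_delta_linearity = tr$true_delta_linearity,
      baseline_depth_um = tr$boundary_model$baseline_depth,
      true_depth_um = tr$true_depth_um,
      true_thickness_profile_um = tr$true_thickness_profile_um
    )
  )
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(tif, json))
}

#' Read a two-channel cross-section from TIFF
#'
#' Reads a 2-page grayscale TIFF (autofluorescence first, SHG second) into
#' a [cross_section()]. Pixel sizes come from the sidecar JSON written by
#' [write_phantom()] (located by replacing the extension) or from explicit
#' arguments, which take precedence.
#'
#' @param path TIFF file path.
#' @param sidecar Optional sidecar JSON path; defaults to `path` with the
#'   extension replaced by `.json` when that file exists.
#' @param px_lateral,px_axial Pixel sizes (um/px); required when no sidecar
#'   is available.
#' @return A [cross_section()]; the sidecar ground truth (if any) is
#'   attached as attribute `"ground_truth"`.
#' @export
read_cross_section <- function(path, sidecar = NULL,
                               px_lateral = NULL, px_axial = NULL) {
  if (!file.exists(path)) stop("TIFF not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2L) {
    stop("format error in ", path, ": expected 2 grayscale pages ",
         "(autofluorescence, SHG), found ", length(pages))
  }
  if (is.null(sidecar)) {
    guess <- sub("\\.tiff?$", ".json", path)
    if (file.exists(guess)) sidecar <- guess
  }
  meta <- NULL
  if (!is.null(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(px_lateral)) px_lateral <- meta$px_lateral_um
    if (is.null(px_axial)) px_axial <- meta$px_axial_um
  }
  if (is.null(px_lateral) || is.null(px_axial)) {
    stop("pixel sizes required: supply `px_lateral`/`px_axial` or a ",
         "sidecar JSON")
  }
  sec <- cross_section(pages[[1]] * 255, pages[[2]] * 255,
                       px_lateral, px_axial)
  if (!is.null(meta$ground_truth)) {
    attr(sec, "ground_truth") <- meta$ground_truth
  }
  sec
}

#' Write a boundary trace and its metrics
#'
#' Writes the traced interface as CSV (`column_x_um`, `depth_z_um`) and its
#' measurements and parameters as a JSON metrics record conforming to the
#' schema shipped in `inst/schema/metrics-schema.json`.
#'
#' @param trace A `boundary_trace`.
#' @param csv_path,json_path Output paths.
#' @param seed Seed recorded in the metrics record (NA when the input was
#'   not simulated).
#' @param extra Optional named list merged into the record (e.g. thickness
#'   or nuclear density results).
#' @return Invisibly, the metrics record.
#' @export
write_trace <- function(trace, csv_path, json_path, seed = NA,
                        extra = NULL) {
  stopifnot(inherits(trace, "boundary_trace"))
  pts <- data.frame(column_x_um = trace$points$x_um,
                    depth_z_um = trace$points$z_um)
  write.csv(pts, csv_path, row.names = FALSE)
  rec <- list(
    schema = "ectishape-metrics/1",
    l_um = trace$l_um,
    L_um = trace$L_um,
    delta_L_um = trace$delta_L_um,
    delta_L_norm = trace$delta_L_norm,
    parameters = trace$params,
    seed = seed
  )
  if (!is.null(extra)) rec <- c(rec, extra)
  jsonlite::write_json(rec, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(rec)
}

#' Read or write a cohort CSV
#'
#' The cohort table has one row per imaged site with columns `site_id`,
#' `group`, `modality`, `delta_linearity` and optionally `thickness_um`
#' (and `nuclear_density_per_100um2`).
#'
#' @param cohort Data frame to write.
#' @param path CSV path.
#' @return `read_cohort_csv` returns the validated data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  need <- c("site_id", "group", "modality", "delta_linearity")
  if (!all(need %in% names(cohort))) {
    stop("cohort table must have columns: ", paste(need, collapse = ", "))
  }
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cohort CSV not found: ", path)
  coh <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "group", "modality", "delta_linearity")
  miss <- setdiff(need, names(coh))
  if (length(miss)) {
    stop("format error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
  if (any(coh$delta_linearity < 0, na.rm = TRUE)) {
    stop("format error in ", path, ": negative delta_linearity")
  }
  coh
}

#' Validate a metrics record against the shipped schema
#'
#' Checks a metrics JSON record (path or parsed list) against the simple
#' field/type schema in `inst/schema/metrics-schema.json`: every required
#' field must be present with the declared type.
#'
#' @param record Path to a JSON file or a named list.
#' @param schema_path Optional alternative schema file.
#' @return `TRUE` invisibly; errors name the offending field.
#' @export
validate_metrics <- function(record, schema_path = NULL) {
  if (is.character(record)) {
    record <- jsonlite::read_json(record, simplifyVector = TRUE)
  }
  if (is.null(schema_path)) {
    schema_path <- system.file("schema", "metrics-schema.json",
                               package = "ectishape")
  }
  schema <- jsonlite::read_json(schema_path, simplifyVector = TRUE)
  for (field in names(schema$required)) {
    if (is.null(record[[field]])) {
      stop("metrics record missing required field `", field, "`")
    }
    type <- schema$required[[field]]
    ok <- switch(type,
      number = is.numeric(record[[field]]),
      string = is.character(record[[field]]),
      object = is.list(record[[field]]),
      TRUE)
    if (!ok) {
      stop("metrics field `", field, "` must be of type ", type)
    }
  }
  invisible(TRUE)
}
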