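# Trial dataset assembly: acquisitions (dense image time series) joined to
# sparse destructive reference measurements, with a treatment-held-out split.

.metadata_cols <- c("microplot_id", "treatment_id", "date", "thermal_time",
                    "camera", "image_path")

new_trial_dataset <- function(acquisitions, references, split = character(),
                              images = NULL, features = NULL,
                              organ_appearance = NULL) {
  ds <- list(acquisitions = acquisitions, references = references,
             split = split, images = images, features = features,
             organ_appearance = organ_appearance)
  class(ds) <- "trial_dataset"
  ds
}

#' @export
print.trial_dataset <- function(x, ...) {
  m <- nrow(x$acquisitions); n <- nrow(x$references)
  cat("wheat trial dataset: m =", m, "acquisitions, n =", n, "references\n")
  cat("  microplots:", length(unique(x$acquisitions$microplot_id)),
      "| treatments:", length(unique(x$acquisitions$treatment_id)),
      "| dates:", length(unique(x$acquisitions$date)), "\n")
  if (length(x$split)) {
    cat("  split:", sum(x$split == "train"), "train /",
        sum(x$split == "val"), "val treatments\n")
  }
  invisible(x)
}

#' Load a trial dataset from metadata and reference CSV files
#'
#' Joins per-acquisition image metadata to the sparse reference measurements
#' on the exact key (`microplot_id`, `date`); no nearest-date matching is
#' attempted, so a reference taken between two acquisition dates is reported
#' as unmatched rather than silently attached to the wrong images.
#'
#' The metadata CSV must provide columns
#' `microplot_id,treatment_id,date,thermal_time,camera,image_path` and the
#' reference CSV `microplot_id,date` plus the [trait_columns()]. Organ
#' `dm_*`/`nupt_*` columns are proportions of the plant total; `nconc_*`
#' columns are absolute percentages. Dates are ISO-8601.
#'
#' @param metadata_csv Path to the acquisition metadata CSV.
#' @param reference_csv Path to the reference measurement CSV.
#' @param image_root Directory against which relative image paths resolve.
#' @return A `trial_dataset` with `m = nrow(acquisitions)` images and
#'   `n` matched references; unmatched reference rows raise a warning that
#'   lists them.
#' @export
load_dataset <- function(metadata_csv, reference_csv, image_root = ".") {
  md <- utils::read.csv(metadata_csv, stringsAsFactors = FALSE)
  rf <- utils::read.csv(reference_csv, stringsAsFactors = FALSE)
  miss <- setdiff(.metadata_cols, names(md))
  if (length(miss))
    stop("metadata CSV missing required columns: ",
         paste(miss, collapse = ", "))
  miss <- setdiff(c("microplot_id", "date", trait_columns()), names(rf))
  if (length(miss))
    stop("reference CSV missing required columns: ",
         paste(miss, collapse = ", "))
  md$date <- as.Date(md$date)
  rf$date <- as.Date(rf$date)
  validate_traits(rf)

  # thermal time must increase with date within each microplot
  for (mp in unique(md$microplot_id)) {
    sub <- md[md$microplot_id == mp, ]
    sub <- sub[!duplicated(sub$date), ]
    sub <- sub[order(sub$date), ]
    if (is.unsorted(sub$thermal_time, strictly = TRUE) && nrow(sub) > 1)
      stop("thermal_time not strictly increasing with date in microplot ", mp)
  }

  md$image_path <- ifelse(md$image_path == "" | is.na(md$image_path), NA,
                          file.path(image_root, md$image_path))
  md$acq_id <- sprintf("%s_%s_%s_%d", md$microplot_id, md$date, md$camera,
                       stats::ave(seq_len(nrow(md)),
                                  paste(md$microplot_id, md$date, md$camera),
                                  FUN = seq_along))

  key_md <- paste(md$microplot_id, md$date)
  key_rf <- paste(rf$microplot_id, rf$date)
  matched <- key_rf %in% key_md
  if (any(!matched))
    warning("reference rows with no matching acquisition dropped: ",
            paste(which(!matched), collapse = ", "))
  rf <- rf[matched, , drop = FALSE]
  tt <- md$thermal_time[match(key_rf[matched], key_md)]
  rf$thermal_time <- tt

  new_trial_dataset(md, rf)
}

#' Write a trial dataset back to CSV files
#'
#' Inverse of [load_dataset()] on the metadata fields: writing then reloading
#' reproduces the acquisition and reference tables.
#'
#' @param ds A `trial_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the two paths written, invisibly.
#' @export
save_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  md <- ds$acquisitions
  md$image_path <- ifelse(is.na(md$image_path), "", basename(md$image_path))
  meta_path <- file.path(dir, "metadata.csv")
  ref_path <- file.path(dir, "reference.csv")
  utils::write.csv(md[.metadata_cols], meta_path, row.names = FALSE)
  rf <- ds$references
  utils::write.csv(rf[c("microplot_id", "date", trait_columns())], ref_path,
                   row.names = FALSE)
  invisible(c(metadata = meta_path, reference = ref_path))
}

#' Assign a treatment-held-out train/validation split
#'
#' Entire treatments (and hence all their microplots and replicate images) go
#' to validation, mirroring the practice of holding out whole fertilization
#' treatments rather than random images, which would leak replicate imagery
#' between splits.
#'
#' @param ds A `trial_dataset`.
#' @param val_treatments Character vector of treatment ids to hold out; may be
#'   empty (everything trains).
#' @return `ds` with `ds$split` set (named `"train"`/`"val"` per treatment);
#'   the achieved validation fraction of references is attached as attribute
#'   `val_fraction`.
#' @export
split_by_treatment <- function(ds, val_treatments) {
  trts <- unique(ds$acquisitions$treatment_id)
  unknown <- setdiff(val_treatments, trts)
  if (length(unknown))
    stop("unknown treatment id(s): ", paste(unknown, collapse = ", "))
  split <- stats::setNames(ifelse(trts %in% val_treatments, "val", "train"),
                           trts)
  ds$split <- split
  ref_trt <- ds$acquisitions$treatment_id[
    match(ds$references$microplot_id, ds$acquisitions$microplot_id)]
  attr(ds, "val_fraction") <-
    if (nrow(ds$references)) mean(split[ref_trt] == "val") else 0
  ds
}

#' Microplots belonging to one side of the split
#' @param ds A split `trial_dataset`.
#' @param side `"train"` or `"val"`.
#' @return Character vector of microplot ids.
#' @export
split_microplots <- function(ds, side = c("train", "val")) {
  side <- match.arg(side)
  if (!length(ds$split)) stop("dataset has no split assigned")
  trts <- names(ds$split)[ds$split == side]
  unique(ds$acquisitions$microplot_id[ds$acquisitions$treatment_id %in% trts])
}

#' Read a canopy image from disk
#'
#' @param path TIFF file path.
#' @param kind `"rgb"` (3-channel, 0-255), `"ms"` (6-band bidirectional
#'   reflectance factor in \[0,1\]; stored uint8 data is rescaled by 1/255,
#'   float values above 1 are clipped and the clip count reported) or
#'   `"height"` (single-channel metric height map, returned as a matrix).
#' @return Numeric array `H x W x 3` (rgb), `H x W x 6` (ms) or `H x W`
#'   matrix (height). For `ms`, attribute `clipped` carries the number of
#'   clipped pixels.
#' @export
read_image <- function(path, kind = c("rgb", "ms", "height")) {
  kind <- match.arg(kind)
  img <- read_tiff(path)
  fmt <- attr(img, "sample_format")
  nc <- dim(img)[3]
  expected <- c(rgb = 3L, ms = 6L, height = 1L)[[kind]]
  if (nc != expected)
    stop(sprintf("%s expects %d band(s)/channel(s), file has %d: %s",
                 kind, expected, nc, path))
  if (kind == "rgb") return(img[, , , drop = FALSE])
  if (kind == "height") return(img[, , 1])
  if (fmt == "uint8") img <- img / 255
  clipped <- sum(img > 1)
  if (clipped > 0) {
    message(clipped, " BRF value(s) > 1 clipped in ", basename(path))
    img[img > 1] <- 1
  }
  img[img < 0] <- 0
  structure(img, clipped = clipped, sample_format = NULL)
}

# Fetch the pixel data for one acquisition row, from the in-memory store if
# present, else from disk.
acquisition_image <- function(ds, acq_id, kind = "ms") {
  if (!is.null(ds$images) && !is.null(ds$images[[acq_id]]))
    return(ds$images[[acq_id]][[kind]])
  row <- ds$acquisitions[ds$acquisitions$acq_id == acq_id, ]
  if (nrow(row) != 1 || is.na(row$image_path))
    stop("no image available for acquisition ", acq_id)
  read_image(row$image_path, kind)
}
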