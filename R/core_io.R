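# Shared domain types and file I/O: inversion-time schedules, quantitative
# maps, label masks, tidy ROI tables and the cohort design.

#' Metrics recognised in quantitative maps and ROI tables
#'
#' `t1_s` is the longitudinal relaxation time in seconds, `r1_per_s` its
#' reciprocal (the relaxation rate, a myelin proxy), `md_mm2_per_s` mean
#' diffusivity, `r_squared` the voxelwise goodness of fit of the
#' inversion-recovery model and `b` the effective inversion coefficient.
#' @format Character vector.
#' @export
MAP_METRICS <- c("t1_s", "r1_per_s", "md_mm2_per_s", "r_squared", "b")

#' Metrics allowed as ROI table measurements
#' @format Character vector.
#' @export
ROI_METRICS <- c("t1_s", "r1_per_s", "md_mm2_per_s")

#' Longitudinal timepoint labels and their age windows (days)
#'
#' The cohort is scanned as newborns and again around three and six months
#' of age; ages in days at scan fall within these windows.
#' @format `TIMEPOINTS` is a character vector; `AGE_WINDOWS` a named list of
#'   `c(min, max)` integer day ranges.
#' @export
TIMEPOINTS <- c("newborn", "3mo", "6mo")

#' @rdname TIMEPOINTS
#' @export
AGE_WINDOWS <- list(
  newborn = c(8L, 37L),
  `3mo`   = c(78L, 106L),
  `6mo`   = c(167L, 195L)
)

HEMISPHERES <- c("left", "right")

#' Inversion-time schedule
#'
#' An ordered set of inversion times (TI, milliseconds) at which the
#' inversion-recovery signal is sampled. At least three TIs are required to
#' identify the three parameters of the signal model.
#'
#' @param times_ms Numeric vector of inversion times in milliseconds;
#'   strictly increasing, all positive, length at least 3.
#' @return A `ti_schedule` object (numeric vector).
#' @examples
#' ti_schedule(c(50, 200, 350))
#' @export
ti_schedule <- function(times_ms) {
  times_ms <- as.numeric(times_ms)
  if (length(times_ms) < 3L) {
    stop("a TI schedule needs at least 3 inversion times", call. = FALSE)
  }
  if (anyNA(times_ms) || any(times_ms <= 0)) {
    stop("inversion times must be positive and non-missing", call. = FALSE)
  }
  if (any(diff(times_ms) <= 0)) {
    stop("inversion times must be strictly increasing", call. = FALSE)
  }
  structure(times_ms, class = "ti_schedule")
}

#' @export
print.ti_schedule <- function(x, ...) {
  cat("TI schedule:", length(x), "inversion times,",
      x[1], "-", x[length(x)], "ms\n")
  invisible(x)
}

as_ti_schedule <- function(x) {
  if (inherits(x, "ti_schedule")) x else ti_schedule(x)
}

#' Quantitative 3D map
#'
#' A 3D grid of voxel values for one metric, with voxel size in mm. Voxels
#' that were not fit (outside the brain or mask) are `NaN`.
#'
#' @param values 3D numeric array.
#' @param metric One of [MAP_METRICS].
#' @param voxel_size_mm Positive numeric length 3, voxel edge lengths in mm.
#' @return A `quantitative_map` object.
#' @export
quantitative_map <- function(values, metric, voxel_size_mm = c(2, 2, 2)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("'values' must be a 3D array", call. = FALSE)
  }
  metric <- match.arg(metric, MAP_METRICS)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0)) {
    stop("'voxel_size_mm' must be 3 positive numbers", call. = FALSE)
  }
  if (metric %in% c("t1_s", "r1_per_s")) {
    finite <- values[is.finite(values)]
    if (length(finite) && any(finite <= 0)) {
      stop(metric, " values must be strictly positive where fit",
           call. = FALSE)
    }
  }
  structure(
    list(values = values, metric = metric, voxel_size_mm = voxel_size_mm),
    class = "quantitative_map"
  )
}

#' @export
print.quantitative_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("quantitative map [%s]: %d x %d x %d voxels (%g x %g x %g mm), %d fit\n",
              x$metric, d[1], d[2], d[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3],
              sum(is.finite(x$values))))
  invisible(x)
}

#' Label mask
#'
#' A set of voxel (or vertex) indices belonging to one labelled region, in a
#' named index space so that masks from different grids are never compared.
#'
#' @param indices Positive integer linear indices (1-based), unique.
#' @param label Region label, e.g. an area code such as `"V1"`.
#' @param space_dim Integer dimensions of the index space (grid) the indices
#'   refer to.
#' @return A `label_mask` object.
#' @export
label_mask <- function(indices, label, space_dim) {
  indices <- as.integer(indices)
  space_dim <- as.integer(space_dim)
  if (anyNA(indices) || any(indices < 1L)) {
    stop("mask indices must be positive integers", call. = FALSE)
  }
  if (anyDuplicated(indices)) {
    stop("mask indices must be unique", call. = FALSE)
  }
  if (any(indices > prod(space_dim))) {
    stop("mask indices exceed the index space", call. = FALSE)
  }
  structure(
    list(indices = sort(indices), label = as.character(label),
         space_dim = space_dim),
    class = "label_mask"
  )
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("label mask '%s': %d voxels in %s space\n", x$label,
              length(x$indices), paste(x$space_dim, collapse = "x")))
  invisible(x)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write a quantitative map as NIfTI with a JSON sidecar
#'
#' The NIfTI container has no field for the metric, so it travels in a JSON
#' sidecar next to the volume (same stem, `.json` extension).
#'
#' @param map A [quantitative_map()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(map, path) {
  stopifnot(inherits(map, "quantitative_map"))
  img <- RNifti::asNifti(map$values)
  RNifti::pixdim(img) <- map$voxel_size_mm
  RNifti::writeNifti(img, path, datatype = "double")
  jsonlite::write_json(
    list(metric = map$metric, voxel_size_mm = map$voxel_size_mm),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a quantitative map written by [write_volume()]
#'
#' @param path Path to a 3D NIfTI volume; the metric is taken from the JSON
#'   sidecar.
#' @return A [quantitative_map()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such volume: ", path, call. = FALSE)
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    stop("missing JSON sidecar for ", path, ": expected ", sc, call. = FALSE)
  }
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$metric)) {
    stop("sidecar ", sc, " lacks a 'metric' entry", call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  if (length(dim(vals)) != 3L) {
    stop("expected a 3D volume, got ", length(dim(vals)), "D; ",
         "use read_ir_series() for 4D inversion-recovery data", call. = FALSE)
  }
  quantitative_map(vals, meta$metric,
                   voxel_size_mm = RNifti::pixdim(img)[1:3])
}

#' Write a 4D inversion-recovery series with its TI schedule
#'
#' The 4th dimension indexes inversion times; the schedule is stored in a
#' JSON sidecar under the key `inversion_times_ms`.
#'
#' @param signals 4D numeric array `(x, y, z, TI)` of magnitude signals.
#' @param schedule A [ti_schedule()] with one entry per 4th-dimension frame.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param voxel_size_mm Voxel size in mm.
#' @return `path`, invisibly.
#' @export
write_ir_series <- function(signals, schedule, path, voxel_size_mm = c(2, 2, 2)) {
  schedule <- as_ti_schedule(schedule)
  if (length(dim(signals)) != 4L) {
    stop("'signals' must be a 4D array (x, y, z, TI)", call. = FALSE)
  }
  if (dim(signals)[4] != length(schedule)) {
    stop("4th dimension (", dim(signals)[4], " frames) does not match the ",
         "TI schedule (", length(schedule), " times)", call. = FALSE)
  }
  img <- RNifti::asNifti(signals)
  RNifti::pixdim(img) <- c(voxel_size_mm, 1)
  RNifti::writeNifti(img, path, datatype = "double")
  jsonlite::write_json(
    list(inversion_times_ms = as.numeric(schedule)),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a 4D inversion-recovery series and its TI schedule
#'
#' @param path Path to a 4D NIfTI volume with a JSON sidecar carrying
#'   `inversion_times_ms`.
#' @return A list with `signals` (4D array), `schedule` ([ti_schedule()])
#'   and `voxel_size_mm`.
#' @export
read_ir_series <- function(path) {
  if (!file.exists(path)) stop("no such volume: ", path, call. = FALSE)
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    stop("missing TI sidecar for ", path, ": expected ", sc,
         " with key 'inversion_times_ms'", call. = FALSE)
  }
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$inversion_times_ms)) {
    stop("sidecar ", sc, " lacks 'inversion_times_ms'", call. = FALSE)
  }
  schedule <- ti_schedule(meta$inversion_times_ms)
  img <- RNifti::readNifti(path)
  signals <- array(as.numeric(img), dim = dim(img))
  if (length(dim(signals)) != 4L) {
    stop("expected a 4D series, got ", length(dim(signals)), "D", call. = FALSE)
  }
  if (dim(signals)[4] != length(schedule)) {
    stop("volume has ", dim(signals)[4], " frames but sidecar ", sc,
         " lists ", length(schedule), " inversion times", call. = FALSE)
  }
  list(signals = signals, schedule = schedule,
       voxel_size_mm = RNifti::pixdim(img)[1:3])
}

ROI_COLUMNS <- c("infant_id", "age_days", "timepoint", "hemisphere",
                 "area", "metric", "value")

roi_key <- function(tab) {
  paste(tab$infant_id, tab$timepoint, tab$hemisphere, tab$area, tab$metric,
        sep = "|")
}

#' Validate a tidy ROI measurement table
#'
#' One row per (infant, timepoint, hemisphere, area, metric); `value` holds
#' the ROI mean of that metric, `age_days` the infant's age at scan.
#'
#' @param tab A data.frame with columns `infant_id`, `age_days`, `timepoint`,
#'   `hemisphere`, `area`, `metric`, `value`.
#' @return The validated data.frame (types coerced).
#' @export
validate_roi_table <- function(tab) {
  missing_cols <- setdiff(ROI_COLUMNS, names(tab))
  if (length(missing_cols)) {
    stop("ROI table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  tab <- tab[ROI_COLUMNS]
  tab$infant_id <- as.character(tab$infant_id)
  tab$age_days <- as.integer(tab$age_days)
  tab$timepoint <- as.character(tab$timepoint)
  tab$hemisphere <- as.character(tab$hemisphere)
  tab$area <- as.character(tab$area)
  tab$metric <- as.character(tab$metric)
  tab$value <- as.numeric(tab$value)
  if (any(is.na(tab$age_days)) || any(tab$age_days <= 0L)) {
    stop("age_days must be positive integers", call. = FALSE)
  }
  bad_tp <- setdiff(unique(tab$timepoint), TIMEPOINTS)
  if (length(bad_tp)) {
    stop("unknown timepoint code(s): ", paste(bad_tp, collapse = ", "),
         call. = FALSE)
  }
  bad_hemi <- setdiff(unique(tab$hemisphere), HEMISPHERES)
  if (length(bad_hemi)) {
    stop("unknown hemisphere code(s): ", paste(bad_hemi, collapse = ", "),
         call. = FALSE)
  }
  bad_metric <- setdiff(unique(tab$metric), ROI_METRICS)
  if (length(bad_metric)) {
    stop("unknown metric code(s): ", paste(bad_metric, collapse = ", "),
         call. = FALSE)
  }
  keys <- roi_key(tab)
  dup <- duplicated(keys)
  if (any(dup)) {
    stop("duplicate ROI table key: ", keys[which(dup)[1]], call. = FALSE)
  }
  rownames(tab) <- NULL
  tab
}

#' Read / write an ROI table as TSV
#'
#' Tables are tab-separated with a fixed lowercase header and full float
#' precision, so a write/read round trip is lossless.
#'
#' @param path File path.
#' @return `read_roi_table()` returns the validated data.frame;
#'   `write_roi_table()` returns `path` invisibly.
#' @export
read_roi_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character",
                           check.names = FALSE)
  if (!identical(names(tab), ROI_COLUMNS)) {
    stop("ROI table header must be exactly: ",
         paste(ROI_COLUMNS, collapse = ", "), call. = FALSE)
  }
  validate_roi_table(tab)
}

#' @param tab An ROI table (see [validate_roi_table()]).
#' @rdname read_roi_table
#' @export
write_roi_table <- function(tab, path) {
  tab <- validate_roi_table(tab)
  out <- tab
  out$value <- sprintf("%.17g", out$value)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Longitudinal cohort design
#'
#' Which infants are scanned at which timepoints, and the age window (in
#' days) of each timepoint. The default mirrors the study design: 13 infants,
#' three timepoints, 10 infants per timepoint, 7 scanned at all three.
#'
#' @param participation Logical matrix, infants x timepoints; column names
#'   must be the timepoint codes.
#' @param age_windows Named list of `c(min, max)` integer day windows per
#'   timepoint.
#' @return A `cohort_design` object.
#' @seealso [default_cohort_design()]
#' @export
cohort_design <- function(participation, age_windows = AGE_WINDOWS) {
  if (!is.matrix(participation) || !is.logical(participation)) {
    stop("'participation' must be a logical matrix", call. = FALSE)
  }
  if (is.null(colnames(participation)) ||
      !all(colnames(participation) %in% TIMEPOINTS)) {
    stop("participation columns must be named with timepoint codes",
         call. = FALSE)
  }
  if (is.null(rownames(participation))) {
    rownames(participation) <- sprintf("infant%02d", seq_len(nrow(participation)))
  }
  if (any(colSums(participation) == 0L)) {
    stop("every timepoint must have at least one participating infant",
         call. = FALSE)
  }
  if (!all(colnames(participation) %in% names(age_windows))) {
    stop("age window missing for some timepoint", call. = FALSE)
  }
  structure(
    list(participation = participation,
         n_infants = nrow(participation),
         age_windows = age_windows),
    class = "cohort_design"
  )
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf("cohort design: %d infants, %d timepoints (%s per timepoint)\n",
              x$n_infants, ncol(x$participation),
              paste(colSums(x$participation), collapse = "/")))
  invisible(x)
}

#' The study's default cohort design
#'
#' 13 infants over three timepoints (newborn, 3 months, 6 months) with 10
#' participating at each timepoint; seven infants complete all three, three
#' complete two sessions and three a single session.
#'
#' @return A [cohort_design()].
#' @export
default_cohort_design <- function() {
  p <- matrix(FALSE, nrow = 13, ncol = 3,
              dimnames = list(sprintf("infant%02d", 1:13), TIMEPOINTS))
  p[1:7, ] <- TRUE                     # longitudinal infants, all sessions
  p["infant08", c("newborn", "3mo")] <- TRUE
  p["infant09", c("3mo", "6mo")] <- TRUE
  p["infant10", c("newborn", "6mo")] <- TRUE
  p["infant11", "newborn"] <- TRUE
  p["infant12", "3mo"] <- TRUE
  p["infant13", "6mo"] <- TRUE
  cohort_design(p)
}
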