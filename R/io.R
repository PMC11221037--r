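# File interfaces: MetaImage (MHD + RAW) for voxel images, a columnar binary
# + JSON header for phase spaces, CSV for curves, JSON for reports.

mhd_types <- c(double = "MET_DOUBLE", float = "MET_FLOAT", uchar = "MET_UCHAR")

write_mhd_array <- function(x, origin, spacing, path, type = "double") {
  stopifnot(type %in% names(mhd_types))
  raw_name <- paste0(sub("\\.mhd$", "", basename(path)), ".raw")
  dims <- dim(x)
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False", "CompressedData = False",
           paste("DimSize =", paste(dims, collapse = " ")),
           paste("ElementSpacing =", paste(spacing, collapse = " ")),
           paste("Offset =", paste(origin, collapse = " ")),
           paste("ElementType =", mhd_types[[type]]),
           paste("ElementDataFile =", raw_name))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  if (type == "uchar") {
    writeBin(as.integer(x), con, size = 1)
  } else {
    writeBin(as.numeric(x), con,
             size = if (type == "float") 4L else 8L)
  }
  invisible(path)
}

read_mhd_array <- function(path) {
  hdr <- readLines(path)
  get1 <- function(key) {
    ln <- grep(paste0("^", key, " *="), hdr, value = TRUE)[1]
    trimws(sub("^[^=]*=", "", ln))
  }
  dims <- as.integer(strsplit(get1("DimSize"), " +")[[1]])
  spacing <- as.numeric(strsplit(get1("ElementSpacing"), " +")[[1]])
  origin <- as.numeric(strsplit(get1("Offset"), " +")[[1]])
  type <- get1("ElementType")
  raw_path <- file.path(dirname(path), get1("ElementDataFile"))
  n <- prod(dims)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  x <- switch(type,
              MET_DOUBLE = readBin(con, "numeric", n, size = 8),
              MET_FLOAT = readBin(con, "numeric", n, size = 4),
              MET_UCHAR = as.numeric(readBin(con, "integer", n, size = 1,
                                             signed = FALSE)),
              stop("unsupported element type: ", type))
  list(data = array(x, dim = dims), origin = origin, spacing = spacing)
}

#' Write a voxel phantom as MetaImage + JSON sidecar
#'
#' Writes `<stem>_density.mhd/.raw`, `<stem>_material.mhd/.raw` and
#' `<stem>.json` (material catalog).
#'
#' @param grid a [voxel_grid()].
#' @param stem output path stem.
#' @export
write_voxel_grid <- function(grid, stem) {
  write_mhd_array(grid$density, grid$origin, grid$spacing,
                  paste0(stem, "_density.mhd"))
  write_mhd_array(grid$material - 1L, grid$origin, grid$spacing,
                  paste0(stem, "_material.mhd"), type = "uchar")
  jsonlite::write_json(list(materials = grid$materials),
                       paste0(stem, ".json"), dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' Read a voxel phantom written by [write_voxel_grid()]
#' @param stem path stem.
#' @export
read_voxel_grid <- function(stem) {
  d <- read_mhd_array(paste0(stem, "_density.mhd"))
  m <- read_mhd_array(paste0(stem, "_material.mhd"))
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  voxel_grid(d$data, array(as.integer(m$data) + 1L, dim = dim(m$data)),
             d$origin, d$spacing,
             materials = as.data.frame(side$materials))
}

#' Write a dose grid as MetaImage (dose + uncertainty) + JSON manifest
#' @param dose a `dose_grid`.
#' @param stem output path stem.
#' @export
write_dose_grid <- function(dose, stem) {
  write_mhd_array(dose$dose, dose$origin, dose$spacing,
                  paste0(stem, "_dose.mhd"))
  write_mhd_array(dose$rel_uncertainty, dose$origin, dose$spacing,
                  paste0(stem, "_uncertainty.mhd"))
  jsonlite::write_json(list(histories = dose$histories,
                            batches = dose$batches,
                            manifest = dose$manifest),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(stem)
}

#' Read a dose grid written by [write_dose_grid()]
#' @param stem path stem.
#' @export
read_dose_grid <- function(stem) {
  d <- read_mhd_array(paste0(stem, "_dose.mhd"))
  u <- read_mhd_array(paste0(stem, "_uncertainty.mhd"))
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  structure(list(origin = d$origin, spacing = d$spacing,
                 dims = dim(d$data), dose = d$data,
                 rel_uncertainty = u$data,
                 histories = side$histories, batches = side$batches,
                 batch_doses = NULL, manifest = side$manifest),
            class = "dose_grid")
}

#' Write a structure mask as a MetaImage label image
#' @param mask a [structure_mask()].
#' @param path output `.mhd` path.
#' @export
write_structure_mask <- function(mask, path) {
  write_mhd_array(array(as.integer(mask$mask), dim = mask$dims),
                  mask$origin, mask$spacing, path, type = "uchar")
}

#' Write a phase space (columnar binary + JSON header)
#'
#' Columns energy, x, y, u, v, w, weight as little-endian doubles in
#' `<stem>.psb`; counts, plane, collimator and provenance in `<stem>.json`.
#'
#' @param ps a `phase_space`.
#' @param stem output path stem.
#' @export
write_phase_space <- function(ps, stem) {
  cols <- c("energy", "x", "y", "u", "v", "w", "weight")
  con <- file(paste0(stem, ".psb"), "wb")
  on.exit(close(con))
  for (cl in cols) writeBin(as.numeric(ps$particles[[cl]]), con, size = 8)
  jsonlite::write_json(list(n = nrow(ps$particles), columns = cols,
                            plane_z = ps$plane_z, collimator = ps$collimator,
                            provenance = ps$provenance),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(stem)
}

#' Read a phase space written by [write_phase_space()]
#' @param stem path stem.
#' @export
read_phase_space <- function(stem) {
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  con <- file(paste0(stem, ".psb"), "rb")
  on.exit(close(con))
  p <- as.data.frame(lapply(side$columns, function(cl)
    readBin(con, "numeric", side$n, size = 8)))
  names(p) <- side$columns
  phase_space(p, plane_z = side$plane_z, collimator = side$collimator,
              provenance = as.list(side$provenance))
}

#' Write a curve (2-column CSV)
#' @param curve data.frame of two columns (position/depth mm, value).
#' @param path output path.
#' @export
write_curve_csv <- function(curve, path) {
  write.csv(curve, path, row.names = FALSE)
  invisible(path)
}

#' Read a curve CSV
#' @param path input path.
#' @export
read_curve_csv <- function(path) read.csv(path)

#' Serialize a comparison report to JSON
#'
#' Writes the gamma and DVH tables and the run manifests (not the dose
#' arrays; write those with [write_dose_grid()]).
#'
#' @param report a `comparison_report`.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(list(gamma = report$gamma, dvh = report$dvh,
                            manifests = report$manifests),
                       path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, force = TRUE, null = "null")
  invisible(path)
}

#' Read a comparison report written by [write_report()]
#' @param path input path.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(gamma = as.data.frame(x$gamma),
                 dvh = if (is.null(x$dvh)) NULL else as.data.frame(x$dvh),
                 manifests = x$manifests, doses = NULL),
            class = "comparison_report")
}
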