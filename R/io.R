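## File interfaces: NIfTI volumes, atlas label maps, cohort CSV.

#' Read / write parameter maps as NIfTI
#'
#' Maps are written one file per parameter (`cbf.nii.gz`, `att.nii.gz`,
#' `kw.nii.gz`, `flags.nii.gz`, `mask.nii.gz`); the affine/header of
#' `reference` (a NIfTI file or image) is preserved when given.
#'
#' @param maps a `parameter_maps` object from [quantify_series()].
#' @param dir output directory (created if needed).
#' @param reference optional NIfTI image or path whose geometry is copied.
#' @return [write_parameter_maps()] returns the written paths invisibly;
#'   [read_parameter_maps()] returns a `parameter_maps` object.
#' @export
write_parameter_maps <- function(maps, dir, reference = NULL) {
  stopifnot(inherits(maps, "parameter_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  template <- if (!is.null(reference)) RNifti::asNifti(reference) else NULL
  paths <- character(0)
  for (nm in c("cbf", "att", "kw")) {
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    img <- if (is.null(template)) RNifti::asNifti(maps[[nm]])
           else RNifti::asNifti(maps[[nm]], reference = template)
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  for (nm in c("flags", "mask")) {
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    vol <- maps[[nm]] + 0L
    img <- if (is.null(template)) RNifti::asNifti(vol)
           else RNifti::asNifti(vol, reference = template)
    RNifti::writeNifti(img, p, datatype = "int32")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_parameter_maps
#' @export
read_parameter_maps <- function(dir) {
  rd <- function(nm) {
    arr <- as.array(RNifti::readNifti(file.path(dir, paste0(nm, ".nii.gz"))))
    array(as.vector(arr), dim(arr))
  }
  cbf <- rd("cbf"); att <- rd("att"); kw <- rd("kw")
  flags <- array(as.integer(rd("flags")), dim(cbf))
  mask <- array(as.integer(rd("mask")) != 0L, dim(cbf))
  cbf[!mask] <- NA_real_; att[!mask] <- NA_real_; kw[!mask] <- NA_real_
  structure(list(cbf = cbf, att = att, kw = kw, flags = flags, mask = mask,
                 log = c(n_missing = sum(has_flag(flags, "missing")),
                         n_clamp_lo = sum(has_flag(flags, "clamp_lo")),
                         n_clamp_hi = sum(has_flag(flags, "clamp_hi")),
                         n_saturated = sum(has_flag(flags, "saturated")),
                         n_clipped = sum(has_flag(flags, "clipped")))),
            class = "parameter_maps")
}

#' Read an integer atlas volume and its label table
#'
#' @param nifti_path path to an integer-labeled NIfTI volume.
#' @param labels_path tab-separated table with columns `label` (integer)
#'   and `name`.
#' @return A `roi_set`, see [roi_set()].
#' @export
read_atlas <- function(nifti_path, labels_path) {
  arr <- as.array(RNifti::readNifti(nifti_path))
  atlas <- array(as.integer(round(as.vector(arr))), dim(arr))
  tab <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
  labels <- stats::setNames(as.integer(tab$label), tab$name)
  roi_set(atlas, labels)
}

#' Write / read a cohort table as CSV with a units header row
#'
#' The first line is the column names, the second a `#units` comment row
#' carrying the unit tag of each column, then the data.
#'
#' @param cohort a cohort `data.frame` (see [build_cohort_table()]).
#' @param path output path.
#' @return [write_cohort()] returns `path` invisibly; [read_cohort()]
#'   returns the cohort `data.frame` with its `units` attribute restored.
#' @export
write_cohort <- function(cohort, path) {
  units <- attr(cohort, "units")
  if (is.null(units)) units <- stats::setNames(rep("", ncol(cohort)),
                                               names(cohort))
  units <- units[names(cohort)]
  units[is.na(units)] <- ""
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(cohort), collapse = ","), con)
  writeLines(paste0("#units,", paste(units[-1], collapse = ",")), con)
  utils::write.table(cohort, con, sep = ",", row.names = FALSE,
                     col.names = FALSE, qmethod = "double")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  header <- readLines(path, n = 2L)
  cols <- strsplit(header[1], ",")[[1]]
  units <- strsplit(header[2], ",")[[1]]
  df <- utils::read.csv(path, skip = 2L, header = FALSE,
                        stringsAsFactors = FALSE)
  names(df) <- cols
  units[1] <- ""
  attr(df, "units") <- stats::setNames(units, cols)
  df
}
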