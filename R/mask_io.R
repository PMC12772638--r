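#' Read a label volume from NIfTI and canonicalize it
#'
#' Reads a segmentation mask (label 1 = intrameatal, label 2 = extrameatal),
#' reorients it to the canonical RAS frame so that the third array axis is
#' inferior-superior, and validates labels and spacing. Voxel values within
#' 1e-6 of an integer are rounded; any other value, or a label outside
#' \{0, 1, 2\} (after optional remapping), is an error.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param labelMap Optional named integer vector remapping the file's label
#'   encoding onto the canonical one, e.g. `c("3" = 1, "4" = 2)`. Unmapped
#'   non-zero labels remain and must already be canonical.
#' @return A [LabeledVolume-class] in the canonical frame.
#' @export
readLabeledVolume <- function(path, labelMap = NULL) {
  if (!file.exists(path))
    stop(sprintf("mask file not found: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop(sprintf("not a readable NIfTI file: %s (%s)",
                                 path, conditionMessage(e))))
  img <- .canonicalize(img)
  # pixdim is float32 on disk; snap to micrometre precision so spacing
  # round-trips (sub-um voxel spacing is physically meaningless)
  spacing <- round(RNifti::pixdim(img)[1:3], 6)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop(sprintf("degenerate voxel spacing in %s", path))
  a <- as.array(img)
  if (length(dim(a)) == 4L && dim(a)[4L] == 1L) a <- a[, , , 1L, drop = TRUE]
  if (length(dim(a)) != 3L)
    stop(sprintf("expected a 3D volume in %s", path))
  r <- round(a)
  if (any(abs(a - r) > 1e-6))
    stop(sprintf("non-integer voxel values in %s", path))
  lab <- array(as.integer(r), dim(a))
  if (!is.null(labelMap)) {
    from <- as.integer(names(labelMap))
    to <- as.integer(labelMap)
    out <- lab
    for (k in seq_along(from)) out[lab == from[k]] <- to[k]
    lab <- out
  }
  bad <- setdiff(unique(as.vector(lab)), c(0L, 1L, 2L))
  if (length(bad))
    stop(sprintf("unknown label value(s) %s in %s",
                 paste(bad, collapse = ", "), path))
  LabeledVolume(lab, spacing = as.numeric(spacing), orientation = "RAS")
}

# Reorient to RAS where the image carries an xform; images without one are
# taken as already canonical (RNifti reports them as RAS).
.canonicalize <- function(img) {
  withCallingHandlers(
    {
      if (!identical(RNifti::orientation(img), "RAS"))
        RNifti::orientation(img) <- "RAS"
      img
    },
    warning = function(w) {
      if (grepl("cannot be reoriented", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
}

#' Write a LabeledVolume to NIfTI
#'
#' Writes the canonical label array with its spacing and an RAS xform, so a
#' subsequent [readLabeledVolume()] round-trips labels and spacing exactly.
#'
#' @param vol A [LabeledVolume-class].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeLabeledVolume <- function(vol, path) {
  stopifnot(is(vol, "LabeledVolume"))
  img <- RNifti::asNifti(vol@labels)
  RNifti::pixdim(img) <- vol@spacing
  m <- diag(c(vol@spacing, 1))
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Read a timeline manifest
#'
#' Parses a CSV or JSON manifest listing one imaging session per row with
#' columns/keys `patient_id`, `date` (ISO-8601), `status` ("preoperative",
#' "postoperative" or "post-SRS"), `mask_path`, and optionally `image_path`
#' and `decision`. Sessions are grouped per patient and sorted by date;
#' `months_since_index` is the day count from the index (earliest) session
#' divided by the mean month length of 30.44 days.
#'
#' Rows with an unparseable date, a duplicate (patient, date) pair, or a
#' missing mask file are collected and dropped with a warning - unless the
#' affected row is (or should have been) the patient's index session, in
#' which case the manifest is rejected.
#'
#' @param path Path to a `.csv` or `.json` manifest. Relative mask/image
#'   paths are resolved against the manifest's directory.
#' @return Named list of [PatientTimeline-class], one per patient, sorted by
#'   patient id.
#' @export
readTimelineManifest <- function(path) {
  if (!file.exists(path))
    stop(sprintf("manifest not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  rows <- if (ext == "json") {
    df <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    as.data.frame(df, stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  req <- c("patient_id", "date", "status", "mask_path")
  if (!all(req %in% names(rows)))
    stop(sprintf("manifest must have columns: %s", paste(req, collapse = ", ")))
  if (is.null(rows$image_path)) rows$image_path <- NA_character_
  if (is.null(rows$decision)) rows$decision <- NA_character_
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(is.na(p) | p == "" | grepl("^(/|[A-Za-z]:)", p), p,
           file.path(base, p))
  }
  rows$mask_path <- resolve(rows$mask_path)
  rows$image_path <- resolve(rows$image_path)

  parsed <- as.Date(rows$date, format = "%Y-%m-%d")
  errs <- character()
  bad <- logical(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    if (is.na(parsed[i])) {
      errs <- c(errs, sprintf("row %d: unparseable date '%s'", i, rows$date[i]))
      bad[i] <- TRUE
    } else if (!file.exists(rows$mask_path[i])) {
      errs <- c(errs, sprintf("row %d: missing mask file '%s'", i,
                              rows$mask_path[i]))
      bad[i] <- TRUE
    }
  }
  key <- paste(rows$patient_id, rows$date)
  dup <- duplicated(key)
  if (any(dup & !bad)) {
    for (i in which(dup & !bad))
      errs <- c(errs, sprintf("row %d: duplicate session (%s, %s)", i,
                              rows$patient_id[i], rows$date[i]))
    bad <- bad | dup
  }
  # a bad row that would have been a patient's earliest session invalidates
  # the index -> reject
  for (pid in unique(rows$patient_id)) {
    sel <- rows$patient_id == pid
    if (all(bad[sel]))
      stop(sprintf("manifest rejected: no valid session for patient '%s'\n%s",
                   pid, paste(errs, collapse = "\n")))
    badDates <- parsed[sel & bad]
    goodMin <- min(parsed[sel & !bad])
    if (any(!is.na(badDates) & badDates < goodMin) ||
        any(is.na(parsed[sel & bad])))
      stop(sprintf(
        "manifest rejected: index session invalid for patient '%s'\n%s",
        pid, paste(errs, collapse = "\n")))
  }
  if (length(errs))
    warning(sprintf("dropped %d manifest row(s):\n%s", sum(bad),
                    paste(errs, collapse = "\n")))
  rows <- rows[!bad, , drop = FALSE]
  parsed <- parsed[!bad]

  out <- list()
  for (pid in sort(unique(rows$patient_id))) {
    sel <- which(rows$patient_id == pid)
    ord <- sel[order(parsed[sel])]
    d <- parsed[ord]
    s <- data.frame(
      session_date = d,
      months_since_index = as.numeric(d - d[1L]) / 30.44,
      operative_status = rows$status[ord],
      mask_path = rows$mask_path[ord],
      image_path = rows$image_path[ord],
      decision_label = rows$decision[ord],
      stringsAsFactors = FALSE
    )
    out[[pid]] <- new("PatientTimeline", patientId = pid, sessions = s)
  }
  out
}
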