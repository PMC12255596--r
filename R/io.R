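sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

#' Write a volume, label map or echo series as NIfTI-1
#'
#' Volumes are written as float NIfTI with the voxel size in the header;
#' label maps as int32 with their legend in a JSON sidecar; echo series as a
#' 4-D NIfTI with echo times (ms) in the sidecar.
#'
#' @param x a [susceptibility_volume()], [field_volume()], [label_map()] or
#'   [echo_series()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return the path, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, c("susceptibility_volume", "field_volume"))) {
    img <- RNifti::asNifti(x$values)
    RNifti::pixdim(img) <- x$voxel_size
    RNifti::writeNifti(img, path, datatype = "double")
  } else if (inherits(x, "label_map")) {
    arr <- x$labels
    img <- RNifti::asNifti(arr)
    RNifti::writeNifti(img, path, datatype = "int32")
    jsonlite::write_json(list(type = "label_map",
                              legend = as.list(x$legend)),
                         sidecar_path(path), auto_unbox = TRUE)
  } else if (inherits(x, "echo_series")) {
    img <- RNifti::asNifti(x$magnitudes)
    RNifti::writeNifti(img, path, datatype = "double")
    jsonlite::write_json(list(type = "echo_series",
                              echo_times_ms = x$echo_times),
                         sidecar_path(path), auto_unbox = TRUE)
  } else stop("don't know how to write objects of class ",
              paste(class(x), collapse = "/"))
  invisible(path)
}

#' Read a NIfTI-1 volume, label map or echo series
#'
#' 4-D images require a JSON sidecar carrying `echo_times_ms` and load as an
#' [echo_series()]. 3-D images load as a [label_map()] when the sidecar
#' declares one or the file uses an integer datatype (with an automatic
#' legend when none is stored), and as a [susceptibility_volume()]
#' otherwise.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return a `susceptibility_volume`, `label_map` or `echo_series`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  side <- sidecar_path(path)
  meta <- if (file.exists(side)) jsonlite::read_json(side) else NULL
  if (length(d) == 4L) {
    if (is.null(meta$echo_times_ms))
      stop("4-D image needs a JSON sidecar with echo_times_ms: ", side)
    return(echo_series(array(as.numeric(img), d),
                       unlist(meta$echo_times_ms)))
  }
  if (length(d) != 3L)
    stop("expected a 3-D or 4-D image, got ", length(d), " dimensions")
  vx <- RNifti::pixdim(img)[1:3]
  hdr <- RNifti::niftiHeader(img)
  is_int <- hdr$datatype %in% c(2L, 4L, 8L, 256L, 512L, 768L)
  if (identical(meta$type, "label_map") ||
      (is_int && !identical(meta$type, "susceptibility_volume"))) {
    arr <- array(as.integer(img), d)
    legend <- if (!is.null(meta$legend)) unlist(meta$legend) else {
      ids <- sort(unique(as.vector(arr)))
      ids <- ids[ids != 0L]
      setNames(paste0("roi_", ids), as.character(ids))
    }
    return(label_map(arr, legend))
  }
  susceptibility_volume(array(as.numeric(img), d), voxel_size = vx)
}

#' Write a cohort table as CSV
#'
#' @param cohort data.frame from [simulate_cohort()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' @param path CSV path with `subject_id`, `group`, `age` and `<roi>_mean`
#'   columns.
#' @return data.frame with `group` as a factor.
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "age")
  miss <- setdiff(need, names(out))
  if (length(miss)) stop("cohort CSV lacks column(s): ",
                         paste(miss, collapse = ", "))
  out$group <- factor(out$group, levels = unique(out$group))
  out
}

fmt_num <- function(x) {
  ifelse(is.na(x), "", sprintf("%.10g", x))
}

report_frame <- function(report) {
  if (inherits(report, "group_stat_report")) {
    an <- report$anova
    vc <- report$variance_change
    out <- merge(an, vc, by = "roi", sort = FALSE)
    pairs <- unique(paste0("p_", report$tukey$group1, "_",
                           report$tukey$group2))
    for (p in pairs) out[[p]] <- NA_real_
    if (nrow(report$tukey)) for (i in seq_len(nrow(report$tukey))) {
      tk <- report$tukey[i, ]
      out[out$roi == tk$roi, paste0("p_", tk$group1, "_", tk$group2)] <- tk$p
    }
    out$strategy <- report$strategy
    out[, c("strategy", setdiff(names(out), "strategy"))]
  } else if (inherits(report, "accuracy_table")) {
    counts <- rbind(report$counts, Sum = report$sums)
    data.frame(roi = rownames(counts), counts, row.names = NULL,
               check.names = FALSE)
  } else if (is.data.frame(report)) {
    report
  } else stop("unsupported report class: ",
              paste(class(report), collapse = "/"))
}

#' Write an analysis report as deterministic CSV
#'
#' Group-statistics reports flatten to one row per ROI (F, p, variance
#' change, pairwise Tukey p columns, blank where the ANOVA gate was not
#' passed); accuracy tables to the ROI x strategy count matrix plus a `Sum`
#' row; plain data frames (e.g. theory scans) are written as-is. Numeric
#' cells are formatted to 10 significant digits, so identical inputs yield
#' byte-identical files.
#'
#' @param report a `group_stat_report`, `accuracy_table`, or data.frame.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_report <- function(report, path) {
  df <- report_frame(report)
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- fmt_num(df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
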