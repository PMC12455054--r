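# On-disk representations: LFP sessions, BOLD series, NIfTI VOI extraction,
# result tables.
#
# Native LFP container: a plain-text trace file with a `# key: value` header
# (sample_rate, t0, free-form meta) followed by one voltage per line, plus a
# sibling `<stem>_events.csv` table (event_type, time_s) holding volume
# triggers and stimulation pulses. Values are written with 17 significant
# digits so a write/read cycle is bit-exact for doubles.

events_path_for <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_events.csv")
}

#' Write an LFP recording to the native text container
#'
#' @param rec An [lfp_recording].
#' @param path Trace file path; the event table is written next to it as
#'   `<stem>_events.csv`.
#' @return `path`, invisibly.
#' @seealso [read_lfp()]
#' @export
write_lfp <- function(rec, path) {
  stopifnot(inherits(rec, "lfp_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# sample_rate: %.17g", rec$sample_rate),
    sprintf("# t0: %.17g", rec$t0),
    vapply(names(rec$meta), function(k)
      sprintf("# meta_%s: %s", k, as.character(rec$meta[[k]])), character(1))
  ), con)
  writeLines(sprintf("%.17g", rec$samples), con)
  ev <- rbind(
    data.frame(event_type = rep("volume_trigger", length(rec$volume_triggers)),
               time_s = rec$volume_triggers),
    data.frame(event_type = rep("stim_pulse", length(rec$stim_pulses)),
               time_s = rec$stim_pulses))
  utils::write.csv(ev, events_path_for(path), row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an LFP recording from the native text container
#'
#' Parses the `# key: value` header (which must declare `sample_rate`), the
#' voltage column, and the sibling event table if present. The result is
#' validated: a missing sample rate is a format error and non-monotone
#' volume triggers a validation error; files are never silently coerced.
#'
#' @param path Trace file path.
#' @param dialect Container dialect; only `"csv"` (the delimited-text native
#'   format) is supported.
#' @return An [lfp_recording].
#' @export
read_lfp <- function(path, dialect = c("csv", "hdf5")) {
  dialect <- match.arg(dialect)
  if (dialect == "hdf5")
    stop("the hdf5 dialect is not available in this build; ",
         "use the delimited-text container", call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  is_hdr <- grepl("^#", lines)
  n_hdr <- if (any(!is_hdr)) which(!is_hdr)[1L] - 1L else length(lines)
  hdr <- lines[seq_len(n_hdr)]
  kv <- regmatches(hdr, regexec("^#\\s*([^:]+):\\s*(.*)$", hdr))
  keys <- vapply(kv, function(m) if (length(m) == 3L) trimws(m[2L]) else NA_character_,
                 character(1))
  vals <- vapply(kv, function(m) if (length(m) == 3L) trimws(m[3L]) else NA_character_,
                 character(1))
  if (!"sample_rate" %in% keys)
    stop("format error: header does not declare sample_rate", call. = FALSE)
  sample_rate <- as.numeric(vals[match("sample_rate", keys)])
  if (!is.finite(sample_rate))
    stop("format error: sample_rate is not numeric", call. = FALSE)
  t0 <- if ("t0" %in% keys) as.numeric(vals[match("t0", keys)]) else 0
  meta_idx <- grep("^meta_", keys)
  meta <- as.list(vals[meta_idx])
  names(meta) <- sub("^meta_", "", keys[meta_idx])
  samples <- as.numeric(lines[!is_hdr])
  if (anyNA(samples))
    stop("format error: non-numeric sample values", call. = FALSE)
  vt <- numeric(0); sp <- numeric(0)
  epath <- events_path_for(path)
  if (file.exists(epath)) {
    ev <- utils::read.csv(epath, stringsAsFactors = FALSE)
    vt <- ev$time_s[ev$event_type == "volume_trigger"]
    sp <- ev$time_s[ev$event_type == "stim_pulse"]
  }
  lfp_recording(samples, sample_rate, t0 = t0,
                volume_triggers = vt, stim_pulses = sp, meta = meta)
}

#' Write a BOLD series to CSV
#'
#' Columns `volume` (0-based) and `value`; TR and the stimulation volume are
#' kept in `# key: value` comment lines at the top.
#'
#' @param series A [bold_series].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bold_series <- function(series, path) {
  stopifnot(inherits(series, "bold_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tr: %.17g", series$tr), con)
  if (!is.null(series$stim_volume))
    writeLines(sprintf("# stim_volume: %d", series$stim_volume), con)
  writeLines("volume,value", con)
  writeLines(sprintf("%d,%.17g", seq_along(series$values) - 1L, series$values), con)
  invisible(path)
}

#' Read a BOLD series written by [write_bold_series()]
#' @param path CSV path.
#' @return A [bold_series].
#' @export
read_bold_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- lines[grepl("^#", lines)]
  get_key <- function(key) {
    m <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (!length(m)) return(NULL)
    as.numeric(sub(paste0("^#\\s*", key, ":\\s*"), "", m[1L]))
  }
  tr <- get_key("tr")
  if (is.null(tr)) stop("format error: header does not declare tr", call. = FALSE)
  dat <- utils::read.csv(text = lines[!grepl("^#", lines)])
  dat <- dat[order(dat$volume), ]
  sv <- get_key("stim_volume")
  bold_series(dat$value, tr = tr,
              stim_volume = if (is.null(sv)) NULL else as.integer(sv))
}

#' Extract the mean VOI time series from a 4D NIfTI image
#'
#' For each volume the arithmetic mean over all masked voxels is taken, in
#' double precision regardless of the on-disk data type; all voxels are
#' weighted equally.
#'
#' @param volumes Path to a 4D NIfTI file, or a 4D array.
#' @param mask A [voi_mask], a 3D logical/0-1 array, or a path to a 3D
#'   NIfTI mask image.
#' @param tr Repetition time in seconds for the resulting series.
#' @return A [bold_series] with one value per volume.
#' @export
extract_voi_series <- function(volumes, mask, tr = 2) {
  if (is.character(volumes)) volumes <- as.array(RNifti::readNifti(volumes))
  if (length(dim(volumes)) != 4L)
    stop("volumes must be 4D (x, y, z, time)", call. = FALSE)
  if (is.character(mask)) mask <- as.array(RNifti::readNifti(mask))
  if (!inherits(mask, "voi_mask")) mask <- voi_mask(mask)
  if (!identical(as.integer(dim(volumes)[1:3]), as.integer(mask$dim)))
    stop("mask grid ", paste(mask$dim, collapse = "x"),
         " does not match image grid ",
         paste(dim(volumes)[1:3], collapse = "x"), call. = FALSE)
  nvox <- prod(dim(volumes)[1:3])
  n_vol <- dim(volumes)[4L]
  flat <- matrix(as.numeric(volumes), nrow = nvox, ncol = n_vol)
  values <- colMeans(flat[mask$indices, , drop = FALSE])
  bold_series(values, tr = tr, meta = list(voi = mask$label))
}

#' Write result tables to CSV files
#'
#' Each element of `tables` (a named list of data frames) is written to
#' `<path>/<name>.csv` with its column order preserved, so identical inputs
#' always produce byte-identical files.
#'
#' @param tables Named list of data frames.
#' @param path Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(tables, path) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(path, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
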