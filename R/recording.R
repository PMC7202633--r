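#' Time-series recording of one mechanical test segment
#'
#' Container for the sampled channels of a single test on one motion segment:
#' time, a load channel (force or torque) and a deformation channel
#' (displacement or rotation). Units are declared, never guessed; rotation
#' supplied in degrees is converted to radians on construction.
#'
#' @param time numeric vector of sample times (s), strictly increasing.
#' @param load numeric vector, same length as `time`; force (N) or torque
#'   (N*m) depending on `kind`.
#' @param deformation numeric vector, same length as `time`; displacement
#'   (mm) or rotation (rad; `"deg"` accepted and converted).
#' @param kind test kind, one of `"axial_cyclic"`, `"creep"`,
#'   `"torsional_cyclic"`, `"torsion_to_failure"`.
#' @param load_unit `"N"` or `"Nm"`.
#' @param deformation_unit `"mm"`, `"rad"` or `"deg"` (stored as rad).
#' @param specimen_id optional specimen identifier.
#' @param metadata optional named list (protocol limits, annotations such as
#'   failure location).
#'
#' @return An object of class `ts_recording`: a list with elements `time`,
#'   `load`, `deformation`, `kind`, `load_unit`, `deformation_unit`,
#'   `specimen_id`, `sampling_rate` (Hz, median of 1/diff(time)) and
#'   `metadata`.
#' @export
#' @examples
#' t <- seq(0, 1, by = 0.01)
#' rec <- ts_recording(t, sin(2 * pi * t), 0.02 * sin(2 * pi * t),
#'                     kind = "axial_cyclic")
#' rec$sampling_rate
ts_recording <- function(time, load, deformation, kind,
                         load_unit = c("N", "Nm"),
                         deformation_unit = c("mm", "rad", "deg"),
                         specimen_id = NA_character_,
                         metadata = list()) {
  kind <- match.arg(kind, c("axial_cyclic", "creep", "torsional_cyclic",
                            "torsion_to_failure"))
  load_unit <- match.arg(load_unit)
  deformation_unit <- match.arg(deformation_unit)
  time <- as.numeric(time); load <- as.numeric(load)
  deformation <- as.numeric(deformation)
  if (length(time) != length(load) || length(time) != length(deformation))
    stop("time, load and deformation must have equal length", call. = FALSE)
  if (length(time) < 2L)
    stop("a recording needs at least two samples", call. = FALSE)
  if (any(!is.finite(time)))
    stop("non-finite values in time channel", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  nbad <- sum(!is.finite(load)) + sum(!is.finite(deformation))
  if (nbad > 0.01 * 2 * length(time))
    stop("more than 1% non-finite samples in data channels", call. = FALSE)
  if (deformation_unit == "deg") {
    deformation <- deformation * pi / 180
    deformation_unit <- "rad"
  }
  structure(list(
    time = time, load = load, deformation = deformation,
    kind = kind, load_unit = load_unit, deformation_unit = deformation_unit,
    specimen_id = specimen_id,
    sampling_rate = 1 / stats::median(diff(time)),
    metadata = metadata
  ), class = "ts_recording")
}

#' @export
print.ts_recording <- function(x, ...) {
  cat(sprintf("<ts_recording> %s  specimen=%s\n", x$kind, x$specimen_id))
  cat(sprintf("  %d samples, %.1f s at ~%.1f Hz\n",
              length(x$time), diff(range(x$time)), x$sampling_rate))
  cat(sprintf("  load [%s] in [%.4g, %.4g]; deformation [%s] in [%.4g, %.4g]\n",
              x$load_unit, min(x$load), max(x$load),
              x$deformation_unit, min(x$deformation), max(x$deformation)))
  invisible(x)
}

#' Read a recording from a delimited text file
#'
#' Reads a CSV or TSV time-series file with a header row naming the time,
#' load and deformation columns. The delimiter is auto-detected from the
#' first non-comment line. Lines starting with `#` before the header are
#' parsed as `key: value` metadata; declared units there are honoured unless
#' overridden by the function arguments.
#'
#' Recognized column names (case-insensitive): time; force, load, torque;
#' displacement, rotation, deformation, angle.
#'
#' @param path file path.
#' @param kind test kind; defaults to a `kind` metadata line if present.
#' @param load_unit,deformation_unit unit declarations; default to metadata
#'   lines `load_unit:` / `deformation_unit:` if present.
#' @param specimen_id defaults to the file name without extension.
#' @return A [ts_recording()].
#' @export
read_recording <- function(path, kind = NULL, load_unit = NULL,
                           deformation_unit = NULL, specimen_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 200L, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.+?)\\s*$", ml))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  header_line <- lines[!grepl("^#", lines) & nzchar(lines)][1]
  if (is.na(header_line)) stop("no header line found in ", path, call. = FALSE)
  sep <- if (grepl("\t", header_line)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  pick <- function(cands, what) {
    i <- which(nm %in% cands)[1]
    if (is.na(i)) stop("missing ", what, " column in ", path,
                       " (expected one of: ", paste(cands, collapse = ", "), ")",
                       call. = FALSE)
    df[[i]]
  }
  time <- pick("time", "time")
  load <- pick(c("force", "load", "torque"), "load")
  defo <- pick(c("displacement", "rotation", "deformation", "angle"),
               "deformation")
  kind <- kind %||% meta$kind %||%
    stop("test kind neither declared in file metadata nor supplied",
         call. = FALSE)
  load_unit <- load_unit %||% meta$load_unit %||%
    if (tolower(nm[which(nm %in% c("force", "load", "torque"))[1]]) == "torque")
      "Nm" else "N"
  deformation_unit <- deformation_unit %||% meta$deformation_unit %||%
    if (grepl("torsion", kind)) "rad" else "mm"
  specimen_id <- specimen_id %||% meta$specimen_id %||%
    tools::file_path_sans_ext(basename(path))
  ts_recording(time, load, defo, kind = kind, load_unit = load_unit,
               deformation_unit = deformation_unit, specimen_id = specimen_id,
               metadata = meta)
}

#' Write a recording to a CSV file
#'
#' Writes `# key: value` metadata lines (kind, units, specimen id) followed by
#' a three-column CSV (`time`, `load`, `deformation`) at full double
#' precision, so that `read_recording(write_recording(x))` round-trips the
#' values exactly.
#'
#' @param rec a [ts_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "ts_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# kind: %s", rec$kind),
    sprintf("# load_unit: %s", rec$load_unit),
    sprintf("# deformation_unit: %s", rec$deformation_unit),
    sprintf("# specimen_id: %s", rec$specimen_id)
  ), con)
  df <- data.frame(time = rec$time, load = rec$load,
                   deformation = rec$deformation)
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
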