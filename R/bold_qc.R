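# BOLD motion quality control: framewise displacement (Power's convention)
# and the pass/fail gate (any FD > 3 mm, or mean FD > 1 mm, fails).

#' Framewise displacement from a rigid motion trace
#'
#' Power's convention: for each frame the sum of absolute backward
#' differences of the three translations (mm) plus the head radius times
#' the sum of absolute differences of the three rotations (radians). The
#' first frame has FD 0.
#'
#' @param trace numeric n x 6 matrix: columns 1-3 translations in mm,
#'   columns 4-6 rotations in radians.
#' @param head_radius_mm radius converting rotations to arc length
#'   (default 50 mm).
#' @return Numeric vector of per-frame FD values (first element 0).
#' @export
framewise_displacement <- function(trace, head_radius_mm = 50) {
  trace <- as.matrix(trace)
  if (ncol(trace) != 6L)
    stop("motion trace must have 6 columns (3 translations, 3 rotations)")
  if (nrow(trace) < 2L) stop("at least 2 frames are required")
  if (!all(is.finite(trace))) stop("non-finite values in motion trace")
  d <- abs(diff(trace))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    head_radius_mm * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' BOLD motion QC gate
#'
#' Fails a session if any framewise displacement exceeds `max_fd` (default
#' 3 mm) or the average framewise displacement exceeds `max_mean_fd`
#' (default 1 mm). The mean includes the zero first frame.
#'
#' @param fd numeric vector of framewise displacements.
#' @param max_fd single-frame FD limit in mm.
#' @param max_mean_fd mean-FD limit in mm.
#' @return A `bold_qc` list: `pass` (logical), `reasons` (character vector
#'   of violated rules, empty if passing), `fd_max`, `fd_mean`, and the
#'   thresholds used. Manual checks (artifacts, carpet-plot intensity
#'   changes) are listed under `manual_checklist` for the reviewer.
#' @export
qc_bold <- function(fd, max_fd = 3, max_mean_fd = 1) {
  if (length(fd) == 0L) stop("empty FD series")
  reasons <- character(0)
  if (any(fd > max_fd))
    reasons <- c(reasons, sprintf("max FD exceeded (%.3g mm > %.3g mm)",
                                  max(fd), max_fd))
  if (mean(fd) > max_mean_fd)
    reasons <- c(reasons, sprintf("mean FD exceeded (%.3g mm > %.3g mm)",
                                  mean(fd), max_mean_fd))
  structure(list(pass = length(reasons) == 0L,
                 reasons = reasons,
                 fd_max = max(fd), fd_mean = mean(fd),
                 max_fd = max_fd, max_mean_fd = max_mean_fd,
                 manual_checklist = c("image artifacts",
                                      "long-lasting carpet-plot intensity changes",
                                      "T1 head coverage / incidental findings")),
            class = "bold_qc")
}

#' @export
print.bold_qc <- function(x, ...) {
  cat(sprintf("<bold_qc> %s (max FD %.3g mm, mean FD %.3g mm)\n",
              if (x$pass) "PASS" else "FAIL", x$fd_max, x$fd_mean))
  if (!x$pass) cat(paste0("  - ", x$reasons, collapse = "\n"), "\n")
  invisible(x)
}

#' Read a 6-column motion-parameter table
#'
#' Whitespace- or tab-separated text, one row per frame: three translations
#' (mm) then three rotations (radians).
#'
#' @param path file path.
#' @return n x 6 numeric matrix.
#' @export
read_motion_trace <- function(path) {
  m <- as.matrix(read.table(path, header = FALSE))
  if (ncol(m) != 6L) stop("expected 6 columns in motion file, got ", ncol(m))
  unname(m)
}

#' Write a motion QC report as JSON
#'
#' @param qc a `bold_qc` object.
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
write_qc_report <- function(qc, path) {
  jsonlite::write_json(list(pass = qc$pass, reasons = qc$reasons,
                            fd_max = qc$fd_max, fd_mean = qc$fd_mean,
                            thresholds = list(max_fd = qc$max_fd,
                                              max_mean_fd = qc$max_mean_fd),
                            manual_checklist = qc$manual_checklist),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
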