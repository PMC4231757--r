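#' In-plane trajectory of a single tethered bead
#'
#' Time-stamped x/y positions (nm) of one bead, sampled uniformly. This is
#' the raw unit of TPM analysis: everything downstream (drift filtering,
#' windowed RMS, screening, persistence estimation) consumes it.
#'
#' @param t Time stamps in seconds; strictly increasing, uniform spacing
#'   (within 1e-6 relative).
#' @param x,y Positions in nm; finite, same length as `t`.
#' @param bead_id Identifier for the tether.
#' @return An object of class `tpm_trajectory` with fields `t`, `x`, `y`,
#'   `bead_id` and inferred `sample_rate` (Hz).
#' @export
tpm_trajectory <- function(t, x, y, bead_id = "bead") {
  stopifnot(is.numeric(t), is.numeric(x), is.numeric(y))
  n <- length(t)
  if (n < 2L || length(x) != n || length(y) != n) {
    stop("t, x, y must have equal length >= 2")
  }
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(t))) {
    stop("trajectory contains non-finite values")
  }
  dt <- diff(t)
  if (any(dt <= 0)) stop("time stamps must be strictly increasing")
  med <- stats::median(dt)
  if (max(abs(dt - med)) > 1e-6 * med) {
    stop("non-uniform sampling: time steps deviate by more than 1e-6 relative")
  }
  structure(list(t = t, x = x, y = y, bead_id = as.character(bead_id)[1],
                 sample_rate = 1 / med),
            class = "tpm_trajectory")
}

#' @export
print.tpm_trajectory <- function(x, ...) {
  cat(sprintf("TPM trajectory '%s': %d samples at %.3g Hz (%.1f s)\n",
              x$bead_id, length(x$t), x$sample_rate,
              x$t[length(x$t)] - x$t[1]))
  invisible(x)
}

#' Windowed RMS excursion series
#'
#' @param t Time stamps (s), centre of each window.
#' @param rms RMS excursion values (nm), >= 0 (NA allowed for masked spans).
#' @param window Window duration (s), > 0.
#' @param bead_id Identifier carried through from the trajectory.
#' @return An object of class `rms_series`.
#' @export
rms_series <- function(t, rms, window, bead_id = "bead") {
  stopifnot(is.numeric(t), is.numeric(rms), length(t) == length(rms),
            length(t) >= 1L, is.numeric(window), length(window) == 1L,
            window > 0)
  if (any(rms < 0, na.rm = TRUE)) stop("rms values must be non-negative")
  structure(list(t = t, rms = rms, window = window,
                 bead_id = as.character(bead_id)[1]),
            class = "rms_series")
}

#' @export
print.rms_series <- function(x, ...) {
  cat(sprintf("RMS series '%s': %d points, %g s window, mean %.1f nm\n",
              x$bead_id, length(x$t), x$window, mean(x$rms, na.rm = TRUE)))
  invisible(x)
}

#' Read a TPM trajectory from a CSV/TSV file
#'
#' Expects a header `time_s,x_nm,y_nm` with an optional `bead_id` column;
#' lines starting with `#` are comments. Rows with non-numeric entries are
#' reported with their file line numbers. Files holding several beads return
#' a named list of trajectories.
#'
#' @param path Path to the file.
#' @param sep Field separator; `","` (default) or `"\t"`.
#' @return A [tpm_trajectory()], or a named list of them when the file holds
#'   more than one `bead_id`.
#' @export
read_trajectory <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           stringsAsFactors = FALSE, colClasses = "character")
  need <- c("time_s", "x_nm", "y_nm")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  num <- lapply(raw[need], function(col) suppressWarnings(as.numeric(col)))
  bad <- which(Reduce(`|`, lapply(num, function(v) !is.finite(v))))
  if (length(bad) > 0) {
    stop("malformed (non-numeric) data rows at line(s): ",
         paste(utils::head(bad + 1L, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "")
  }
  ids <- if ("bead_id" %in% names(raw)) raw$bead_id else "bead"
  df <- data.frame(t = num$time_s, x = num$x_nm, y = num$y_nm,
                   bead_id = ids, stringsAsFactors = FALSE)
  split_df <- split(df, df$bead_id)
  out <- lapply(split_df, function(d) {
    tpm_trajectory(d$t, d$x, d$y, bead_id = d$bead_id[1])
  })
  if (length(out) == 1L) out[[1]] else out
}

#' Write a TPM trajectory to CSV
#'
#' Values are written with 17 significant digits so that a write/read cycle
#' reproduces the trajectory exactly.
#'
#' @param traj A [tpm_trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "tpm_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_s,x_nm,y_nm,bead_id", con)
  writeLines(sprintf("%.17g,%.17g,%.17g,%s", traj$t, traj$x, traj$y,
                     traj$bead_id), con)
  invisible(path)
}

#' Write an RMS series to CSV (`time_s,rms_nm`)
#' @param series An [rms_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rms_series <- function(series, path) {
  stopifnot(inherits(series, "rms_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# window_s=%g bead_id=%s", series$window,
                     series$bead_id), con)
  writeLines("time_s,rms_nm", con)
  writeLines(sprintf("%.17g,%.17g", series$t, series$rms), con)
  invisible(path)
}

#' Read an RMS series written by [write_rms_series()]
#' @param path Input path.
#' @return An [rms_series()].
#' @export
read_rms_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  window <- 4
  bead_id <- "bead"
  if (startsWith(first, "#")) {
    w <- regmatches(first, regexec("window_s=([0-9.eE+-]+)", first))[[1]]
    if (length(w) == 2) window <- as.numeric(w[2])
    b <- regmatches(first, regexec("bead_id=(\\S+)", first))[[1]]
    if (length(b) == 2) bead_id <- b[2]
  }
  df <- utils::read.csv(path, comment.char = "#")
  rms_series(df$time_s, df$rms_nm, window = window, bead_id = bead_id)
}
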