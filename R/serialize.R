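#' Write / read trajectories and flows as CSV
#'
#' Columnar plain-text serialization: trajectories as
#' `t, xi_r, v_r, xi_l, v_l`, flows as `t, u0`. The fundamental frequency
#' of the attached [time_scale] is stored in a header comment and restored
#' on read.
#'
#' @param x a `vfo_trajectory` or `glottal_flow`
#' @param path output path
#' @return `path` invisibly (writers); the restored object (readers)
#' @export
write_series_csv <- function(x, path) {
  ts <- attr(x, "timescale")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(ts)) writeLines(sprintf("# f0_hz: %.10g", ts$f0), con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  first <- readLines(path, n = 1)
  ts <- NULL
  if (startsWith(first, "# f0_hz:")) {
    ts <- time_scale(as.numeric(sub("# f0_hz:", "", first)))
  }
  df <- utils::read.csv(path, comment.char = "#")
  attr(df, "timescale") <- ts
  cls <- if (all(c("xi_r", "v_r", "xi_l", "v_l") %in% names(df))) {
    "vfo_trajectory"
  } else if ("u0" %in% names(df)) "glottal_flow" else NULL
  class(df) <- c(cls, "data.frame")
  df
}

#' Write / read a space-time field as plain text
#'
#' Matrix serialization with a small JSON metadata header line (grid shape
#' and, when available, the tract configuration), then CSV rows (one per
#' spatial node).
#'
#' @param x matrix-like field (`vt_profile`, or the `u`/`z` matrix of a
#'   solver result)
#' @param path output path
#' @param meta named list merged into the metadata header
#' @export
write_field_txt <- function(x, path, meta = list()) {
  m <- unclass(if (is.list(x)) x$u else x)
  hdr <- c(list(nrow = nrow(m), ncol = ncol(m)), meta)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", jsonlite::toJSON(hdr, auto_unbox = TRUE)), con)
  utils::write.table(m, con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_field_txt
#' @export
read_field_txt <- function(path) {
  hdr <- jsonlite::fromJSON(sub("^# ", "", readLines(path, n = 1)))
  m <- as.matrix(utils::read.table(path, sep = ",", comment.char = "#"))
  dimnames(m) <- NULL
  stopifnot(nrow(m) == hdr$nrow, ncol(m) == hdr$ncol)
  attr(m, "meta") <- hdr
  m
}

#' Dynamics summary as JSON
#'
#' @param summary a `dynamics_summary`
#' @param path output path, or `NULL` to return the JSON string
#' @export
write_summary_json <- function(summary, path = NULL) {
  s <- unclass(summary)
  if (!is.null(s$entrainment)) {
    s$entrainment <- list(n = s$entrainment$n, m = s$entrainment$m)
  }
  js <- jsonlite::toJSON(s, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
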