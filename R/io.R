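#' Read and write photon traces
#'
#' Plain-text trace format: two header lines `# bin_width_s=<float>` and
#' `# n=<int>`, then one integer count per line. Round trips are bit exact.
#'
#' @param path File path.
#' @return `read_trace()` returns a [photon_trace()].
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("trace file too short: ", path)
  h1 <- regmatches(lines[1], regexec("^#\\s*bin_width_s=([0-9.eE+-]+)\\s*$", lines[1]))[[1]]
  h2 <- regmatches(lines[2], regexec("^#\\s*n=([0-9]+)\\s*$", lines[2]))[[1]]
  if (length(h1) != 2L) stop("missing `# bin_width_s=` header (line 1) in ", path)
  if (length(h2) != 2L) stop("missing `# n=` header (line 2) in ", path)
  bin_width <- as.numeric(h1[2])
  n <- as.integer(h2[2])
  body <- lines[-(1:2)]
  if (length(body) != n)
    stop("trace file declares n=", n, " but has ", length(body), " count lines")
  counts <- suppressWarnings(as.numeric(body))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad))
    stop("invalid count at line ", bad[1] + 2L, " of ", path, ": '", body[bad[1]], "'")
  photon_trace(counts, bin_width)
}

#' @param trace A [photon_trace()].
#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "photon_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# bin_width_s=%.17g", trace$bin_width),
               sprintf("# n=%d", length(trace$counts)),
               format(trace$counts, scientific = FALSE, trim = TRUE)), con)
  invisible(path)
}

#' Read and write mSMR curves
#'
#' CSV with columns `T_s, m1, m2, m3, n_bins, Q, mu_cps, corr_deadtime,
#' corr_afterpulse, corr_background`; sampling times must be strictly
#' increasing. Numeric round trips are exact to full double precision.
#'
#' @param path File path.
#' @return `read_curve()` returns an `msmr_curve`.
#' @export
read_curve <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("T_s", "m1", "m2", "m3", "n_bins", "Q", "mu_cps",
            "corr_deadtime", "corr_afterpulse", "corr_background")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("curve file missing column(s): ", paste(miss, collapse = ", "))
  if (is.unsorted(df$T_s, strictly = TRUE))
    stop("sampling times in ", path, " are not strictly increasing")
  structure(df[need], class = c("msmr_curve", "data.frame"),
            bin_width = df$T_s[1], T_obs = df$T_s[1] * df$n_bins[1])
}

#' @param curve An `msmr_curve`.
#' @rdname read_curve
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "msmr_curve"))
  df <- as.data.frame(curve)
  for (col in c("T_s", "m1", "m2", "m3", "Q", "mu_cps"))
    df[[col]] <- sprintf("%.17g", df[[col]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
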