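#' @keywords internal
"_PACKAGE"

## Deterministic seed streams: every Monte-Carlo table derives its own seed
## from the master seed and a set of labels, so results do not depend on the
## order in which tables are built.  Kept below 2^31 - 1 (R integers).
derive_seed <- function(master, ...) {
  labels <- paste(c(format(master), vapply(list(...), format, "")),
                  collapse = "|")
  h <- as.double(master %% 2147483629L)
  for (ch in utf8ToInt(labels)) {
    h <- (h * 31 + ch) %% 2147483629
  }
  as.integer(h) + 1L
}

## Composite trapezoid on an arbitrary sorted grid.
trapz_grid <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

## Trapezoid quadrature weights (for error propagation).
trapz_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  dx <- diff(x)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dx[-1] + dx[-(n - 1)]) / 2
  w
}

log_msg <- function(level = "INFO", ..., verbose = getOption("neqafs.verbose", FALSE)) {
  if (isTRUE(verbose) || level %in% c("WARN", "ERROR")) {
    message(sprintf("[neqafs %s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

#' Write a table as TSV with provenance comments
#'
#' Writes a data frame as tab-separated text preceded by `#`-prefixed
#' comment lines echoing the parameters that produced it, so that an output
#' file is self-describing and reruns can be compared byte for byte.
#'
#' @param df data frame to write.
#' @param path output file path.
#' @param provenance named list of scalar parameters echoed as comments.
#' @return `path`, invisibly.
#' @export
write_tsv_provenance <- function(df, path, provenance = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(provenance)) {
    writeLines(sprintf("# %s: %s", nm,
                       paste(format(provenance[[nm]], digits = 15), collapse = ",")),
               con)
  }
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## linear interpolation of a table column at arbitrary y, log-spaced safe
interp_log_y <- function(y_nodes, values, rule = 2) {
  stats::approxfun(log(y_nodes), values, rule = rule)
}
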