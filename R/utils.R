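# shared numeric and I/O helpers

# floor for p-values before -log10 so weights stay finite
.P_FLOOR <- 1e-300

clamp_p <- function(p) pmax(p, .P_FLOOR)

#' Minus log10 of a p-value with underflow protection
#'
#' p-values below 1e-300 are clamped so that the -log10 weight used
#' throughout the integration stage stays finite.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return numeric vector of -log10(p) after clamping.
#' @keywords internal
neglog10 <- function(p) -log10(clamp_p(p))

# fixed 6-significant-digit formatting for byte-stable output files
fmt_num <- function(x) {
  out <- formatC(x, digits = 6, format = "g")
  out[is.na(x)] <- "NA"
  out
}

# deterministic hash of an R object via its deparsed form
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

provenance_header <- function(seed, config = NULL) {
  ver <- as.character(utils::packageVersion("metafold"))
  c(
    sprintf("# metafold %s", ver),
    sprintf("# seed=%s", format(seed)),
    sprintf("# config_hash=%s", config_hash(config))
  )
}

# TSV writer with optional '#' provenance header and fixed numeric format
write_tsv <- function(df, path, header_lines = NULL) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  for (j in which(num)) df[[j]] <- fmt_num(df[[j]])
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(header_lines, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}
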