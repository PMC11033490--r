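#' Read an ESRI ASCII grid raster
#'
#' Expects the six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`) followed by row-major values with the
#' northernmost row first. Cells equal to the nodata value become `NA`.
#'
#' @param path raster file path
#' @return an [EnvGrid-class]
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 6L) stop("ASCII grid too short for a 6-line header")
  hdr <- list()
  for (i in 1:6) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) != 2L) stop(sprintf("bad header line %d: '%s'", i, lines[i]))
    hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("ASCII grid header missing: ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  body <- lines[-(1:6)]
  rows <- lapply(seq_along(body), function(i) {
    v <- as.numeric(strsplit(trimws(body[i]), "\\s+")[[1]])
    if (length(v) != nc)
      stop(sprintf("row %d has %d values; header declares ncols %d",
                   i, length(v), nc))
    v
  })
  if (length(rows) != nr)
    stop(sprintf("grid has %d data rows; header declares nrows %d",
                 length(rows), nr))
  g <- do.call(rbind, rows)
  g[g == hdr$nodata_value] <- NA_real_
  EnvGrid(g, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, hdr$nodata_value)
}

#' Write an EnvGrid as an ESRI ASCII grid
#'
#' Values are written with enough significant digits (%.10g) that a
#' read/write round trip preserves them well beyond 1e-6.
#'
#' @param grid an [EnvGrid-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeAsciiGrid <- function(grid, path) {
  g <- grid@grid
  hdr <- c(sprintf("ncols %d", ncol(g)),
           sprintf("nrows %d", nrow(g)),
           sprintf("xllcorner %.10g", grid@xll),
           sprintf("yllcorner %.10g", grid@yll),
           sprintf("cellsize %.10g", grid@cellsize),
           sprintf("NODATA_value %.10g", grid@nodata))
  g[is.na(g)] <- grid@nodata
  body <- apply(g, 1, function(r) paste(sprintf("%.10g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
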