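# Plain-text raster I/O in the ESRI ASCII grid format: a 6-line header
# (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
# nrows rows of values, northernmost row first.  Monthly climate stacks
# are stored as 12 tmin + 12 tmax files in one directory.

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @return a list with `values` (numeric matrix, row 1 = northernmost,
#'   nodata as `NA`), `xll`, `yll`, `cellsize`, `nodata`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  header <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    header[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(header))
  if (length(miss)) {
    stop_invalid("malformed ASCII grid header in ", path, ": missing ",
                 paste(miss, collapse = ", "))
  }
  nodata <- header$nodata_value %||% -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- header$nrows; nc <- header$ncols
  if (length(vals) != nr * nc) {
    stop_invalid("ASCII grid ", path, " has ", length(vals),
                 " values, expected ", nr * nc)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  list(values = m, xll = header$xllcorner, yll = header$yllcorner,
       cellsize = header$cellsize, nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' @param values numeric matrix (row 1 = northernmost row); `NA` written
#'   as the nodata value.
#' @param path file path.
#' @param xll,yll lower-left corner coordinates.
#' @param cellsize cell size.
#' @param nodata nodata sentinel (default -9999).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(values, path, xll = 0, yll = 0, cellsize = 1,
                             nodata = -9999) {
  stopifnot(is.matrix(values))
  m <- values
  m[is.na(m)] <- nodata
  header <- c(paste("ncols", ncol(m)),
              paste("nrows", nrow(m)),
              paste("xllcorner", format(xll, scientific = FALSE)),
              paste("yllcorner", format(yll, scientific = FALSE)),
              paste("cellsize", format(cellsize, scientific = FALSE)),
              paste("NODATA_value", nodata))
  body <- apply(m, 1, function(r) {
    paste(formatC(r, digits = 15, format = "g"), collapse = " ")
  })
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a monthly climate stack from a directory of ASCII grids
#'
#' Expects 12 tmin and 12 tmax files named by `sprintf(tmin_pattern, month)`
#' and `sprintf(tmax_pattern, month)`.
#'
#' @param dir directory containing the 24 layers.
#' @param tmin_pattern,tmax_pattern `sprintf` patterns with one integer
#'   slot for the month (defaults `"tmin_%02d.asc"`, `"tmax_%02d.asc"`).
#' @param crs free-text coordinate reference description.
#' @return a [climate_grid()].
#' @export
read_climate_grid <- function(dir, tmin_pattern = "tmin_%02d.asc",
                              tmax_pattern = "tmax_%02d.asc",
                              crs = "unspecified") {
  read_stack <- function(pattern) {
    layers <- lapply(1:12, function(m) {
      read_ascii_grid(file.path(dir, sprintf(pattern, m)))
    })
    geo <- layers[[1]][c("xll", "yll", "cellsize")]
    for (l in layers) {
      if (!identical(l[c("xll", "yll", "cellsize")], geo) ||
          !identical(dim(l$values), dim(layers[[1]]$values))) {
        stop_invalid("climate stack layers are not aligned in ", dir)
      }
    }
    arr <- array(NA_real_, c(dim(layers[[1]]$values), 12))
    for (m in 1:12) arr[, , m] <- layers[[m]]$values
    list(arr = arr, geo = geo)
  }
  mn <- read_stack(tmin_pattern)
  mx <- read_stack(tmax_pattern)
  climate_grid(mn$arr, mx$arr, xll = mn$geo$xll, yll = mn$geo$yll,
               cellsize = mn$geo$cellsize, crs = crs)
}

#' Write a monthly climate stack as ASCII grids
#'
#' @param grid a [climate_grid()].
#' @param dir output directory (created if needed).
#' @inheritParams read_climate_grid
#' @return `dir`, invisibly.
#' @export
write_climate_grid <- function(grid, dir, tmin_pattern = "tmin_%02d.asc",
                               tmax_pattern = "tmax_%02d.asc") {
  stopifnot(inherits(grid, "climate_grid"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in 1:12) {
    write_ascii_grid(grid$tmin[, , m], file.path(dir, sprintf(tmin_pattern, m)),
                     grid$xll, grid$yll, grid$cellsize)
    write_ascii_grid(grid$tmax[, , m], file.path(dir, sprintf(tmax_pattern, m)),
                     grid$xll, grid$yll, grid$cellsize)
  }
  invisible(dir)
}

#' Write an index grid as an ESRI ASCII grid
#'
#' @param grid an [index_grid()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_index_grid <- function(grid, path) {
  stopifnot(inherits(grid, "index_grid"))
  write_ascii_grid(grid$values, path, grid$xll, grid$yll, grid$cellsize)
}
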