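#' Corneal elevation grid
#'
#' Sampled surface heights z(x, y) in mm on a regular Cartesian grid centred
#' on the instrument (visual) axis — the package's stand-in for exported
#' Scheimpflug height maps. Invalid cells are `NA`. Rows run y-descending,
#' columns x-ascending, matching the CSV dialect written by
#' [write_elevation_csv()].
#'
#' @param heights numeric matrix of heights in mm (`NA`/`NaN` = invalid);
#'   dimensions must be odd so the grid is symmetric about (0, 0).
#' @param spacing grid spacing in mm (> 0).
#' @param surface `"anterior"` or `"posterior"`.
#' @return an object of class `elevation_grid` with fields `heights`,
#'   `spacing`, `half_aperture`, `surface`, and axis vectors `x`
#'   (ascending) and `y` (descending).
#' @export
elevation_grid <- function(heights, spacing, surface = c("anterior", "posterior")) {
  surface <- match.arg(surface)
  heights <- as.matrix(heights)
  stopifnot(is.numeric(heights), is.numeric(spacing), length(spacing) == 1)
  if (!is.finite(spacing) || spacing <= 0) stop("spacing must be > 0")
  if (nrow(heights) %% 2 == 0 || ncol(heights) %% 2 == 0)
    stop("grid dimensions must be odd so the grid is centred on (0, 0)")
  if (any(is.infinite(heights)))
    stop("heights must be finite or NA wherever the mask is valid")
  hx <- (ncol(heights) - 1) / 2
  hy <- (nrow(heights) - 1) / 2
  structure(
    list(heights = unname(heights), spacing = spacing,
         half_aperture = max(hx, hy) * spacing, surface = surface,
         x = spacing * seq(-hx, hx), y = spacing * seq(hy, -hy)),
    class = "elevation_grid"
  )
}

#' @export
print.elevation_grid <- function(x, ...) {
  cat(sprintf("<elevation_grid> %s, %d x %d, spacing %.4g mm, half-aperture %.4g mm, %d valid cells\n",
              x$surface, nrow(x$heights), ncol(x$heights), x$spacing,
              x$half_aperture, sum(is.finite(x$heights))))
  invisible(x)
}

#' Write an elevation grid to CSV
#'
#' Dialect: comment headers `# spacing_mm=<v>`, `# half_aperture_mm=<v>`,
#' `# surface=<anterior|posterior>`, then the dense height matrix in mm with
#' `NaN` marking invalid cells; rows are y-descending, columns x-ascending.
#' Finite values round-trip bit-identically through [read_elevation_csv()].
#'
#' @param grid an [elevation_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_elevation_csv <- function(grid, path) {
  stopifnot(inherits(grid, "elevation_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# spacing_mm=%s", format_double(grid$spacing)),
               sprintf("# half_aperture_mm=%s", format_double(grid$half_aperture)),
               sprintf("# surface=%s", grid$surface)), con)
  h <- grid$heights
  h[is.na(h)] <- NaN
  writeLines(apply(h, 1L, function(row) paste(format_double(row), collapse = ",")), con)
  invisible(path)
}

#' Read an elevation grid from CSV
#'
#' @param path file in the dialect of [write_elevation_csv()].
#' @return an [elevation_grid()].
#' @export
read_elevation_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  get_field <- function(key) {
    m <- grep(paste0("^#\\s*", key, "="), hdr, value = TRUE)
    if (length(m) != 1) stop("elevation CSV: missing or duplicated header '", key, "'")
    sub(paste0("^#\\s*", key, "="), "", m)
  }
  spacing <- as.numeric(get_field("spacing_mm"))
  surface <- get_field("surface")
  rows <- strsplit(body, ",", fixed = TRUE)
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1) stop("elevation CSV: ragged height matrix")
  h <- matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
  elevation_grid(h, spacing = spacing, surface = surface)
}

# matrices of grid coordinates matching grid$heights layout
grid_xy <- function(grid) {
  list(x = matrix(grid$x, nrow(grid$heights), ncol(grid$heights), byrow = TRUE),
       y = matrix(grid$y, nrow(grid$heights), ncol(grid$heights)))
}
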