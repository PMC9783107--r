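#' Load a gridded steady velocity field
#'
#' Reads a structured-grid velocity field and wraps it as a [flow_field()]
#' with trilinear interpolation inside the grid; queries outside the grid
#' bounding box raise an error.
#'
#' Supported formats:
#' * `csv_points`: CSV with a required header `x,y,z,ux,uy,uz` (SI units),
#'   one row per node of a full tensor-product grid, in any row order.
#' * `vtk_structured`: legacy ASCII VTK `STRUCTURED_POINTS` dataset with a
#'   `VECTORS` point-data attribute.
#'
#' @param path File path.
#' @param format `"csv_points"` or `"vtk_structured"`.
#' @param ds Wall offset metadata for shear sampling (m).
#' @return A [flow_field()] of kind `"gridded"`, with the node data kept in
#'   `$params$grid` (axes `xs`, `ys`, `zs` and arrays `ux`, `uy`, `uz`).
#' @export
load_gridded_field <- function(path, format = c("csv_points", "vtk_structured"),
                               ds = 50e-6) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  grid <- if (format == "csv_points") .read_csv_points(path)
          else .read_vtk_structured_points(path)
  for (comp in c("ux", "uy", "uz"))
    if (any(!is.finite(grid[[comp]])))
      stop("non-finite velocity values in ", path, call. = FALSE)
  vel <- function(p) .trilinear(grid, p)
  cpp_spec <- list(kind = 4L,
                   xs = grid$xs, ys = grid$ys, zs = grid$zs,
                   ux = as.numeric(grid$ux), uy = as.numeric(grid$uy),
                   uz = as.numeric(grid$uz))
  flow_field(vel, kind = "gridded", ds = ds, params = list(grid = grid),
             cpp_spec = cpp_spec)
}

#' Write a gridded velocity field
#'
#' Writes grid node data in the `csv_points` dialect (`x,y,z,ux,uy,uz`,
#' header required). Values are printed with 17 significant digits so that
#' a write/load round trip preserves node velocities bit-exactly.
#'
#' @param field A gridded [flow_field()] (from [load_gridded_field()] or
#'   [sample_field_to_grid()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gridded_field <- function(field, path) {
  grid <- field$params$grid
  if (is.null(grid)) stop("field carries no grid data", call. = FALSE)
  nodes <- expand.grid(x = grid$xs, y = grid$ys, z = grid$zs,
                       KEEP.OUT.ATTRS = FALSE)
  lines <- c("x,y,z,ux,uy,uz",
             sprintf("%.17g,%.17g,%.17g,%.17g,%.17g,%.17g",
                     nodes$x, nodes$y, nodes$z,
                     as.numeric(grid$ux), as.numeric(grid$uy),
                     as.numeric(grid$uz)))
  writeLines(lines, path)
  invisible(path)
}

#' Sample any flow field onto a structured grid
#'
#' Evaluates `field` at the nodes of a tensor-product grid and returns a
#' gridded [flow_field()] that interpolates those samples. Useful for
#' writing fixture files and for interpolation-error studies.
#'
#' @param field A [flow_field()].
#' @param xs,ys,zs Strictly increasing node coordinate vectors (m).
#' @param ds Wall offset metadata (m).
#' @return A gridded [flow_field()].
#' @export
sample_field_to_grid <- function(field, xs, ys, zs, ds = field$ds) {
  nodes <- expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE)
  v <- field_velocity(field, as.matrix(nodes))
  dims <- c(length(xs), length(ys), length(zs))
  grid <- list(xs = xs, ys = ys, zs = zs,
               ux = array(v[, 1], dims), uy = array(v[, 2], dims),
               uz = array(v[, 3], dims))
  vel <- function(p) .trilinear(grid, p)
  cpp_spec <- list(kind = 4L, xs = xs, ys = ys, zs = zs,
                   ux = as.numeric(grid$ux), uy = as.numeric(grid$uy),
                   uz = as.numeric(grid$uz))
  flow_field(vel, kind = "gridded", ds = ds,
             flow_rate_lpm = field$flow_rate_lpm, geom = field$geom,
             params = list(grid = grid), cpp_spec = cpp_spec)
}

.read_csv_points <- function(path) {
  df <- utils::read.csv(path, header = TRUE)
  need <- c("x", "y", "z", "ux", "uy", "uz")
  if (!all(need %in% names(df)))
    stop("csv_points file must have header columns x,y,z,ux,uy,uz: ", path,
         call. = FALSE)
  xs <- sort(unique(df$x)); ys <- sort(unique(df$y)); zs <- sort(unique(df$z))
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  if (nrow(df) != nx * ny * nz)
    stop(sprintf("csv_points grid is not a full tensor product (%d rows, expected %d)",
                 nrow(df), nx * ny * nz), call. = FALSE)
  ix <- match(df$x, xs); iy <- match(df$y, ys); iz <- match(df$z, zs)
  lin <- ix + nx * (iy - 1L) + nx * ny * (iz - 1L)
  if (anyDuplicated(lin))
    stop("duplicate grid nodes in ", path, call. = FALSE)
  dims <- c(nx, ny, nz)
  ux <- uy <- uz <- array(NA_real_, dims)
  ux[lin] <- df$ux; uy[lin] <- df$uy; uz[lin] <- df$uz
  list(xs = xs, ys = ys, zs = zs, ux = ux, uy = uy, uz = uz)
}

.read_vtk_structured_points <- function(path) {
  ln <- readLines(path)
  g <- function(pat) grep(pat, ln, ignore.case = TRUE)[1]
  i_dim <- g("^DIMENSIONS"); i_org <- g("^ORIGIN"); i_spc <- g("^SPACING")
  i_vec <- g("^VECTORS")
  if (any(is.na(c(i_dim, i_org, i_spc, i_vec))))
    stop("not a legacy VTK STRUCTURED_POINTS file with VECTORS data: ", path,
         call. = FALSE)
  num <- function(i) as.numeric(strsplit(trimws(ln[i]), "\\s+")[[1]][-1])
  dims <- as.integer(num(i_dim)); org <- num(i_org); spc <- num(i_spc)
  if (length(dims) != 3 || any(dims < 2))
    stop("bad DIMENSIONS line (line ", i_dim, ") in ", path, call. = FALSE)
  vals <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(ln[(i_vec + 1):length(ln)]), "\\s+"))))
  vals <- vals[!is.na(vals)]
  npt <- prod(dims)
  if (length(vals) < 3 * npt)
    stop(sprintf("VECTORS data truncated after line %d: got %d values, need %d",
                 i_vec, length(vals), 3 * npt), call. = FALSE)
  m <- matrix(vals[1:(3 * npt)], ncol = 3, byrow = TRUE)  # x varies fastest
  list(xs = org[1] + spc[1] * (0:(dims[1] - 1)),
       ys = org[2] + spc[2] * (0:(dims[2] - 1)),
       zs = org[3] + spc[3] * (0:(dims[3] - 1)),
       ux = array(m[, 1], dims), uy = array(m[, 2], dims),
       uz = array(m[, 3], dims))
}

# vectorized trilinear interpolation on a tensor grid; errors outside bounds
.trilinear <- function(grid, p) {
  xs <- grid$xs; ys <- grid$ys; zs <- grid$zs
  tol <- 1e-12
  if (any(p[, 1] < xs[1] - tol | p[, 1] > xs[length(xs)] + tol |
          p[, 2] < ys[1] - tol | p[, 2] > ys[length(ys)] + tol |
          p[, 3] < zs[1] - tol | p[, 3] > zs[length(zs)] + tol))
    stop("query point outside the gridded field domain", call. = FALSE)
  cl <- function(v, ax) pmin(pmax(v, ax[1]), ax[length(ax)])
  x <- cl(p[, 1], xs); y <- cl(p[, 2], ys); z <- cl(p[, 3], zs)
  ix <- pmin(pmax(findInterval(x, xs), 1L), length(xs) - 1L)
  iy <- pmin(pmax(findInterval(y, ys), 1L), length(ys) - 1L)
  iz <- pmin(pmax(findInterval(z, zs), 1L), length(zs) - 1L)
  tx <- (x - xs[ix]) / (xs[ix + 1L] - xs[ix])
  ty <- (y - ys[iy]) / (ys[iy + 1L] - ys[iy])
  tz <- (z - zs[iz]) / (zs[iz + 1L] - zs[iz])
  interp1 <- function(a) {
    v000 <- a[cbind(ix, iy, iz)];        v100 <- a[cbind(ix + 1L, iy, iz)]
    v010 <- a[cbind(ix, iy + 1L, iz)];   v110 <- a[cbind(ix + 1L, iy + 1L, iz)]
    v001 <- a[cbind(ix, iy, iz + 1L)];   v101 <- a[cbind(ix + 1L, iy, iz + 1L)]
    v011 <- a[cbind(ix, iy + 1L, iz + 1L)]
    v111 <- a[cbind(ix + 1L, iy + 1L, iz + 1L)]
    (((v000 * (1 - tx) + v100 * tx) * (1 - ty) +
      (v010 * (1 - tx) + v110 * tx) * ty) * (1 - tz) +
     ((v001 * (1 - tx) + v101 * tx) * (1 - ty) +
      (v011 * (1 - tx) + v111 * tx) * ty) * tz)
  }
  cbind(interp1(grid$ux), interp1(grid$uy), interp1(grid$uz),
        deparse.level = 0)
}
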