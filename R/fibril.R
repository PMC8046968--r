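#' Construct a fibril polyline
#'
#' An ordered 3D polyline in world coordinates (nm) with an id and a
#' cylinder radius used for volume and elasticity calculations.
#'
#' @param points n x 3 numeric matrix (nm), n >= 2, consecutive rows
#'   distinct.
#' @param id fibril label (coerced to character).
#' @param radius cylinder radius in nm (default 5).
#' @return object of class `fibril`.
#' @export
fibril <- function(points, id = "1", radius = .default_fibril_radius_nm) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3 || nrow(points) < 2)
    .stopf("fibril %s: need an n x 3 matrix with n >= 2", id,
           class = "fibrilstats_validation_error")
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  if (any(seg == 0))
    .stopf("fibril %s: duplicate consecutive points", id,
           class = "fibrilstats_validation_error")
  if (!is.numeric(radius) || radius <= 0)
    .stopf("fibril %s: radius must be positive", id,
           class = "fibrilstats_validation_error")
  colnames(points) <- c("x", "y", "z")
  structure(list(points = points, id = as.character(id), radius = radius),
            class = "fibril")
}

#' @export
print.fibril <- function(x, ...) {
  cat(sprintf("fibril %s: %d points, length %.1f nm, radius %g nm\n",
              x$id, nrow(x$points), fibril_length(x), x$radius))
  invisible(x)
}

#' Total arc length of a fibril
#'
#' Sum of Euclidean norms of consecutive segments.
#'
#' @param fib a [fibril()].
#' @return length in nm.
#' @export
#' @examples
#' fibril_length(fibril(rbind(c(0, 0, 0), c(3, 4, 0))))  # 5
fibril_length <- function(fib) {
  p <- fib$points
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Read fibril polylines from CSV or VTK legacy polydata
#'
#' CSV dialect: mandatory header `fibril_id,x_nm,y_nm,z_nm`, rows ordered
#' along each fibril. VTK dialect: legacy ASCII POLYDATA with one polyline
#' cell per fibril. Fibrils shorter than `min_length` are dropped with a
#' message (the count is also returned as an attribute `n_dropped`).
#'
#' @param path input file; dialect chosen by extension (`.csv` vs
#'   `.vtk`).
#' @param min_length minimum retained arc length in nm (default 100, the
#'   tracing minimum).
#' @param radius cylinder radius assigned to every fibril (nm).
#' @return list of [fibril()] objects, attribute `n_dropped`.
#' @export
read_fibrils <- function(path, min_length = .default_min_fibril_length_nm,
                         radius = .default_fibril_radius_nm) {
  if (grepl("\\.vtk$", path, ignore.case = TRUE)) {
    fl <- .read_fibrils_vtk(path, radius)
  } else {
    fl <- .read_fibrils_csv(path, radius)
  }
  lens <- vapply(fl, fibril_length, numeric(1))
  keep <- lens >= min_length
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(sprintf("read_fibrils: dropped %d fibril(s) below %g nm",
                    n_dropped, min_length))
  structure(fl[keep], n_dropped = n_dropped)
}

.read_fibrils_csv <- function(path, radius) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("fibril_id", "x_nm", "y_nm", "z_nm")
  if (!all(need %in% names(df)))
    .stopf("fibril CSV must have header %s", paste(need, collapse = ","),
           class = "fibrilstats_format_error")
  ids <- unique(df$fibril_id)
  lapply(ids, function(i) {
    rows <- df[df$fibril_id == i, , drop = FALSE]
    fibril(cbind(rows$x_nm, rows$y_nm, rows$z_nm), id = i, radius = radius)
  })
}

.read_fibrils_vtk <- function(path, radius) {
  ln <- readLines(path)
  ip <- grep("^POINTS", ln)
  il <- grep("^LINES", ln)
  if (!length(ip) || !length(il))
    .stopf("%s is not a legacy VTK polydata polyline file", path,
           class = "fibrilstats_format_error")
  npts <- as.integer(strsplit(trimws(ln[ip]), "\\s+")[[1]][2])
  nums <- as.numeric(scan(text = paste(ln[(ip + 1):(il - 1)], collapse = " "),
                          what = numeric(), quiet = TRUE))
  pts <- matrix(nums[seq_len(3 * npts)], ncol = 3, byrow = TRUE)
  ncell <- as.integer(strsplit(trimws(ln[il]), "\\s+")[[1]][2])
  idx <- as.integer(scan(text = paste(ln[(il + 1):length(ln)], collapse = " "),
                         what = integer(), quiet = TRUE))
  out <- vector("list", ncell)
  pos <- 1
  for (c_i in seq_len(ncell)) {
    k <- idx[pos]
    sel <- idx[(pos + 1):(pos + k)] + 1L   # VTK indices are 0-based
    out[[c_i]] <- fibril(pts[sel, , drop = FALSE], id = c_i, radius = radius)
    pos <- pos + k + 1
  }
  out
}

#' Write fibrils to CSV (`fibril_id,x_nm,y_nm,z_nm`)
#' @param fibrils list of [fibril()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fibrils_csv <- function(fibrils, path) {
  df <- do.call(rbind, lapply(fibrils, function(f)
    data.frame(fibril_id = f$id, x_nm = f$points[, 1], y_nm = f$points[, 2],
               z_nm = f$points[, 3])))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write fibrils as legacy VTK polydata (ASCII)
#' @param fibrils list of [fibril()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fibrils_vtk <- function(fibrils, path) {
  npts <- vapply(fibrils, function(f) nrow(f$points), integer(1))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c("# vtk DataFile Version 3.0", "fibril polylines", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", sum(npts))), con)
  for (f in fibrils)
    writeLines(apply(f$points, 1, function(p)
      sprintf("%.6f %.6f %.6f", p[1], p[2], p[3])), con)
  writeLines(sprintf("LINES %d %d", length(fibrils), sum(npts) + length(npts)),
             con)
  off <- 0L
  for (k in seq_along(fibrils)) {
    writeLines(paste(c(npts[k], seq.int(off, off + npts[k] - 1L)),
                     collapse = " "), con)
    off <- off + npts[k]
  }
  invisible(path)
}

#' Resample a fibril at uniform arc-length spacing
#'
#' Linear interpolation along the polyline at arc-length positions
#' `0, step, 2*step, ...`, with the original endpoint appended so endpoints
#' and total length are preserved (the final segment may be shorter than
#' `step`). Resampling an already uniformly resampled fibril is a no-op,
#' so the operation is idempotent.
#'
#' @param fib a [fibril()].
#' @param step spacing in nm (> 0).
#' @return a resampled [fibril()]; a two-point fibril (endpoints only, with
#'   a warning) when `step >= ` fibril length.
#' @export
resample_polyline <- function(fib, step) {
  if (step <= 0) .stopf("step must be positive")
  p <- fib$points
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  L <- sum(seg)
  if (step >= L) {
    warning(sprintf("fibril %s: step %g >= length %g; returning endpoints",
                    fib$id, step, L))
    return(fibril(p[c(1, nrow(p)), ], id = fib$id, radius = fib$radius))
  }
  # already uniform at this step (up to chord-vs-arc error): no-op, so the
  # operation is idempotent
  if (nrow(p) >= 3) {
    internal <- seg[-length(seg)]
    if (all(abs(internal - step) < 1e-5 * step) &&
        seg[length(seg)] <= step * (1 + 1e-5))
      return(fib)
  }
  cum <- c(0, cumsum(seg))
  s <- seq(0, L, by = step)
  if (L - s[length(s)] > 1e-9) s <- c(s, L) else s[length(s)] <- L
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(seg))
  t <- (s - cum[i]) / seg[i]
  q <- p[i, , drop = FALSE] + (p[i + 1L, , drop = FALSE] -
                                 p[i, , drop = FALSE]) * t
  fibril(q, id = fib$id, radius = fib$radius)
}
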