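#' Construct a force-distance curve
#'
#' A `fd_curve` holds one AFM force-distance trace: tip-sample separation in
#' nm (0 at the surface contact side), baseline-referenced force in pN
#' (adhesive, i.e. attractive, force is negative), and a per-sample segment
#' label (`"approach"` or `"retract"`). All rupture-event scoring operates on
#' the retract segment. On construction each segment is canonicalized to
#' strictly increasing separation, so downstream code may assume the retract
#' trace runs outward from the surface.
#'
#' @param separation numeric vector, tip-sample separation (nm), non-negative.
#' @param force numeric vector, force (pN), same length as `separation`.
#' @param segment character vector of `"approach"`/`"retract"` labels, either
#'   length 1 (recycled) or one per sample.
#' @param grid_index integer vector `c(row, col)`, non-negative, 0-based
#'   position in the force-volume grid.
#' @param surface_label free-form label of the functionalized surface the
#'   curve was recorded on (e.g. `"G7-pPDL1"`).
#' @param sample_spacing nm per sample along the separation axis; inferred
#'   from the retract grid when `NULL`.
#' @return An object of class `fd_curve`.
#' @examples
#' z <- seq(0, 50, by = 0.5)
#' crv <- fd_curve(z, -100 * exp(-z / 5), "retract")
#' range(retract_of(crv)$separation)
#' @export
fd_curve <- function(separation, force, segment = "retract",
                     grid_index = c(0L, 0L), surface_label = "unlabelled",
                     sample_spacing = NULL) {
  separation <- as.numeric(separation)
  force <- as.numeric(force)
  if (length(separation) != length(force))
    stop("separation and force must have equal length", call. = FALSE)
  if (length(separation) < 8L)
    stop("a force-distance curve needs at least 8 samples", call. = FALSE)
  if (!all(is.finite(separation)) || !all(is.finite(force)))
    stop("separation and force must be finite", call. = FALSE)
  if (length(segment) == 1L) segment <- rep(segment, length(separation))
  if (length(segment) != length(separation))
    stop("segment labels must be length 1 or one per sample", call. = FALSE)
  if (!all(segment %in% c("approach", "retract")))
    stop("segment labels must be 'approach' or 'retract'", call. = FALSE)
  grid_index <- as.integer(grid_index)
  if (length(grid_index) != 2L || any(is.na(grid_index)) || any(grid_index < 0L))
    stop("grid_index must be two non-negative integers", call. = FALSE)

  # canonical order: within each segment, strictly increasing separation
  ord <- order(match(segment, c("approach", "retract")), separation)
  separation <- separation[ord]; force <- force[ord]; segment <- segment[ord]
  for (seg in unique(segment)) {
    zs <- separation[segment == seg]
    if (any(diff(zs) <= 0))
      stop("separation must be strictly monotone within segment '", seg, "'",
           call. = FALSE)
  }
  if (is.null(sample_spacing)) {
    zr <- separation[segment == "retract"]
    sample_spacing <- if (length(zr) >= 2L) stats::median(diff(zr)) else NA_real_
  }
  structure(
    list(separation = separation, force = force, segment = segment,
         grid_index = grid_index, surface_label = surface_label,
         sample_spacing = sample_spacing),
    class = "fd_curve"
  )
}

#' @export
print.fd_curve <- function(x, ...) {
  nr <- sum(x$segment == "retract")
  cat(sprintf(
    "<fd_curve> %s @ grid (%d,%d): %d samples (%d retract), z %.1f-%.1f nm, F [%.1f, %.1f] pN\n",
    x$surface_label, x$grid_index[1], x$grid_index[2], length(x$force), nr,
    min(x$separation), max(x$separation), min(x$force), max(x$force)))
  invisible(x)
}

#' Extract the retract segment of a curve
#'
#' @param curve an [fd_curve()].
#' @return A list with `separation` and `force` vectors of the retract
#'   segment (strictly increasing separation).
#' @export
retract_of <- function(curve) {
  stopifnot(inherits(curve, "fd_curve"))
  i <- curve$segment == "retract"
  if (!any(i)) stop("curve has no retract segment", call. = FALSE)
  list(separation = curve$separation[i], force = curve$force[i])
}

# replace the retract-segment forces of a curve, preserving everything else
replace_retract_force <- function(curve, force) {
  i <- curve$segment == "retract"
  stopifnot(sum(i) == length(force))
  curve$force[i] <- force
  curve
}

#' Construct a force-volume grid
#'
#' An `fd_grid` is a collection of [fd_curve()]s acquired on a regular
#' `n_rows` x `n_cols` raster over a square scan area (the mapping
#' experiments use 20 x 20 curves over 2 x 2 um). Grid indices must be
#' unique and inside the raster.
#'
#' @param curves list of [fd_curve()] objects.
#' @param n_rows,n_cols raster dimensions (default 20 x 20).
#' @param scan_extent_um scan edge length in micrometres (default 2).
#' @param surface_label label for the surface; defaults to the label of the
#'   first curve.
#' @return An object of class `fd_grid`.
#' @export
fd_grid <- function(curves, n_rows = 20L, n_cols = 20L, scan_extent_um = 2,
                    surface_label = NULL) {
  stopifnot(is.list(curves))
  if (!all(vapply(curves, inherits, logical(1), "fd_curve")))
    stop("all elements of curves must be fd_curve objects", call. = FALSE)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (length(curves) > n_rows * n_cols)
    stop("more curves than grid positions", call. = FALSE)
  idx <- vapply(curves, function(cv) paste(cv$grid_index, collapse = ","),
                character(1))
  if (anyDuplicated(idx))
    stop("duplicate grid_index in grid: ", idx[duplicated(idx)][1], call. = FALSE)
  for (cv in curves) {
    if (cv$grid_index[1] >= n_rows || cv$grid_index[2] >= n_cols)
      stop("grid_index (", paste(cv$grid_index, collapse = ","),
           ") outside ", n_rows, "x", n_cols, " raster", call. = FALSE)
  }
  if (is.null(surface_label))
    surface_label <- if (length(curves)) curves[[1]]$surface_label else "unlabelled"
  structure(
    list(curves = curves, n_rows = n_rows, n_cols = n_cols,
         scan_extent_um = scan_extent_um, surface_label = surface_label),
    class = "fd_grid"
  )
}

#' @export
print.fd_grid <- function(x, ...) {
  cat(sprintf("<fd_grid> %s: %d curves on %dx%d raster (%g x %g um)\n",
              x$surface_label, length(x$curves), x$n_rows, x$n_cols,
              x$scan_extent_um, x$scan_extent_um))
  invisible(x)
}

fd_curve_ids <- function(grid) {
  vapply(grid$curves,
         function(cv) sprintf("r%02dc%02d", cv$grid_index[1], cv$grid_index[2]),
         character(1))
}

sidecar_path <- function(path) paste0(sub("\\.tsv$", "", path), ".json")

#' Write a force-volume grid to long-format TSV
#'
#' The on-disk dialect is a single UTF-8 tab-separated file with columns
#' `curve_id`, `segment`, `separation_nm`, `force_pN` ('.' decimal, fixed
#' `%.6f` formatting so write-read-write round-trips are byte identical),
#' plus a JSON sidecar (`<path minus .tsv>.json`) with the grid metadata
#' (`n_rows`, `n_cols`, `scan_extent_um`, `surface_label`).
#'
#' @param grid an [fd_grid()].
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @seealso [read_fd_curves()]
#' @export
write_fd_curves <- function(grid, path) {
  stopifnot(inherits(grid, "fd_grid"))
  ids <- fd_curve_ids(grid)
  rows <- lapply(seq_along(grid$curves), function(i) {
    cv <- grid$curves[[i]]
    data.table::data.table(
      curve_id = ids[i], segment = cv$segment,
      separation_nm = sprintf("%.6f", cv$separation),
      force_pN = sprintf("%.6f", cv$force))
  })
  dt <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(curve_id = character(), segment = character(),
                           separation_nm = character(), force_pN = character())
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  meta <- list(n_rows = grid$n_rows, n_cols = grid$n_cols,
               scan_extent_um = grid$scan_extent_um,
               surface_label = grid$surface_label,
               grid_index = lapply(grid$curves, function(cv) cv$grid_index))
  names(meta$grid_index) <- ids
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a force-volume grid from long-format TSV
#'
#' Reads the dialect written by [write_fd_curves()]. Rows with non-finite
#' separation or force are rejected with an error naming the offending
#' curve, as are curves with fewer than 8 samples.
#'
#' @param path TSV path; the JSON sidecar is looked up next to it (grids
#'   without a sidecar get default 20x20 metadata and indices assigned in
#'   row-major file order).
#' @param dialect currently only `"long_tsv"`.
#' @return An [fd_grid()].
#' @export
read_fd_curves <- function(path, dialect = "long_tsv") {
  if (!identical(dialect, "long_tsv"))
    stop("unknown dialect: ", dialect, call. = FALSE)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", colClasses = list(
    character = c("curve_id", "segment")))
  need <- c("curve_id", "segment", "separation_nm", "force_pN")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols))
    stop("format error: missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  meta <- NULL
  if (file.exists(sidecar_path(path)))
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  ids <- unique(dt$curve_id)
  curves <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sub <- dt[dt$curve_id == ids[i], ]
    if (!all(is.finite(sub$separation_nm)) || !all(is.finite(sub$force_pN)))
      stop("validation error: non-finite values in curve '", ids[i], "'",
           call. = FALSE)
    if (nrow(sub) < 8L)
      stop("validation error: curve '", ids[i], "' has fewer than 8 samples",
           call. = FALSE)
    gi <- if (!is.null(meta$grid_index[[ids[i]]])) {
      as.integer(meta$grid_index[[ids[i]]])
    } else {
      nc <- if (!is.null(meta$n_cols)) meta$n_cols else 20L
      c((i - 1L) %/% nc, (i - 1L) %% nc)
    }
    curves[[i]] <- fd_curve(sub$separation_nm, sub$force_pN, sub$segment,
                            grid_index = gi,
                            surface_label = if (!is.null(meta$surface_label))
                              meta$surface_label else "unlabelled")
  }
  fd_grid(curves,
          n_rows = if (!is.null(meta$n_rows)) meta$n_rows else 20L,
          n_cols = if (!is.null(meta$n_cols)) meta$n_cols else 20L,
          scan_extent_um = if (!is.null(meta$scan_extent_um)) meta$scan_extent_um else 2,
          surface_label = if (!is.null(meta$surface_label)) meta$surface_label
          else "unlabelled")
}
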