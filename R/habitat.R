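# Categorical habitat rasters: reclassification and composition of core-use
# isopleths. Rasters are plain integer grids (ESRI ASCII format on disk);
# the polygon overlay rule is cell-centre rasterization.

#' Construct a habitat raster
#'
#' @param values integer matrix of class ids; row 1 is the northern-most row
#'   (as in an ESRI ASCII grid).
#' @param cellsize cell edge length in metres.
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @param nodata no-data value (default -9999).
#' @param legend named integer vector mapping class names to ids.
#' @return Object of class `"habitat_raster"`.
#' @export
habitat_raster <- function(values, cellsize, xll = 0, yll = 0,
                           nodata = -9999L, legend = NULL) {
  stopifnot(is.matrix(values), cellsize > 0)
  structure(list(values = values, cellsize = cellsize, xll = xll, yll = yll,
                 nodata = nodata, legend = legend),
            class = "habitat_raster")
}

#' @export
print.habitat_raster <- function(x, ...) {
  cat(sprintf("Habitat raster: %d x %d cells, %.0f m resolution\n",
              nrow(x$values), ncol(x$values), x$cellsize))
  tab <- table(x$values[x$values != x$nodata])
  nm <- if (!is.null(x$legend)) names(x$legend)[match(names(tab), x$legend)]
        else names(tab)
  cat("  classes:", paste0(nm, " (", tab, ")", collapse = ", "), "\n")
  invisible(x)
}

# Cell-centre coordinates (x for columns, y for rows; row 1 = top).
raster_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  list(x = r$xll + (seq_len(nc) - 0.5) * r$cellsize,
       y = r$yll + (nr - seq_len(nr) + 0.5) * r$cellsize)
}

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` file path.
#' @param legend optional named integer vector of class names.
#' @return A [habitat_raster()].
#' @export
read_asc <- function(path, legend = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, n = 6)
  hdr <- list()
  for (l in lines) {
    parts <- strsplit(trimws(l), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("not an ESRI ASCII grid: missing header field(s)")
  }
  nodata <- if ("nodata_value" %in% names(hdr)) hdr$nodata_value else -9999
  vals <- scan(path, skip = length(hdr), quiet = TRUE)
  m <- matrix(as.integer(vals), nrow = hdr$nrows, ncol = hdr$ncols,
              byrow = TRUE)
  habitat_raster(m, hdr$cellsize, hdr$xllcorner, hdr$yllcorner,
                 as.integer(nodata), legend)
}

#' Write an ESRI ASCII grid
#'
#' @param r a [habitat_raster()].
#' @param path output path.
#' @export
write_asc <- function(r, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(r$values)),
               paste("nrows", nrow(r$values)),
               paste("xllcorner", r$xll),
               paste("yllcorner", r$yll),
               paste("cellsize", r$cellsize),
               paste("NODATA_value", r$nodata)), con)
  utils::write.table(r$values, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Reclassify a habitat raster
#'
#' @param r a [habitat_raster()].
#' @param mapping named integer vector or two-column data frame (`from`,
#'   `to`) mapping original class ids to target ids. Every id present in the
#'   raster must be mapped (no-data cells excepted).
#' @param legend optional named integer vector for the new classes.
#' @return The relabelled raster.
#' @export
reclassify <- function(r, mapping, legend = NULL) {
  if (is.data.frame(mapping)) {
    map <- stats::setNames(as.integer(mapping$to), mapping$from)
  } else {
    map <- mapping
  }
  vals <- r$values
  present <- unique(vals[vals != r$nodata])
  unmapped <- setdiff(present, as.integer(names(map)))
  if (length(unmapped)) {
    stop("unmapped raster class id(s): ", paste(sort(unmapped), collapse = ", "))
  }
  out <- vals
  sel <- vals != r$nodata
  out[sel] <- map[as.character(vals[sel])]
  habitat_raster(out, r$cellsize, r$xll, r$yll, r$nodata, legend)
}

#' Habitat composition of a polygon or isopleth
#'
#' Cells whose centre lies inside the region are tallied by class;
#' proportions are computed over the non-excluded classes (mirroring the
#' exclusion of water and infrastructure from composition analyses).
#'
#' @param region an `"isopleth"` or a convex polygon matrix.
#' @param r a [habitat_raster()].
#' @param exclude integer vector of class ids to exclude.
#' @return List of class `"habitat_composition"`: `proportions` (named over
#'   included classes, summing to 1), `n_cells`, `excluded_fraction`.
#' @export
composition <- function(region, r, exclude = integer(0)) {
  cc <- raster_centers(r)
  pts <- expand.grid(x = cc$x, y = cc$y)
  inside <- if (inherits(region, "isopleth")) {
    in_isopleth(region, pts$x, pts$y)
  } else {
    points_in_convex(pts$x, pts$y, region)
  }
  # expand.grid(x, y) varies x fastest; values[row, col] has rows = y
  vals <- t(r$values)[inside]
  vals <- vals[vals != r$nodata]
  if (!length(vals)) stop("polygon covers no raster cells")
  excl_frac <- mean(vals %in% exclude)
  vals <- vals[!vals %in% exclude]
  if (!length(vals)) stop("no included cells after exclusion")
  tab <- table(vals)
  props <- as.numeric(tab) / sum(tab)
  ids <- as.integer(names(tab))
  nm <- if (!is.null(r$legend)) names(r$legend)[match(ids, r$legend)]
        else as.character(ids)
  structure(list(proportions = stats::setNames(props, nm),
                 class_ids = ids, n_cells = sum(tab),
                 excluded_fraction = excl_frac),
            class = "habitat_composition")
}

#' @export
print.habitat_composition <- function(x, ...) {
  cat("Habitat composition over", x$n_cells, "cells",
      sprintf("(%.1f%% excluded)\n", 100 * x$excluded_fraction))
  print(round(x$proportions, 3))
  invisible(x)
}

#' Long-format habitat composition table for a set of animals
#'
#' One row per animal x ordering x habitat class: the analysis-ready table
#' for multivariate comparisons of NSV- and MNLV-range composition.
#' Per-animal failures are reported as warnings and skipped so one bad
#' geometry does not abort the batch.
#'
#' @param isos nested list: `isos[[animal]][[ordering]]` is a 50%
#'   `"isopleth"`; orderings are typically `"nsv"` and `"mnlv"`.
#' @param r a [habitat_raster()] with a legend.
#' @param exclude class ids excluded from the proportions.
#' @return Data frame with `animal`, `ordering`, `class_id`, `class_name`,
#'   `proportion` (all raster classes listed, zero-filled).
#' @export
composition_table <- function(isos, r, exclude = integer(0)) {
  all_ids <- if (!is.null(r$legend)) unname(r$legend) else
    sort(unique(r$values[r$values != r$nodata]))
  all_ids <- setdiff(all_ids, exclude)
  all_nm <- if (!is.null(r$legend)) {
    names(r$legend)[match(all_ids, r$legend)]
  } else {
    as.character(all_ids)
  }
  rows <- list()
  for (animal in names(isos)) {
    for (ordering in names(isos[[animal]])) {
      comp <- tryCatch(composition(isos[[animal]][[ordering]], r, exclude),
                       error = function(e) {
                         warning("composition failed for ", animal, "/",
                                 ordering, ": ", conditionMessage(e))
                         NULL
                       })
      if (is.null(comp)) next
      prop <- stats::setNames(rep(0, length(all_ids)), all_ids)
      prop[as.character(comp$class_ids)] <- comp$proportions
      rows[[length(rows) + 1L]] <- data.frame(
        animal = animal, ordering = ordering, class_id = all_ids,
        class_name = all_nm, proportion = unname(prop))
    }
  }
  do.call(rbind, rows)
}
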