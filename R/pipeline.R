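# Configuration-driven orchestration: screening -> hullsets -> isopleths ->
# dyads/Minta -> habitat composition -> summary tables, with a run manifest.

#' Default pipeline configuration
#'
#' All defaults follow the field protocol the package implements: 12-h
#' inter-visit gap, 50/95% isopleths, 3.2-km neighbour rule, 5-min
#' simultaneity buffer, 999 permutations.
#'
#' @return Nested list of configuration defaults; override entries and pass
#'   to [run_pipeline()].
#' @export
default_config <- function() {
  list(
    projection = list(center = NULL),
    screening = list(bin_width = 12, max_lag = 24 * 45,
                     plateau_window = c(5, 10) * 24,
                     tail_window = c(25, 40) * 24, tol = 0.5, hampel_k = 3),
    tlocoh = list(s = NULL, a = NULL, ivg = 43200, levels = c(0.5, 0.95),
                  grid_n = 256),
    interactions = list(threshold = 3200, buffer = 300,
                        p_method = "chisq", alpha = 0.05),
    habitat = list(raster = NULL, exclude = integer(0)),
    stats = list(n_perm = 999),
    seed = 1,
    output_dir = NULL
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a YAML pipeline configuration
#'
#' @param path YAML file; entries override [default_config()].
#' @return Merged configuration list.
#' @export
read_config <- function(path) {
  merge_config(default_config(), yaml::read_yaml(path))
}

#' Run the full space-use and interaction pipeline
#'
#' Screens each trajectory for residency, removes excursions, fits T-LoCoH
#' hullsets, builds density (50/95%) and NSV/MNLV (50%) isopleths, finds
#' neighbouring dyads and computes their overlap and Minta coefficients, and
#' (when a raster is configured) tabulates habitat composition. Writes
#' per-stage CSV/GeoJSON outputs plus a JSON manifest when `output_dir` is
#' set. Deterministic for a fixed configuration.
#'
#' @param trajs named list of `traj` objects (projected, or with lon/lat to
#'   be projected), or a fix-table CSV path.
#' @param config configuration list (see [default_config()]) or a YAML path.
#' @param species optional named character vector of species labels
#'   (defaults to the labels stored on the trajectories).
#' @return Class `"dyadhulls_run"`: `verdicts`, `fits`, `isopleths`,
#'   `dyads`, `overlaps`, `minta`, `habitat`, `manifest`.
#' @export
run_pipeline <- function(trajs, config = default_config(), species = NULL) {
  if (is.character(config)) config <- read_config(config)
  config <- merge_config(default_config(), config)
  if (is.character(trajs)) trajs <- read_fix_table(trajs)
  stopifnot(length(trajs) >= 1)
  if (is.null(names(trajs)) || any(!nzchar(names(trajs)))) {
    names(trajs) <- vapply(trajs, `[[`, character(1), "animal_id")
  }
  if (is.null(species)) {
    species <- vapply(trajs, function(tr) {
      if (is.null(tr$species)) NA_character_ else tr$species
    }, character(1))
  }
  if (!all(vapply(trajs, function(tr) all(is.finite(tr$fixes$x)), logical(1)))) {
    trajs <- project_to_plane(trajs, center = config$projection$center)
  }
  hab_cfg <- config$habitat
  if (!is.null(hab_cfg$raster) && is.character(hab_cfg$raster) &&
      !file.exists(hab_cfg$raster)) {
    stop("configured habitat raster not found: ", hab_cfg$raster)
  }

  sc <- config$screening
  verdicts <- list(); kept <- list(); excursions <- list()
  for (id in names(trajs)) {
    tr <- trajs[[id]]
    res <- tryCatch({
      vg <- empirical_variogram(tr, bin_width = sc$bin_width,
                                max_lag = sc$max_lag)
      assess_residency(vg, plateau_window = sc$plateau_window,
                       tail_window = sc$tail_window, tol = sc$tol)
    }, error = function(e) {
      structure(list(verdict = paste("error:", conditionMessage(e)),
                     ratio = NA), class = "residency")
    })
    verdicts[[id]] <- res$verdict
    if (identical(res$verdict, "resident")) {
      ef <- remove_excursions(tr, k = sc$hampel_k)
      kept[[id]] <- ef$kept
      excursions[[id]] <- ef$excursions
    }
  }
  excursions <- do.call(rbind, excursions)

  tc <- config$tlocoh
  fits <- list(); isos <- list()
  for (id in names(kept)) {
    fits[[id]] <- tlocoh(kept[[id]], s = tc$s, a = tc$a, ivg = tc$ivg)
    isos[[id]] <- list(
      density = isopleths(fits[[id]], "density", levels = tc$levels,
                          grid_n = tc$grid_n),
      nsv = isopleths(fits[[id]], "nsv", levels = 0.5, grid_n = tc$grid_n),
      mnlv = isopleths(fits[[id]], "mnlv", levels = 0.5, grid_n = tc$grid_n))
  }

  ic <- config$interactions
  hr <- lapply(isos, function(z) {
    z$density$isopleths[[length(z$density$levels)]]
  })
  core <- lapply(isos, function(z) z$density$isopleths[[1]])
  dyads <- if (length(hr) >= 2) {
    find_dyads(hr, threshold = ic$threshold, species = species)
  } else {
    data.frame(a = character(), b = character(),
               species_pair = character(), distance_m = numeric())
  }
  overlaps <- NULL; minta_res <- list()
  if (nrow(dyads)) {
    rows <- lapply(seq_len(nrow(dyads)), function(i) {
      a <- dyads$a[i]; b <- dyads$b[i]
      ov <- overlap_index(hr[[a]], hr[[b]])
      ovc <- tryCatch(overlap_index(core[[a]], core[[b]]),
                      error = function(e) list(index = NA_real_))
      data.frame(a = a, b = b, species_pair = dyads$species_pair[i],
                 overlap_95 = ov$index, overlap_50 = ovc$index)
    })
    overlaps <- do.call(rbind, rows)
    for (i in seq_len(nrow(dyads))) {
      a <- dyads$a[i]; b <- dyads$b[i]
      mr <- tryCatch(
        minta(kept[[a]], kept[[b]], hr[[a]], hr[[b]], buffer = ic$buffer,
              p_method = ic$p_method, alpha = ic$alpha),
        error = function(e) conditionMessage(e))
      minta_res[[paste(a, b, sep = "-")]] <- mr
    }
  }

  hab <- NULL
  if (!is.null(hab_cfg$raster)) {
    r <- if (is.character(hab_cfg$raster)) read_asc(hab_cfg$raster)
         else hab_cfg$raster
    core_isos <- lapply(isos, function(z) {
      list(nsv = z$nsv$isopleths[[1]], mnlv = z$mnlv$isopleths[[1]])
    })
    hab <- composition_table(core_isos, r, exclude = hab_cfg$exclude)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("dyadhulls")),
    seed = config$seed,
    n_animals = length(trajs),
    verdicts = verdicts,
    params = lapply(fits, function(fz) fz$params),
    config = config[c("screening", "tlocoh", "interactions", "stats")],
    n_dyads = nrow(dyads))

  out <- structure(list(verdicts = verdicts, excursions = excursions,
                        fits = fits, isopleths = isos, dyads = dyads,
                        overlaps = overlaps, minta = minta_res,
                        habitat = hab, manifest = manifest),
                   class = "dyadhulls_run")
  if (!is.null(config$output_dir)) write_run(out, config$output_dir)
  out
}

#' @export
print.dyadhulls_run <- function(x, ...) {
  cat("dyadhulls pipeline run\n")
  cat("  animals:", length(x$verdicts),
      " residents:", sum(unlist(x$verdicts) == "resident"), "\n")
  cat("  dyads:", nrow(x$dyads), "\n")
  if (!is.null(x$habitat)) {
    cat("  habitat rows:", nrow(x$habitat), "\n")
  }
  invisible(x)
}

write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(run$excursions) && nrow(run$excursions)) {
    utils::write.csv(run$excursions, file.path(dir, "excursions.csv"),
                     row.names = FALSE)
  }
  if (!is.null(run$overlaps)) {
    utils::write.csv(run$overlaps, file.path(dir, "overlaps.csv"),
                     row.names = FALSE)
  }
  if (length(run$minta)) {
    utils::write.csv(minta_table(run$minta), file.path(dir, "minta.csv"),
                     row.names = FALSE)
  }
  if (!is.null(run$habitat)) {
    utils::write.csv(run$habitat, file.path(dir, "habitat_composition.csv"),
                     row.names = FALSE)
  }
  for (id in names(run$isopleths)) {
    write_isopleth_geojson(run$isopleths[[id]]$density,
                           file.path(dir, paste0("isopleths_", id, ".geojson")))
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(dir)
}

#' Flatten Minta dyad results to a table
#'
#' @param minta_list named list of `"minta"` objects (error strings allowed,
#'   they are skipped).
#' @return Data frame mirroring the columns of a dyad interaction table:
#'   coefficients, p-values, labels and the four odds.
#' @export
minta_table <- function(minta_list) {
  rows <- lapply(names(minta_list), function(nm) {
    m <- minta_list[[nm]]
    if (!inherits(m, "minta")) return(NULL)
    data.frame(dyad = nm, a = m$a, b = m$b,
               L_a = m$spatial_a$L, p_a = m$spatial_a$p,
               L_b = m$spatial_b$L, p_b = m$spatial_b$p,
               L_ixn = m$temporal$L_ixn, p_ixn = m$temporal$p,
               spatial = m$labels$spatial, temporal = m$labels$temporal,
               odds_ab = m$odds[["AB"]], odds_a0 = m$odds[["A0"]],
               odds_0b = m$odds[["0B"]], odds_00 = m$odds[["00"]],
               n_pairs = m$n_pairs)
  })
  do.call(rbind, rows)
}

#' Overlap summary by species pair
#'
#' Mean, standard error, min, max, median and n of an overlap column per
#' species pair — the standard per-dyad-type summary table.
#'
#' @param overlaps data frame with `species_pair` and the overlap column.
#' @param column which column to summarize (default `"overlap_95"`).
#' @return One row per species pair.
#' @export
overlap_summary <- function(overlaps, column = "overlap_95") {
  sp <- split(overlaps[[column]], overlaps$species_pair)
  rows <- lapply(names(sp), function(nm) {
    v <- sp[[nm]][is.finite(sp[[nm]])]
    data.frame(species_pair = nm, mean = mean(v),
               se = stats::sd(v) / sqrt(length(v)), min = min(v),
               max = max(v), median = stats::median(v), n = length(v))
  })
  do.call(rbind, rows)
}

#' Write isopleths as GeoJSON
#'
#' One feature per level with a MultiPolygon of the boundary rings and
#' properties `animal`, `level`, `ordering`, `area_m2`, `n_fixes`.
#' Coordinates are in the local planar metric system (or geographic degrees
#' when a projection is supplied for unprojecting).
#'
#' @param iso_set an `"isopleth_set"`.
#' @param path output `.geojson` path.
#' @param projection optional projection list (`lon0`, `lat0`) to write
#'   longitude/latitude instead of metres.
#' @return The path, invisibly.
#' @export
write_isopleth_geojson <- function(iso_set, path, projection = NULL) {
  features <- lapply(iso_set$isopleths, function(iso) {
    rings <- lapply(iso$rings, function(r) {
      if (!is.null(projection)) r <- unproject(r[, 1], r[, 2], projection)
      r <- rbind(r, r[1, , drop = FALSE])  # close the ring
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
    })
    list(type = "Feature",
         properties = list(animal = iso_set$animal_id, level = iso$level,
                           ordering = iso$ordering, area_m2 = iso$area,
                           n_fixes = iso$n_fixes),
         geometry = list(type = "MultiPolygon",
                         coordinates = lapply(rings, list)))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
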