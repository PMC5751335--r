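#' Importance grids (coefficient x standard deviation) per field
#'
#' Maps a fitted model's coefficients back onto the lattice: the importance
#' of grid point j in field b is `beta_j * sd_j` (pE units), the
#' STDEV*COEFF convention used for QSAR contour maps. Columns removed by
#' filtering carry importance 0.
#'
#' @param model a `qsar_pls` produced by [fit_field_model()] (it carries the
#'   descriptor assembly metadata), or a plain `qsar_pls` plus an explicit
#'   `descriptors` argument.
#' @param descriptors assembly metadata from [assemble_descriptors()].
#' @return named list of `qsar_importance_grid` objects (one per field):
#'   `kind`, `values` (length = lattice points, zeros at dropped columns),
#'   `lattice`.
#' @export
importance_grid <- function(model, descriptors = model$descriptors) {
  if (is.null(descriptors))
    stop("model carries no descriptor metadata; pass 'descriptors'")
  if (length(descriptors$col_block) != model$p)
    stop("descriptor metadata does not match the model's column count")
  imp <- model$coefficients * model$col_sd
  lattice <- descriptors$lattice
  out <- list()
  for (kind in unique(descriptors$col_block)) {
    sel <- descriptors$col_block == kind
    values <- numeric(lattice$n_points)
    values[descriptors$col_point[sel]] <- imp[sel]
    out[[kind]] <- structure(list(kind = kind, values = values,
                                  lattice = lattice),
                             class = "qsar_importance_grid")
  }
  out
}

#' Contour levels from cumulative importance mass
#'
#' The favourable (positive) level is the threshold such that cells with
#' importance >= threshold account for `(100 - favored_pct)%` of the total
#' positive importance mass: with the conventional `favored_pct = 80`, the
#' favourable region carries the top 20% of positive mass. The unfavourable
#' level mirrors this on the negative side with `disfavored_pct`: cells with
#' importance <= level account for `(100 - disfavored_pct)%` of the total
#' negative magnitude. The rule is fixed and documented so regions are
#' reproducible; the percentages are free parameters.
#'
#' @param grid a `qsar_importance_grid`.
#' @param favored_pct percentile parameter for the positive level.
#' @param disfavored_pct percentile parameter for the negative level.
#' @return list with `positive` and `negative` levels (NA where the grid has
#'   no mass of that sign).
#' @export
contour_levels <- function(grid, favored_pct = 80, disfavored_pct = 20) {
  v <- grid$values
  if (all(v == 0)) stop("all-zero importance grid")
  pos <- sort(v[v > 0], decreasing = TRUE)
  neg <- sort(-v[v < 0], decreasing = TRUE)   # magnitudes
  level_of <- function(mass, pct) {
    if (!length(mass)) return(NA_real_)
    target <- (100 - pct) / 100 * sum(mass)
    k <- which(cumsum(mass) >= target - 1e-12)[1]
    mass[k]
  }
  list(positive = level_of(pos, favored_pct),
       negative = -level_of(neg, disfavored_pct))
}

#' Extract contour regions at given levels
#'
#' @param grid a `qsar_importance_grid`.
#' @param levels list as returned by [contour_levels()].
#' @return list with `favorable` and `unfavorable`, each a data frame of
#'   grid-point coordinates and importance values.
#' @export
contour_region <- function(grid, levels = contour_levels(grid)) {
  gp <- lattice_points(grid$lattice)
  mk <- function(sel) {
    data.frame(x = gp[sel, 1], y = gp[sel, 2], z = gp[sel, 3],
               importance = grid$values[sel])
  }
  fav <- if (is.na(levels$positive)) logical(length(grid$values)) else
    grid$values >= levels$positive
  unf <- if (is.na(levels$negative)) logical(length(grid$values)) else
    grid$values <= levels$negative
  list(favorable = mk(which(fav)), unfavorable = mk(which(unf)))
}

#' Write an importance grid as a Gaussian cube file
#'
#' Plain-text cube format readable by standard molecular viewers. Cube files
#' store the grid in Bohr; coordinates are converted from Angstrom. The
#' optional molecule provides the atom block (element symbols are written as
#' atomic numbers for the common organic elements).
#'
#' @param grid a `qsar_importance_grid`.
#' @param path output file.
#' @param mol optional molecule to embed.
#' @return `path`, invisibly.
#' @export
write_cube <- function(grid, path, mol = NULL) {
  bohr <- 1 / 0.529177210903
  lat <- grid$lattice
  zmap <- c(H = 1, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16,
            Cl = 17, Br = 35, I = 53)
  natoms <- if (is.null(mol)) 0L else n_atoms(mol)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("qsar3d importance grid:", grid$kind),
               "STDEV*COEFF field importance (pE units)"), con)
  writeLines(sprintf("%5d%12.6f%12.6f%12.6f", natoms,
                     lat$origin[1] * bohr, lat$origin[2] * bohr,
                     lat$origin[3] * bohr), con)
  step <- lat$spacing * bohr
  writeLines(c(sprintf("%5d%12.6f%12.6f%12.6f", lat$counts[1], step, 0, 0),
               sprintf("%5d%12.6f%12.6f%12.6f", lat$counts[2], 0, step, 0),
               sprintf("%5d%12.6f%12.6f%12.6f", lat$counts[3], 0, 0, step)),
             con)
  if (natoms > 0L) {
    z <- zmap[mol$atoms$element]
    z[is.na(z)] <- 0
    xyz <- coords(mol) * bohr
    writeLines(sprintf("%5d%12.6f%12.6f%12.6f%12.6f", z, 0,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  # cube scans z fastest for fixed (x, y); our raster order is x fastest
  arr <- array(grid$values, dim = lat$counts)
  for (i in seq_len(lat$counts[1])) {
    for (j in seq_len(lat$counts[2])) {
      vals <- arr[i, j, ]
      for (off in seq(1, length(vals), by = 6)) {
        chunk <- vals[off:min(off + 5, length(vals))]
        writeLines(paste(sprintf("%13.5E", chunk), collapse = ""), con)
      }
    }
  }
  invisible(path)
}

#' Write an importance grid in OpenDX format
#'
#' @param grid a `qsar_importance_grid`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path) {
  lat <- grid$lattice
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("object 1 class gridpositions counts %d %d %d",
                       lat$counts[3], lat$counts[2], lat$counts[1]),
               sprintf("origin %.6f %.6f %.6f", lat$origin[1], lat$origin[2],
                       lat$origin[3]),
               sprintf("delta %.6f 0 0", lat$spacing),
               sprintf("delta 0 %.6f 0", lat$spacing),
               sprintf("delta 0 0 %.6f", lat$spacing),
               sprintf("object 2 class gridconnections counts %d %d %d",
                       lat$counts[3], lat$counts[2], lat$counts[1]),
               sprintf("object 3 class array type double rank 0 items %d data follows",
                       lat$n_points)), con)
  vals <- grid$values
  for (off in seq(1, length(vals), by = 3)) {
    chunk <- vals[off:min(off + 2, length(vals))]
    writeLines(paste(sprintf("%.6e", chunk), collapse = " "), con)
  }
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}

#' Export contour maps for every field of a fitted model
#'
#' Writes one cube file per field and a JSON manifest listing field, sign,
#' level and file.
#'
#' @param model a `qsar_pls` from [fit_field_model()].
#' @param out_dir output directory (created if needed).
#' @param favored_pct,disfavored_pct see [contour_levels()].
#' @param mol optional reference molecule embedded in the cube files.
#' @return path of the manifest JSON, invisibly.
#' @export
export_contours <- function(model, out_dir, favored_pct = 80,
                            disfavored_pct = 20, mol = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grids <- importance_grid(model)
  manifest <- list()
  for (kind in names(grids)) {
    lev <- tryCatch(contour_levels(grids[[kind]], favored_pct, disfavored_pct),
                    error = function(e) NULL)
    if (is.null(lev)) next
    f <- file.path(out_dir, paste0("contour_", kind, ".cube"))
    write_cube(grids[[kind]], f, mol = mol)
    manifest[[kind]] <- list(field = kind, file = basename(f),
                             positive_level = lev$positive,
                             negative_level = lev$negative,
                             favored_pct = favored_pct,
                             disfavored_pct = disfavored_pct)
  }
  mpath <- file.path(out_dir, "contours_manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}
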