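#' Probe atom definition
#'
#' The standard probe: an sp3-carbon-like atom carrying +1 elementary charge
#' with a 1.52 Angstrom radius for the CoMFA energies, and unit
#' hydrophobicity / H-bond donor / acceptor weights for the CoMSIA
#' similarity indices.
#'
#' @param charge probe charge, elementary units.
#' @param radius probe radius, Angstrom.
#' @param lj_epsilon probe LJ well depth, kcal/mol (sp3 carbon value).
#' @param hydrophobicity,hbd_strength,hba_strength CoMSIA probe weights.
#' @return a `qsar_probe` list.
#' @export
default_probe <- function(charge = 1, radius = 1.52, lj_epsilon = 0.107,
                          hydrophobicity = 1, hbd_strength = 1,
                          hba_strength = 1) {
  structure(list(charge = charge, radius = radius, lj_epsilon = lj_epsilon,
                 hydrophobicity = hydrophobicity,
                 hbd_strength = hbd_strength, hba_strength = hba_strength),
            class = "qsar_probe")
}

#' Build the cubic lattice enclosing an aligned molecule set
#'
#' Axis-aligned bounding box of every atom of every molecule, expanded by
#' `margin` on all sides and discretised at `spacing`. Grid points are
#' ordered in raster order with x varying fastest, then y, then z; this
#' column order is fixed and shared by every field block built on the
#' lattice.
#'
#' @param mols list of aligned molecules.
#' @param spacing grid spacing, Angstrom (2.0 is the conventional setting).
#' @param margin extra box margin on every side, Angstrom.
#' @return a `qsar_lattice`: `origin` (3-vector), `spacing`, `counts`
#'   (points per axis), `n_points`.
#' @export
build_lattice <- function(mols, spacing = 2.0, margin = 4.0) {
  if (!length(mols)) stop("empty molecule collection")
  if (!is.numeric(spacing) || spacing <= 0) stop("spacing must be > 0")
  xyz <- do.call(rbind, lapply(mols, coords))
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  counts <- as.integer(ceiling((hi - lo) / spacing - 1e-9)) + 1L
  structure(list(origin = lo, spacing = spacing, counts = counts,
                 n_points = prod(counts)),
            class = "qsar_lattice")
}

#' @export
print.qsar_lattice <- function(x, ...) {
  cat(sprintf("<qsar_lattice> %d x %d x %d = %d points, spacing %.2f A\n",
              x$counts[1], x$counts[2], x$counts[3], x$n_points, x$spacing))
  invisible(x)
}

#' Grid-point coordinates of a lattice
#'
#' @param lattice a `qsar_lattice`.
#' @return `n_points` x 3 matrix in raster order (x fastest).
#' @export
lattice_points <- function(lattice) {
  gx <- lattice$origin[1] + lattice$spacing * (seq_len(lattice$counts[1]) - 1)
  gy <- lattice$origin[2] + lattice$spacing * (seq_len(lattice$counts[2]) - 1)
  gz <- lattice$origin[3] + lattice$spacing * (seq_len(lattice$counts[3]) - 1)
  cbind(x = rep(gx, times = lattice$counts[2] * lattice$counts[3]),
        y = rep(rep(gy, each = lattice$counts[1]), times = lattice$counts[3]),
        z = rep(gz, each = lattice$counts[1] * lattice$counts[2]))
}

# squared distances: n_points x n_atoms
.grid_dist2 <- function(lattice, mol) {
  gp <- lattice_points(lattice)
  at <- coords(mol)
  d2 <- outer(rowSums(gp^2), rep(1, nrow(at))) +
    outer(rep(1, nrow(gp)), rowSums(at^2)) - 2 * gp %*% t(at)
  pmax(d2, 0)
}

.check_params <- function(mol) {
  if (anyNA(mol$atoms$charge) || anyNA(mol$atoms$vdw) ||
      anyNA(mol$atoms$hphob))
    stop("molecule '", mol$id, "': atom parameters not assigned ",
         "(run assign_atom_parameters first)")
}

#' CoMFA probe energies for one molecule
#'
#' Steric: Lennard-Jones 6-12 energy of the probe summed over atoms, with
#' Lorentz-Berthelot-style combination (r_min = atom radius + probe radius,
#' epsilon = sqrt of the product of well depths), truncated at `+cutoff`.
#' Electrostatic: Coulomb energy `332.17 q_i q_probe / (eps(r) r)` summed
#' over atoms, with a distance-dependent dielectric `eps(r) = r` by default,
#' truncated to `[-cutoff, +cutoff]`. At lattice points where the steric
#' energy hits the cutoff (probe inside the molecule) the electrostatic
#' value is returned as `NA`; [field_blocks()] replaces those by the column
#' mean over molecules.
#'
#' @param mol molecule with assigned parameters.
#' @param lattice a `qsar_lattice`.
#' @param probe a [default_probe()].
#' @param cutoff truncation energy, kcal/mol.
#' @param dielectric `"distance"` (eps = r) or `"constant"`.
#' @param eps_const dielectric constant when `dielectric = "constant"`.
#' @return list of two numeric vectors (`steric`, `electrostatic`) of length
#'   `lattice$n_points`.
#' @export
comfa_fields <- function(mol, lattice, probe = default_probe(), cutoff = 30,
                         dielectric = c("distance", "constant"),
                         eps_const = 1) {
  dielectric <- match.arg(dielectric)
  .check_params(mol)
  if (anyNA(mol$atoms$lj_eps))
    stop("molecule '", mol$id, "': LJ well depths not assigned")
  r2 <- .grid_dist2(lattice, mol)
  r2[r2 < 1e-12] <- 1e-12
  rmin <- mol$atoms$vdw + probe$radius
  eps <- sqrt(mol$atoms$lj_eps * probe$lj_epsilon)
  s6 <- sweep(1 / r2, 2, rmin^2, `*`)^3          # (rmin/r)^6
  ster <- rowSums(sweep(s6^2 - 2 * s6, 2, eps, `*`))
  ster <- pmin(ster, cutoff)
  r <- sqrt(r2)
  denom <- if (dielectric == "distance") r2 else eps_const * r
  elec <- rowSums(sweep(1 / denom, 2, 332.17 * mol$atoms$charge * probe$charge,
                        `*`))
  elec <- pmin(pmax(elec, -cutoff), cutoff)
  elec[ster >= cutoff] <- NA_real_
  list(steric = ster, electrostatic = elec)
}

#' CoMSIA similarity indices for one molecule
#'
#' For each field the value at grid point q is
#' `-sum_i w_probe * w_i * exp(-alpha * r_iq^2)` with atomic weights:
#' steric = vdW radius cubed, electrostatic = partial charge, hydrophobic =
#' atomic hydrophobicity, donor/acceptor = 0/1 flags. Gaussian attenuation
#' means no cutoff is needed and the fields are smooth everywhere.
#'
#' @param mol molecule with assigned parameters.
#' @param lattice a `qsar_lattice`.
#' @param probe a [default_probe()].
#' @param alpha attenuation factor, 1/Angstrom^2 (conventional default 0.3).
#' @return named list of five numeric vectors: `S`, `E`, `H`, `D`, `A`.
#' @export
comsia_fields <- function(mol, lattice, probe = default_probe(),
                          alpha = 0.3) {
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0")
  .check_params(mol)
  g <- exp(-alpha * .grid_dist2(lattice, mol))
  w <- list(S = mol$atoms$vdw^3 * probe$radius^3,
            E = mol$atoms$charge * probe$charge,
            H = mol$atoms$hphob * probe$hydrophobicity,
            D = as.numeric(mol$atoms$is_hbd) * probe$hbd_strength,
            A = as.numeric(mol$atoms$is_hba) * probe$hba_strength)
  lapply(w, function(wk) -as.numeric(g %*% wk))
}

#' Compute field blocks over a molecule set
#'
#' Evaluates the requested CoMFA/CoMSIA fields for every molecule on a
#' shared lattice and stacks them into molecules x grid-points matrices
#' (one `qsar_field_block` per field). Sterically excluded CoMFA
#' electrostatic entries (NA) are mean-imputed per column; columns that are
#' NA for every molecule become 0 (and are constant, hence later filtered).
#'
#' @param mols list of aligned, parameterised molecules.
#' @param lattice a `qsar_lattice`; built with defaults if `NULL`.
#' @param fields character vector from `comfa_steric`, `comfa_electrostatic`,
#'   `comsia_S`, `comsia_E`, `comsia_H`, `comsia_D`, `comsia_A`.
#' @param probe,cutoff,alpha,dielectric,eps_const see [comfa_fields()] /
#'   [comsia_fields()].
#' @return named list of `qsar_field_block` objects, each with `kind`,
#'   `matrix` (rownames = molecule ids), `lattice`, `dropped` (filled by
#'   [filter_columns()]).
#' @export
field_blocks <- function(mols, lattice = NULL,
                         fields = c("comfa_steric", "comfa_electrostatic",
                                    "comsia_S", "comsia_E", "comsia_H",
                                    "comsia_D", "comsia_A"),
                         probe = default_probe(), cutoff = 30, alpha = 0.3,
                         dielectric = "distance", eps_const = 1) {
  if (!length(mols)) stop("empty molecule collection")
  if (is.null(lattice)) lattice <- build_lattice(mols)
  ids <- vapply(mols, function(m) m$id, "")
  want_comfa <- any(grepl("^comfa", fields))
  want_comsia_kinds <- sub("^comsia_", "", grep("^comsia", fields, value = TRUE))
  rows <- lapply(mols, function(m) {
    out <- list()
    if (want_comfa)
      out$comfa <- comfa_fields(m, lattice, probe, cutoff,
                                dielectric = dielectric,
                                eps_const = eps_const)
    if (length(want_comsia_kinds))
      out$comsia <- comsia_fields(m, lattice, probe, alpha)
    out
  })
  blocks <- list()
  for (f in fields) {
    mat <- do.call(rbind, lapply(rows, function(r) {
      switch(f,
             comfa_steric = r$comfa$steric,
             comfa_electrostatic = r$comfa$electrostatic,
             r$comsia[[sub("^comsia_", "", f)]])
    }))
    rownames(mat) <- ids
    if (anyNA(mat)) {
      for (j in which(colSums(is.na(mat)) > 0)) {
        v <- mat[, j]
        v[is.na(v)] <- if (all(is.na(v))) 0 else mean(v, na.rm = TRUE)
        mat[, j] <- v
      }
    }
    blocks[[f]] <- structure(list(kind = f, matrix = mat, lattice = lattice,
                                  dropped = integer()),
                             class = "qsar_field_block")
  }
  blocks
}

#' @export
print.qsar_field_block <- function(x, ...) {
  cat(sprintf("<qsar_field_block> %s: %d molecules x %d points (%d dropped)\n",
              x$kind, nrow(x$matrix), ncol(x$matrix), length(x$dropped)))
  invisible(x)
}

#' Column filtering by energy variation
#'
#' Drops lattice columns whose variation (max - min across molecules) falls
#' below a threshold: 2.0 kcal/mol is the conventional CoMFA setting. CoMSIA
#' similarity indices live on a different scale, so they use their own
#' threshold (default 0, meaning only constant columns are removed;
#' zero-variation columns are always removed).
#'
#' @param blocks list of `qsar_field_block` (at least 2 molecules each).
#' @param threshold CoMFA variation threshold, kcal/mol.
#' @param comsia_threshold CoMSIA variation threshold (same rule, field
#'   units).
#' @return the blocks with `dropped` populated.
#' @export
filter_columns <- function(blocks, threshold = 2.0, comsia_threshold = 0) {
  single <- inherits(blocks, "qsar_field_block")
  if (single) blocks <- list(blocks)
  blocks <- lapply(blocks, function(b) {
    if (nrow(b$matrix) < 2L)
      stop("column filtering needs at least 2 molecules")
    thr <- if (grepl("^comsia", b$kind)) comsia_threshold else threshold
    rng <- apply(b$matrix, 2, function(v) max(v) - min(v))
    b$dropped <- which(rng < thr | rng == 0)
    b
  })
  if (single) blocks[[1]] else blocks
}

active_columns <- function(block) {
  setdiff(seq_len(ncol(block$matrix)), block$dropped)
}

#' Assemble the PLS descriptor matrix from field blocks
#'
#' Concatenates the retained (unfiltered) columns of each block. With
#' `block_scale = TRUE` (the CoMFA-standard convention) each block is
#' divided by the standard deviation of all its centred entries, so blocks
#' of different physical scale contribute comparably to the PLS solution.
#'
#' @param blocks list of `qsar_field_block` (run [filter_columns()] first).
#' @param block_scale logical.
#' @return list with `X` (matrix), `col_block` (field kind per column),
#'   `col_point` (lattice column index per column), `block_sd` (named
#'   scaling factors), `lattice`.
#' @export
assemble_descriptors <- function(blocks, block_scale = TRUE) {
  stopifnot(length(blocks) >= 1L)
  Xs <- list(); col_block <- character(); col_point <- integer()
  block_sd <- setNames(numeric(length(blocks)),
                       vapply(blocks, function(b) b$kind, ""))
  for (b in blocks) {
    keep <- active_columns(b)
    m <- b$matrix[, keep, drop = FALSE]
    cm <- sweep(m, 2, colMeans(m))
    s <- sd(as.numeric(cm))
    if (!is.finite(s) || s == 0) s <- 1
    block_sd[b$kind] <- s
    if (block_scale) m <- m / s
    Xs[[b$kind]] <- m
    col_block <- c(col_block, rep(b$kind, length(keep)))
    col_point <- c(col_point, keep)
  }
  list(X = do.call(cbind, Xs), col_block = col_block, col_point = col_point,
       block_sd = block_sd, block_scale = block_scale,
       lattice = blocks[[1]]$lattice)
}
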