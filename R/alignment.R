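#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation (det = +1; reflections are forbidden because the
#' molecules of interest are chiral) and translation minimising the RMSD
#' between two matched coordinate sets.
#'
#' @param ref n x 3 reference coordinates.
#' @param mob n x 3 mobile coordinates (same row correspondence).
#' @return list with `R` (3 x 3 rotation), `t` (translation so that
#'   `mob %*% R + t` superposes onto `ref`), and `rmsd` over the matched
#'   points.
#' @export
kabsch <- function(ref, mob) {
  stopifnot(is.matrix(ref), is.matrix(mob), ncol(ref) == 3L,
            all(dim(ref) == dim(mob)))
  if (nrow(ref) < 3L) stop("need at least 3 matched atoms for superposition")
  cr <- colMeans(ref); cm <- colMeans(mob)
  A <- sweep(mob, 2, cm); B <- sweep(ref, 2, cr)
  sv <- svd(t(A) %*% B)
  if (sv$d[2] < 1e-10)
    stop("matched core atoms are collinear; superposition is underdetermined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fit <- A %*% R
  rmsd <- sqrt(mean(rowSums((fit - B)^2)))
  list(R = R, t = cr - cm %*% R, rmsd = rmsd)
}

#' Superpose a molecule onto a template over a common core
#'
#' Rigid (rotation + translation only) least-squares superposition of the
#' mapped core atoms of `mol` onto the corresponding atoms of `template`;
#' the transform is applied to every atom of `mol`.
#'
#' @param mol molecule to move.
#' @param template template molecule (stays fixed).
#' @param map two-column integer matrix: column 1 = template atom index,
#'   column 2 = `mol` atom index (1-based); at least 3 non-collinear pairs.
#' @return list with `molecule` (transformed) and `rmsd` (Angstrom, over the
#'   mapped core atoms).
#' @export
superpose_core <- function(mol, template, map) {
  map <- as.matrix(map)
  if (ncol(map) != 2L) stop("map must have two columns (template, molecule)")
  if (nrow(map) < 3L) stop("need at least 3 mapped core atoms")
  if (anyDuplicated(map[, 1]) || anyDuplicated(map[, 2]))
    stop("core mapping must be injective")
  if (any(map[, 1] < 1L) || any(map[, 1] > n_atoms(template)) ||
      any(map[, 2] < 1L) || any(map[, 2] > n_atoms(mol)))
    stop("core mapping references an absent atom index")
  fit <- kabsch(coords(template)[map[, 1], , drop = FALSE],
                coords(mol)[map[, 2], , drop = FALSE])
  xyz <- coords(mol) %*% fit$R
  xyz <- sweep(xyz, 2, as.numeric(fit$t), `+`)
  coords(mol) <- xyz
  list(molecule = mol, rmsd = fit$rmsd)
}

#' Align a set of molecules onto one template
#'
#' @param mols list of molecules.
#' @param template_id id of the template molecule (stays fixed).
#' @param mapping core mapping: either `NULL` (atoms `1..k` of every molecule
#'   are assumed to correspond, as produced by the synthetic generator), or a
#'   data frame with columns `template_atom_index`, `molecule_id`,
#'   `molecule_atom_index` (0-based indices, the on-disk CSV convention of
#'   [read_core_mapping()]).
#' @param core_size number of leading atoms used when `mapping` is `NULL`.
#' @return list with `molecules` (aligned, template unchanged) and `rmsd`
#'   (named vector, Angstrom).
#' @export
align_set <- function(mols, template_id, mapping = NULL,
                      core_size = NULL) {
  ids <- vapply(mols, function(m) m$id, "")
  ti <- match(template_id, ids)
  if (is.na(ti)) stop("template id not found: ", template_id)
  template <- mols[[ti]]
  rmsd <- setNames(numeric(length(mols)), ids)
  for (k in seq_along(mols)) {
    if (k == ti) next
    if (is.null(mapping)) {
      ncore <- if (is.null(core_size))
        min(n_atoms(template), n_atoms(mols[[k]])) else core_size
      map <- cbind(seq_len(ncore), seq_len(ncore))
    } else {
      rows <- mapping$molecule_id == ids[k]
      if (!any(rows)) stop("no core mapping for molecule ", ids[k])
      map <- cbind(mapping$template_atom_index[rows] + 1L,
                   mapping$molecule_atom_index[rows] + 1L)
    }
    fit <- superpose_core(mols[[k]], template, map)
    mols[[k]] <- fit$molecule
    rmsd[k] <- fit$rmsd
  }
  list(molecules = mols, rmsd = rmsd)
}

#' Read a core-mapping CSV
#'
#' Plain CSV with columns `template_atom_index`, `molecule_id`,
#' `molecule_atom_index`; atom indices are 0-based on disk and converted to
#' 1-based internally by [align_set()].
#'
#' @param path CSV file.
#' @return data frame.
#' @export
read_core_mapping <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("template_atom_index", "molecule_id", "molecule_atom_index")
  if (!all(need %in% names(m)))
    stop("core mapping CSV needs columns: ", paste(need, collapse = ", "))
  m
}
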