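#' Construct a molecule object
#'
#' A `qsar_mol` is the package's working representation of one 3D structure:
#' an atom table (element, Cartesian coordinates in Angstrom, and - once
#' assigned - partial charge, van der Waals radius, hydrophobicity weight and
#' H-bond donor/acceptor flags), a bond table, and an optional biological
#' activity (elongation E, mm).
#'
#' @param id compound label, e.g. `"6a"`.
#' @param atoms data frame with at least columns `element`, `x`, `y`, `z`.
#'   Optional columns `charge`, `vdw`, `hphob`, `is_hbd`, `is_hba` are kept;
#'   missing ones are initialised to `NA`/`FALSE`.
#' @param bonds data frame with columns `i`, `j`, `order` (1-based atom
#'   indices; order 1, 2, 3 or 4 = aromatic). May be empty.
#' @param activity_E elongation in mm, or `NA`.
#' @param formal_charge net formal charge of the molecule (elementary
#'   charges); the starting point for charge assignment.
#' @return an object of class `qsar_mol`.
#' @export
molecule <- function(id, atoms, bonds = empty_bonds(), activity_E = NA_real_,
                     formal_charge = 0L) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L,
            all(c("element", "x", "y", "z") %in% names(atoms)))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("molecule '", id, "': non-finite coordinates")
  for (col in c("charge", "vdw", "hphob"))
    if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  for (col in c("is_hbd", "is_hba"))
    if (is.null(atoms[[col]])) atoms[[col]] <- FALSE
  rownames(atoms) <- NULL
  structure(list(id = as.character(id), atoms = atoms, bonds = bonds,
                 activity_E = as.numeric(activity_E),
                 formal_charge = as.integer(formal_charge)),
            class = "qsar_mol")
}

empty_bonds <- function() {
  data.frame(i = integer(), j = integer(), order = integer())
}

#' @export
print.qsar_mol <- function(x, ...) {
  cat("<qsar_mol> ", x$id, ": ", nrow(x$atoms), " atoms, ",
      nrow(x$bonds), " bonds",
      if (!is.na(x$activity_E)) sprintf(", E = %.2f mm", x$activity_E),
      "\n", sep = "")
  invisible(x)
}

#' Atom count and coordinate matrix of a molecule
#'
#' @param mol a [molecule()].
#' @return `n_atoms()`: integer; `coords()`: n x 3 matrix, Angstrom.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' @rdname n_atoms
#' @export
coords <- function(mol) as.matrix(mol$atoms[, c("x", "y", "z")])

`coords<-` <- function(mol, value) {
  mol$atoms[, c("x", "y", "z")] <- value
  mol
}

#' Read 3D structures from an SDF or MOL2 file
#'
#' SDF (V2000) records are parsed with ChemmineR; MOL2 files with bio3d
#' (multi-record MOL2 files are split on `@<TRIPOS>MOLECULE` first).
#' Record order is preserved and ids are taken from the record titles.
#' Activities can come from an SDF property tag (default `E_mm`) or from a
#' companion CSV with columns `id,E_mm`; the CSV wins where both exist.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"sdf"` or `"mol2"`.
#' @param activity_tag name of the SDF data field holding elongation (mm).
#' @param activity_csv optional CSV path with columns `id,E_mm`.
#' @param strict_3d error on records whose z coordinates are all zero
#'   (i.e. flat 2D depictions); set `FALSE` to accept them.
#' @return list of [molecule()] objects, in file order.
#' @export
read_structures <- function(path, format = c("auto", "sdf", "mol2"),
                            activity_tag = "E_mm", activity_csv = NULL,
                            strict_3d = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     sdf = "sdf", sd = "sdf", mol2 = "mol2",
                     stop("cannot infer format from extension: ", path))
  }
  mols <- if (format == "sdf") read_sdf_records(path, activity_tag)
          else read_mol2_records(path)
  if (strict_3d) {
    for (k in seq_along(mols)) {
      z <- mols[[k]]$atoms$z
      if (all(abs(z) < 1e-8))
        stop("record ", k, " ('", mols[[k]]$id, "'): no 3D coordinates")
    }
  }
  if (!is.null(activity_csv)) {
    act <- read.csv(activity_csv, stringsAsFactors = FALSE)
    if (!all(c("id", "E_mm") %in% names(act)))
      stop("activity CSV needs columns id,E_mm")
    for (k in seq_along(mols)) {
      hit <- match(mols[[k]]$id, act$id)
      if (!is.na(hit)) mols[[k]]$activity_E <- as.numeric(act$E_mm[hit])
    }
  }
  mols
}

read_sdf_records <- function(path, activity_tag) {
  sdfset <- withCallingHandlers(
    tryCatch(ChemmineR::read.SDFset(path),
             error = function(e) stop("unparsable SDF: ",
                                      conditionMessage(e))),
    # ChemmineR flags bond-less records as "invalid"; they are legal V2000
    warning = function(w) {
      if (grepl("invalid SDFs", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  ids <- ChemmineR::sdfid(sdfset)
  lapply(seq_along(sdfset), function(k) {
    sdf <- sdfset[[k]]
    ab <- ChemmineR::atomblock(sdf)
    if (is.null(ab) || nrow(ab) == 0L)
      stop("unparsable SDF record ", k, ": empty atom block")
    elem <- sub("_\\d+$", "", rownames(ab))
    atoms <- data.frame(element = elem, x = ab[, 1], y = ab[, 2], z = ab[, 3])
    bb <- ChemmineR::bondblock(sdf)
    bonds <- if (is.null(bb) || NROW(bb) == 0L || NCOL(bb) < 3L) empty_bonds() else
      data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                 order = as.integer(bb[, 3]))
    db <- ChemmineR::datablock(sdf)
    act <- if (length(db) && activity_tag %in% names(db))
      suppressWarnings(as.numeric(db[[activity_tag]])) else NA_real_
    molecule(id = ids[k], atoms = atoms, bonds = bonds, activity_E = act)
  })
}

read_mol2_records <- function(path) {
  txt <- readLines(path, warn = FALSE)
  starts <- grep("^@<TRIPOS>MOLECULE", txt)
  if (!length(starts)) stop("unparsable MOL2: no @<TRIPOS>MOLECULE record")
  ends <- c(starts[-1] - 1L, length(txt))
  lapply(seq_along(starts), function(k) {
    tf <- tempfile(fileext = ".mol2")
    on.exit(unlink(tf))
    writeLines(txt[starts[k]:ends[k]], tf)
    m2 <- tryCatch(bio3d::read.mol2(tf),
                   error = function(e) stop("unparsable MOL2 record ", k, ": ",
                                            conditionMessage(e)))
    at <- m2$atom
    elem <- sub("\\..*$", "", at$elety)
    atoms <- data.frame(element = elem, x = at$x, y = at$y, z = at$z)
    bonds <- if (is.null(m2$bond) || !nrow(m2$bond)) empty_bonds() else
      data.frame(i = as.integer(m2$bond$origin),
                 j = as.integer(m2$bond$target),
                 order = suppressWarnings(
                   ifelse(m2$bond$type %in% c("ar", "am"), 4L,
                          as.integer(m2$bond$type))))
    molecule(id = m2$name, atoms = atoms, bonds = bonds)
  })
}

#' Write molecules to an SDF (V2000) file
#'
#' Coordinates are written with 4 decimal places; the activity (if present)
#' is emitted as an `E_mm` property block so that written files round-trip
#' through [read_structures()].
#'
#' @param mols list of [molecule()] objects.
#' @param path output file.
#' @param activity_tag property tag for the activity field.
#' @return `path`, invisibly.
#' @export
write_structures <- function(mols, path, activity_tag = "E_mm") {
  if (inherits(mols, "qsar_mol")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in mols) {
    na <- n_atoms(mol); nb <- nrow(mol$bonds)
    writeLines(c(mol$id, "  qsar3d", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb), con)
    xyz <- coords(mol)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       xyz[, 1], xyz[, 2], xyz[, 3], mol$atoms$element), con)
    if (nb)
      writeLines(sprintf("%3d%3d%3d  0", mol$bonds$i, mol$bonds$j,
                         mol$bonds$order), con)
    writeLines("M  END", con)
    if (!is.na(mol$activity_E))
      writeLines(c(paste0("> <", activity_tag, ">"),
                   format(mol$activity_E), ""), con)
    writeLines("$$$$", con)
  }
  invisible(path)
}

#' Default per-element atom parameter table
#'
#' The packaged plain-text table of van der Waals radii (Bondi), LJ well
#' depths and coarse atomic hydrophobicity contributions; see
#' `inst/extdata/atom_params.csv` for provenance notes.
#'
#' @return data frame with columns `element`, `vdw_radius`, `lj_epsilon`,
#'   `hydrophobicity`.
#' @export
default_atom_params <- function() {
  read.csv(.qsar3d_extdata("atom_params.csv"), comment.char = "#",
           stringsAsFactors = FALSE)
}

gasteiger_param_table <- function() {
  read.csv(.qsar3d_extdata("gasteiger_params.csv"), comment.char = "#",
           stringsAsFactors = FALSE)
}

# Hybridisation state per atom from bond orders: 1 = sp, 2 = sp2, 3 = sp3.
# Aromatic bonds (order 4) count as sp2; two double bonds (cumulated) as sp.
atom_hybridisation <- function(mol) {
  hyb <- rep(3L, n_atoms(mol))
  if (!nrow(mol$bonds)) return(hyb)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    i <- b$i[k]; j <- b$j[k]; o <- b$order[k]
    if (o == 2L) { hyb[i] <- hyb[i] - 1L; hyb[j] <- hyb[j] - 1L }
    if (o == 3L) { hyb[i] <- 1L; hyb[j] <- 1L }
    if (o == 4L) { hyb[i] <- min(hyb[i], 2L); hyb[j] <- min(hyb[j], 2L) }
  }
  pmax(hyb, 1L)
}

adjacency_list <- function(mol) {
  adj <- vector("list", n_atoms(mol))
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

#' Gasteiger (PEOE) sigma partial charges
#'
#' Iterative partial equalization of orbital electronegativities: at step k
#' every bond transfers charge proportional to the electronegativity
#' difference of its atoms, damped by (1/2)^k, with the cation
#' electronegativity of the donor atom as the normalising denominator.
#' Six iterations (the conventional fixed count) are performed.
#'
#' @param mol a [molecule()] with a bond table.
#' @param n_iter number of damping iterations.
#' @return numeric vector of partial charges (elementary-charge units).
#' @export
gasteiger_charges <- function(mol, n_iter = 6L) {
  par <- gasteiger_param_table()
  hyb <- atom_hybridisation(mol)
  elem <- mol$atoms$element
  idx <- integer(n_atoms(mol))
  for (a in seq_along(idx)) {
    hit <- which(par$element == elem[a] & par$hyb == hyb[a])
    if (!length(hit)) hit <- which(par$element == elem[a] & par$hyb == 0L)
    if (!length(hit))
      stop("no electronegativity parameters for element: ", elem[a])
    idx[a] <- hit[1]
  }
  a_ <- par$a[idx]; b_ <- par$b[idx]; c_ <- par$c[idx]
  chi_plus <- ifelse(elem == "H", 20.02, a_ + b_ + c_)
  q <- rep(mol$formal_charge / n_atoms(mol), n_atoms(mol))
  if (!nrow(mol$bonds)) return(q)
  bi <- mol$bonds$i; bj <- mol$bonds$j
  damp <- 1
  for (it in seq_len(n_iter)) {
    damp <- damp * 0.5
    chi <- a_ + b_ * q + c_ * q^2
    dchi <- chi[bj] - chi[bi]
    denom <- ifelse(dchi > 0, chi_plus[bi], chi_plus[bj])
    dq <- dchi / denom * damp
    # positive dq: atom j more electronegative, charge flows i -> j
    dq_atom <- rep(0, length(q))
    for (k in seq_along(bi)) {
      dq_atom[bi[k]] <- dq_atom[bi[k]] + dq[k]
      dq_atom[bj[k]] <- dq_atom[bj[k]] - dq[k]
    }
    q <- q + dq_atom
  }
  q
}

#' Assign physicochemical atom parameters
#'
#' Populates partial charges (Gasteiger PEOE by default), van der Waals
#' radii, LJ well depths, hydrophobicity weights and H-bond donor/acceptor
#' flags on every atom. Donors are hydrogens bonded to O or N; acceptors are
#' all oxygens and any nitrogen with a free lone pair (total bond order < 4).
#' Idempotent: re-running overwrites with identical values.
#'
#' @param mol a [molecule()].
#' @param params parameter table, see [default_atom_params()].
#' @param charge_method `"gasteiger"` or `"none"` (keep charges already on
#'   the atoms; error if any are missing).
#' @return the molecule with all atom fields populated.
#' @export
assign_atom_parameters <- function(mol, params = default_atom_params(),
                                   charge_method = c("gasteiger", "none")) {
  charge_method <- match.arg(charge_method)
  elem <- mol$atoms$element
  hit <- match(elem, params$element)
  if (anyNA(hit))
    stop("element(s) missing from parameter table: ",
         paste(unique(elem[is.na(hit)]), collapse = ", "))
  mol$atoms$vdw <- params$vdw_radius[hit]
  mol$atoms$lj_eps <- params$lj_epsilon[hit]
  mol$atoms$hphob <- params$hydrophobicity[hit]
  if (charge_method == "gasteiger") {
    mol$atoms$charge <- gasteiger_charges(mol)
  } else if (anyNA(mol$atoms$charge)) {
    stop("charge_method = 'none' but atom charges are missing")
  }
  adj <- adjacency_list(mol)
  is_hbd <- is_hba <- logical(length(elem))
  for (a in seq_along(elem)) {
    nbr_elem <- elem[adj[[a]]]
    if (elem[a] == "H" && any(nbr_elem %in% c("O", "N"))) is_hbd[a] <- TRUE
    if (elem[a] == "O") is_hba[a] <- TRUE
    if (elem[a] == "N") {
      border <- sum(pmin(mol$bonds$order[mol$bonds$i == a | mol$bonds$j == a], 3L))
      if (border < 4L) is_hba[a] <- TRUE
    }
  }
  mol$atoms$is_hbd <- is_hbd
  mol$atoms$is_hba <- is_hba
  attr(mol, "params_assigned") <- TRUE
  mol
}
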