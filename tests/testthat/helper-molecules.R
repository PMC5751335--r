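# fixtures built in code: a real bonded ethanol (SDF / MOL2 text) and
# hand-parameterised point-atom molecules for field/PLS tests

ethanol_sdf_lines <- function(id = "ethanol", E = 12.5) {
  c(id, "  test", "",
    " 9  8  0  0  0  0  0  0  0  0999 V2000",
    "   -0.8926    0.1781   -0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.4519   -0.5191    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5282    0.4184    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -1.7088   -0.5489    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.9815    0.8081   -0.8926 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.9815    0.8081    0.8926 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.5508   -1.1545   -0.8861 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.5508   -1.1545    0.8861 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.3567   -0.0717    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    " 1  2  1  0", " 1  4  1  0", " 1  5  1  0", " 1  6  1  0",
    " 2  3  1  0", " 2  7  1  0", " 2  8  1  0", " 3  9  1  0",
    "M  END",
    "> <E_mm>", format(E), "", "$$$$")
}

write_ethanol_sdf <- function(path, ids = "ethanol") {
  writeLines(unlist(lapply(ids, ethanol_sdf_lines)), path)
  path
}

# partial charges for the ethanol fixture computed independently with
# openbabel (obabel --partialcharge gasteiger), frozen as oracle values
ethanol_gasteiger_oracle <- c(-0.0418, 0.0414, -0.3953, 0.0252, 0.0252,
                              0.0252, 0.0554, 0.0554, 0.2094)

two_record_mol2_lines <- function() {
  rec <- function(name, z1) c(
    "@<TRIPOS>MOLECULE", name, " 3 2 1 0 0", "SMALL", "USER_CHARGES",
    "@<TRIPOS>ATOM",
    sprintf("      1 C1         -0.8926    0.1781    %.4f C.3     1  LIG1        0.0000", z1),
    "      2 C2          0.4519   -0.5191    0.1000 C.3     1  LIG1        0.0000",
    "      3 O1          1.5282    0.4184    0.2000 O.3     1  LIG1        0.0000",
    "@<TRIPOS>BOND",
    "     1    1    2   1",
    "     2    2    3   1")
  c(rec("eth1", 0.5), rec("eth2", 0.9))
}

# point-atom molecule with all parameters hand-assigned (bypasses the
# charge-perception path, as the synthetic module does)
point_mol <- function(id, xyz, charge = 0, vdw = 1.70, hphob = 0.34,
                      is_hbd = FALSE, is_hba = FALSE, lj_eps = 0.107,
                      E = 10) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  rep_n <- function(v) rep_len(v, n)
  m <- molecule(id, data.frame(element = "C", x = xyz[, 1], y = xyz[, 2],
                               z = xyz[, 3], charge = rep_n(charge),
                               vdw = rep_n(vdw), hphob = rep_n(hphob),
                               is_hbd = rep_n(is_hbd), is_hba = rep_n(is_hba)),
                activity_E = E)
  m$atoms$lj_eps <- rep_n(lj_eps)
  attr(m, "params_assigned") <- TRUE
  m
}

# lattice wrapper for tests that need full control of the box
make_lattice <- function(origin, spacing, counts) {
  structure(list(origin = origin, spacing = spacing,
                 counts = as.integer(counts),
                 n_points = prod(counts)),
            class = "qsar_lattice")
}

random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# small aligned toy set with varying charges for PLS-level tests
charged_toy_set <- function(n = 10, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    q <- runif(1, -0.5, 0.5)
    point_mol(sprintf("m%02d", i),
              rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0)),
              charge = c(0.05, q, 0.05), E = 10^(1 + q))
  })
}
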