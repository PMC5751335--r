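#' Specification for a synthetic aligned molecule set
#'
#' The generator emulates what a 3D-QSAR study needs from its input: a set
#' of rigidly alignable analogues sharing a scaffold, varying only at a few
#' decoration sites, with activity a known linear function of site
#' properties plus Gaussian noise. Toy atoms carry hand-assigned
#' physicochemical parameters, so field generation and PLS are exercised
#' independently of the charge-assignment path.
#'
#' @param n_molecules number of molecules.
#' @param effects list of effect terms, each `list(site =, property =,
#'   weight =)` with property one of `"charge"`, `"bulk"`, `"hphob"`,
#'   `"hbd"`, `"hba"`. Default: one causal electrostatic site with weight
#'   -1 pE per elementary charge, i.e. electron-rich (negatively charged,
#'   hydroxyl/carbonyl-like) substituents raise activity - the direction
#'   observed for polyhydroxylated steroid growth promoters.
#' @param noise_sd Gaussian noise on the activity, pE units.
#' @param base baseline activity, pE units.
#' @param seed integer RNG seed; the output is reproducible byte-for-byte.
#' @return a `qsar_synth_spec` list.
#' @export
synthetic_spec <- function(n_molecules = 30,
                           effects = list(list(site = 1, property = "charge",
                                               weight = -1.0)),
                           noise_sd = 0.05, base = 1.3, seed = 1L) {
  stopifnot(n_molecules >= 4, noise_sd >= 0)
  structure(list(n_molecules = n_molecules, effects = effects,
                 noise_sd = noise_sd, base = base, seed = as.integer(seed)),
            class = "qsar_synth_spec")
}

# rigid scaffold: 12 carbon point atoms in two fused-ring-like strips,
# plus 3 decoration sites sitting well apart (> 5 A) on the periphery.
.toy_scaffold <- function() {
  xy <- expand.grid(x = c(0, 1.5, 3.0, 4.5), y = c(0, 1.5, 3.0))
  data.frame(element = "C", x = xy$x, y = xy$y,
             z = rep(c(0.25, -0.25), length.out = nrow(xy)),
             charge = 0.05, vdw = 1.70, hphob = 0.34,
             is_hbd = FALSE, is_hba = FALSE, lj_eps = 0.107)
}

.toy_sites <- function() {
  rbind(c(-1.8, 1.5, 0.8), c(6.3, 1.5, 0.8), c(2.25, 4.8, -0.8))
}

# substituent fragment library: single point atoms spanning charge, bulk,
# hydrophobicity and H-bond character
.toy_fragments <- function() {
  data.frame(
    name = c("hydro", "methyl", "hydroxyl", "carbonylO", "ammonium", "halogen"),
    element = c("H", "C", "O", "O", "N", "Cl"),
    charge = c(0.05, 0.00, -0.40, -0.50, 0.30, -0.15),
    vdw = c(1.20, 1.70, 1.52, 1.52, 1.55, 1.75),
    hphob = c(0.10, 0.34, -0.45, -0.45, -0.60, 0.50),
    is_hbd = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE),
    is_hba = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    lj_eps = c(0.042, 0.107, 0.116, 0.116, 0.095, 0.314))
}

.site_property <- function(frag_row, property) {
  switch(property,
         charge = frag_row$charge,
         bulk = frag_row$vdw^3,
         hphob = frag_row$hphob,
         hbd = as.numeric(frag_row$is_hbd),
         hba = as.numeric(frag_row$is_hba),
         stop("unknown site property: ", property))
}

.property_field <- c(charge = "E", bulk = "S", hphob = "H",
                     hbd = "D", hba = "A")

#' Generate a synthetic aligned molecule set with planted activity
#'
#' Molecules share the rigid scaffold exactly (alignment is exact by
#' construction) and differ by the substituent fragment drawn at each of
#' three decoration sites. Activity is `pE = base + sum_effects(weight *
#' property(site)) + N(0, noise_sd)`. The ground truth (weights, causal
#' site coordinates, causal field letters, noise-free activities) is
#' returned for recovery tests.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `molecules` (activity stored as `E = 10^pE` mm, so the
#'   standard transform recovers a shifted copy of the planted pE),
#'   `activities` (data frame id/pE), and `truth`.
#' @export
generate_toy_set <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "qsar_synth_spec"))
  if (!length(spec$effects)) stop("no decoration-site effects specified")
  sites <- .toy_sites()
  frags <- .toy_fragments()
  for (ef in spec$effects)
    if (ef$site < 1 || ef$site > nrow(sites))
      stop("effect references a non-existent decoration site")
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(spec$seed)
  scaffold <- .toy_scaffold()
  n_sites <- nrow(sites)
  choice <- matrix(sample.int(nrow(frags), spec$n_molecules * n_sites,
                              replace = TRUE),
                   nrow = spec$n_molecules)
  pE0 <- rep(spec$base, spec$n_molecules)
  for (ef in spec$effects) {
    prop <- vapply(seq_len(spec$n_molecules), function(i)
      .site_property(frags[choice[i, ef$site], ], ef$property), 0)
    pE0 <- pE0 + ef$weight * prop
  }
  pE <- pE0 + rnorm(spec$n_molecules, sd = spec$noise_sd)
  ids <- sprintf("syn%02d", seq_len(spec$n_molecules))
  mols <- lapply(seq_len(spec$n_molecules), function(i) {
    sub <- frags[choice[i, ], ]
    atoms <- rbind(scaffold,
                   data.frame(element = sub$element, x = sites[, 1],
                              y = sites[, 2], z = sites[, 3],
                              charge = sub$charge, vdw = sub$vdw,
                              hphob = sub$hphob, is_hbd = sub$is_hbd,
                              is_hba = sub$is_hba, lj_eps = sub$lj_eps))
    m <- molecule(ids[i], atoms, activity_E = 10^pE[i])
    attr(m, "params_assigned") <- TRUE
    m
  })
  truth <- list(effects = spec$effects,
                causal_sites = sites[vapply(spec$effects, `[[`, 0, "site"),
                                     , drop = FALSE],
                causal_fields = unname(.property_field[
                  vapply(spec$effects, `[[`, "", "property")]),
                base = spec$base, noise_sd = spec$noise_sd,
                fragment_choice = choice, pE_noiseless = pE0, pE = pE)
  list(molecules = mols,
       activities = data.frame(id = ids, pE = pE),
       truth = truth)
}

#' Small bonded demo set (integration-test mode)
#'
#' Eight ring polyol variants built from a hand-coded cyclohexane-chair
#' template with H or OH at three ring positions, with real bonds - these
#' exercise the full charge-assignment path, unlike the point-atom toys.
#'
#' @return list of molecules (no activities).
#' @export
demo_polyol_set <- function() {
  # chair-like hexagon, 1.54 A bonds
  ring <- data.frame(
    element = "C",
    x = 1.45 * cos(seq(0, 5) * pi / 3),
    y = 1.45 * sin(seq(0, 5) * pi / 3),
    z = rep(c(0.25, -0.25), 3))
  sub_pos <- c(1L, 3L, 5L)
  combos <- expand.grid(s1 = c(FALSE, TRUE), s2 = c(FALSE, TRUE),
                        s3 = c(FALSE, TRUE))
  lapply(seq_len(nrow(combos)), function(k) {
    has_oh <- unlist(combos[k, ])
    atoms <- ring
    bonds <- data.frame(i = 1:6, j = c(2:6, 1), order = 1L)
    for (s in seq_along(sub_pos)) {
      ci <- sub_pos[s]
      dir <- c(ring$x[ci], ring$y[ci], 0)
      dir <- dir / sqrt(sum(dir^2))
      if (has_oh[s]) {
        o <- c(ring$x[ci], ring$y[ci], ring$z[ci]) + 1.43 * dir
        h <- o + c(0, 0, 0.97)
        atoms <- rbind(atoms, data.frame(element = c("O", "H"),
                                         x = c(o[1], h[1]), y = c(o[2], h[2]),
                                         z = c(o[3], h[3])))
        oi <- nrow(atoms) - 1L
        bonds <- rbind(bonds, data.frame(i = c(ci, oi), j = c(oi, oi + 1L),
                                         order = 1L))
      } else {
        h <- c(ring$x[ci], ring$y[ci], ring$z[ci]) + 1.09 * dir
        atoms <- rbind(atoms, data.frame(element = "H",
                                         x = h[1], y = h[2], z = h[3]))
        bonds <- rbind(bonds, data.frame(i = ci, j = nrow(atoms), order = 1L))
      }
    }
    molecule(sprintf("polyol%d", k), atoms, bonds)
  })
}

#' Load a packaged fixture table
#'
#' The package ships, as plain CSV, the printed per-compound activity and
#' prediction tables of the two brassinosteroid datasets (27 compounds
#' assayed at 1e-9 M, "A"; 38 at 1e-10 M, "B"), their elongation tables,
#' and the printed external-validation summaries. For the prediction tables
#' a transcription consistency check is run: actual - predicted must match
#' the printed residual within +-0.005 (residuals are printed to 2
#' decimals) for every row.
#'
#' @param table_id one of `"tableA"`, `"tableB"` (per-compound actual /
#'   predicted pE with test-set flags), `"activityA"`, `"activityB"`
#'   (elongation E in mm with printed pE), `"table5"` (SD / PRESS /
#'   predictive r2 summaries), `"table6"` (external-validation battery
#'   summaries).
#' @return data frame.
#' @export
load_paper_fixtures <- function(table_id) {
  known <- c("tableA", "tableB", "activityA", "activityB", "table5", "table6")
  if (!table_id %in% known)
    stop("unknown fixture id '", table_id, "'; known: ",
         paste(known, collapse = ", "))
  df <- read.csv(.qsar3d_extdata(paste0(table_id, ".csv")),
                 stringsAsFactors = FALSE)
  if (table_id %in% c("tableA", "tableB")) {
    for (mdl in c("comfa", "comsia")) {
      delta <- df$actual_pE - df[[paste0(mdl, "_pred")]]
      bad <- abs(delta - df[[paste0(mdl, "_resid")]]) > 0.005 + 1e-9
      if (any(bad))
        stop("fixture ", table_id, ": residual inconsistency for ",
             paste(df$id[bad], collapse = ", "))
    }
  }
  df
}
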