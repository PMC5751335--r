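# fit a tiny model whose descriptor space is fully controlled: three
# molecules on a 1D lattice where only columns near the varying atom differ
tiny_model <- function() {
  syn <- generate_toy_set(synthetic_spec(n_molecules = 12, seed = 61))
  bl <- filter_columns(field_blocks(syn$molecules, fields = "comsia_E"))
  list(model = fit_field_model(bl, syn$activities$pE, max_N = 2),
       blocks = bl, syn = syn)
}

test_that("importance grids equal coefficient x stdev, mapped to the lattice", {
  tm <- tiny_model()
  grids <- importance_grid(tm$model)
  g <- grids$comsia_E
  expect_equal(length(g$values), g$lattice$n_points)
  # dropped columns carry zero importance
  expect_true(all(g$values[tm$blocks$comsia_E$dropped] == 0))
  # direct recomputation oracle
  desc <- tm$model$descriptors
  imp <- tm$model$coefficients * apply(desc$X, 2, sd)
  expect_equal(g$values[desc$col_point], unname(imp), tolerance = 1e-10)
  # linearity: doubling y doubles every importance value
  g2 <- importance_grid(fit_pls(desc$X, 2 * tm$syn$activities$pE,
                                tm$model$n_components),
                        descriptors = desc)$comsia_E
  expect_equal(g2$values, 2 * g$values, tolerance = 1e-8)
})

test_that("a single-column model yields a single nonzero grid cell", {
  # blocks where only one column survives filtering
  mols <- list(point_mol("a", c(0, 0, 0), charge = 0.4, E = 10),
               point_mol("b", c(0, 0, 0), charge = -0.2, E = 5),
               point_mol("c", c(0, 0, 0), charge = 0.1, E = 7),
               point_mol("d", c(0, 0, 0), charge = -0.4, E = 3))
  lat <- make_lattice(c(-1, 0, 0), 1, c(3, 1, 1))
  bl <- field_blocks(mols, lat, fields = "comsia_E")
  # keep only the centre column artificially
  bl$comsia_E$dropped <- c(1L, 3L)
  fm <- fit_field_model(bl, log10(vapply(mols, function(m) m$activity_E, 0)),
                        max_N = 1)
  g <- importance_grid(fm)$comsia_E
  expect_equal(sum(g$values != 0), 1)
  expect_equal(which(g$values != 0), 2L)
})

test_that("contour levels honour the cumulative-mass rule", {
  lat <- make_lattice(c(0, 0, 0), 1, c(5, 1, 1))
  g <- structure(list(kind = "comsia_E", values = c(0, 4, 0, 0, 0),
                      lattice = lat), class = "qsar_importance_grid")
  lev <- contour_levels(g)
  expect_equal(lev$positive, 4)
  reg <- contour_region(g, lev)
  expect_equal(nrow(reg$favorable), 1)
  expect_equal(reg$favorable$x, 1)         # second cell along x
  expect_equal(nrow(reg$unfavorable), 0)
  # symmetric grids give symmetric levels when percentages match
  gs <- g; gs$values <- c(3, -3, 1, -1, 0)
  lev2 <- contour_levels(gs, favored_pct = 70, disfavored_pct = 70)
  expect_equal(lev2$positive, -lev2$negative)
  expect_error(contour_levels(structure(list(values = rep(0, 5),
                                             lattice = lat),
                                        class = "qsar_importance_grid")),
               "all-zero")
})

test_that("raising favored_pct never enlarges the favorable region", {
  set.seed(62)
  lat <- make_lattice(c(0, 0, 0), 1, c(40, 1, 1))
  g <- structure(list(kind = "comsia_E", values = rnorm(40), lattice = lat),
                 class = "qsar_importance_grid")
  sizes <- vapply(c(20, 40, 60, 80, 95), function(p) {
    lev <- contour_levels(g, favored_pct = p)
    nrow(contour_region(g, lev)$favorable)
  }, 0)
  expect_true(all(diff(sizes) <= 0))
})

test_that("contour regions track a joint rigid translation", {
  tm <- tiny_model()
  g <- importance_grid(tm$model)$comsia_E
  reg <- contour_region(g)
  shift <- c(4, -1, 2)
  g2 <- g; g2$lattice$origin <- g$lattice$origin + shift
  reg2 <- contour_region(g2)
  expect_equal(reg2$favorable$x, reg$favorable$x + shift[1])
  expect_equal(reg2$favorable$importance, reg$favorable$importance)
})

test_that("cube and DX exports are well-formed and complete", {
  tm <- tiny_model()
  out <- withr::local_tempdir()
  mpath <- export_contours(tm$model, out, mol = tm$syn$molecules[[1]])
  man <- jsonlite::read_json(mpath)
  expect_true("comsia_E" %in% names(man))
  cube <- readLines(file.path(out, man$comsia_E$file))
  lat <- tm$model$descriptors$lattice
  nat <- as.integer(substr(cube[3], 1, 5))
  expect_equal(nat, n_atoms(tm$syn$molecules[[1]]))
  vals <- as.numeric(unlist(lapply(cube[-seq_len(6 + nat)], function(l)
    strsplit(trimws(l), "\\s+")[[1]])))
  expect_equal(length(vals), lat$n_points)
  g <- importance_grid(tm$model)$comsia_E
  expect_equal(sum(abs(vals) > 1e-30), sum(abs(g$values) > 1e-30))
  dxf <- file.path(out, "grid.dx")
  write_dx(g, dxf)
  expect_true(any(grepl("gridpositions", readLines(dxf))))
})
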