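#' Default pipeline configuration
#'
#' The canonical settings of the study design this pipeline implements:
#' 2 Angstrom grid spacing with a 4 Angstrom margin, +1/1.52 Angstrom probe,
#' 30 kcal/mol energy truncation, 2.0 kcal/mol column filtering, CoMSIA
#' attenuation 0.3, LOO component search capped at 20, 8:2 random
#' train/test split. `run_pipeline()` refuses configs that silently drift
#' from these canonical field settings unless `allow_nonstandard = TRUE`.
#'
#' @return nested list of defaults.
#' @export
default_config <- function() {
  list(
    input = list(sdf = NULL, activity_tag = "E_mm", activity_csv = NULL,
                 synthetic = NULL),
    align = list(template_id = NULL, mapping_csv = NULL, core_size = NULL),
    grid = list(spacing = 2.0, margin = 4.0),
    probe = list(charge = 1, radius = 1.52),
    cutoff = 30,
    column_filter = 2.0,
    comsia_filter = 0,
    alpha = 0.3,
    dielectric = "distance",
    block_scale = TRUE,
    pls = list(max_N = 20, method = "fast"),
    split = list(test_ids = NULL, ratio = 0.2),
    contours = list(favored_pct = 80, disfavored_pct = 20),
    families = c("comfa", "comsia"),
    seed = 1L,
    allow_nonstandard = FALSE,
    out_dir = NULL)
}

.merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

.family_fields <- function(family) {
  switch(family,
         comfa = c("comfa_steric", "comfa_electrostatic"),
         comsia = c("comsia_S", "comsia_E", "comsia_H", "comsia_D",
                    "comsia_A"),
         stop("unknown field family: ", family))
}

# rows of every block restricted to the given molecule ids
.subset_blocks <- function(blocks, ids) {
  lapply(blocks, function(b) {
    b$matrix <- b$matrix[ids, , drop = FALSE]
    b
  })
}

# descriptor rows for arbitrary molecules, matching a fitted model's
# column selection and block scaling
.descriptor_rows <- function(blocks, ids, desc) {
  Xs <- list()
  for (kind in names(desc$block_sd)) {
    b <- blocks[[kind]]
    keep <- desc$col_point[desc$col_block == kind]
    m <- b$matrix[ids, keep, drop = FALSE]
    if (desc$block_scale) m <- m / desc$block_sd[kind]
    Xs[[kind]] <- m
  }
  do.call(cbind, Xs)
}

#' Run the full 3D-QSAR pipeline
#'
#' Orchestrates: structure input (file or synthetic) -> parameter assignment
#' -> rigid core alignment -> lattice and field generation -> column
#' filtering -> train/test split -> exhaustive field-combination PLS search
#' -> external validation of the best model per field family -> contour
#' export. All randomness derives from `config$seed`; rerunning an
#' identical config reproduces identical reports.
#'
#' Output files in `out_dir`: `model_search.csv` (one row per field
#' combination), `predictions.csv` (per-compound actual/predicted pE and
#' residuals), `validation.json` / `validation.csv` (predictive r2 and the
#' Golbraikh-Tropsha battery), `contours/` (cube files + manifest),
#' `resolved_config.json`, `log.txt`.
#'
#' @param config nested list (see [default_config()]) or path to a YAML
#'   file with the same structure.
#' @return invisible list with molecules, activity table, search tables,
#'   best models, validation reports, and the output directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(default_config(), config)
  canonical <- default_config()
  drift <- c(spacing = cfg$grid$spacing != canonical$grid$spacing,
             cutoff = cfg$cutoff != canonical$cutoff,
             column_filter = cfg$column_filter != canonical$column_filter,
             alpha = cfg$alpha != canonical$alpha,
             probe = cfg$probe$charge != canonical$probe$charge ||
               cfg$probe$radius != canonical$probe$radius)
  if (any(drift) && !isTRUE(cfg$allow_nonstandard))
    stop("config drifts from the canonical field settings (",
         paste(names(drift)[drift], collapse = ", "),
         "); set allow_nonstandard = TRUE to override")
  out_dir <- cfg$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  say <- function(...) log_lines <<- c(log_lines, paste0(...))

  ## --- structures -----------------------------------------------------
  if (!is.null(cfg$input$synthetic)) {
    sargs <- cfg$input$synthetic
    sargs$seed <- if (is.null(sargs$seed)) cfg$seed else sargs$seed
    spec <- do.call(synthetic_spec, sargs)
    syn <- generate_toy_set(spec)
    mols <- syn$molecules
    truth <- syn$truth
    say("input: synthetic set, ", length(mols), " molecules")
  } else {
    if (is.null(cfg$input$sdf)) stop("config$input needs 'sdf' or 'synthetic'")
    mols <- read_structures(cfg$input$sdf, activity_tag = cfg$input$activity_tag,
                            activity_csv = cfg$input$activity_csv)
    mols <- lapply(mols, assign_atom_parameters)
    truth <- NULL
    say("input: ", cfg$input$sdf, ", ", length(mols), " molecules")
    if (!is.null(cfg$align$template_id)) {
      mapping <- if (!is.null(cfg$align$mapping_csv))
        read_core_mapping(cfg$align$mapping_csv) else NULL
      al <- align_set(mols, cfg$align$template_id, mapping,
                      core_size = cfg$align$core_size)
      mols <- al$molecules
      say("alignment: core rmsd max ", sprintf("%.4f", max(al$rmsd)), " A")
    }
  }
  ids <- vapply(mols, function(m) m$id, "")

  ## --- activities -----------------------------------------------------
  E <- vapply(mols, function(m) m$activity_E, 0)
  if (anyNA(E))
    stop("molecule(s) missing activity: ",
         paste(ids[is.na(E)], collapse = ", "))
  act <- activity_table(ids, E)
  say("activities: Emax = ", sprintf("%.2f", max(E)), " mm")

  ## --- split ----------------------------------------------------------
  if (!is.null(cfg$split$test_ids)) {
    test_ids <- cfg$split$test_ids
    if (!all(test_ids %in% ids))
      stop("unknown test ids: ",
           paste(setdiff(test_ids, ids), collapse = ", "))
  } else {
    set.seed(cfg$seed)
    n_test <- max(1L, round(length(ids) * cfg$split$ratio))
    test_ids <- sort(sample(ids, n_test))
  }
  act$role <- ifelse(act$id %in% test_ids, "test", "train")
  train_ids <- act$id[act$role == "train"]
  say("split: ", length(train_ids), " train / ", length(test_ids),
      " test (", paste(test_ids, collapse = ","), ")")

  ## --- fields ---------------------------------------------------------
  lattice <- build_lattice(mols, spacing = cfg$grid$spacing,
                           margin = cfg$grid$margin)
  probe <- default_probe(charge = cfg$probe$charge, radius = cfg$probe$radius)
  all_fields <- unlist(lapply(cfg$families, .family_fields))
  blocks <- field_blocks(mols, lattice, fields = all_fields, probe = probe,
                         cutoff = cfg$cutoff, alpha = cfg$alpha,
                         dielectric = cfg$dielectric)
  say("lattice: ", paste(lattice$counts, collapse = " x "), " = ",
      lattice$n_points, " points")

  ## --- per-family search, fit, validation -----------------------------
  y_train <- act$pE[match(train_ids, act$id)]
  train_mean <- mean(y_train)
  search_tabs <- list(); best <- list(); reports <- list()
  pred_tab <- act
  for (fam in cfg$families) {
    fam_blocks <- .subset_blocks(blocks[.family_fields(fam)], train_ids)
    fam_blocks <- filter_columns(fam_blocks, threshold = cfg$column_filter,
                                 comsia_threshold = cfg$comsia_filter)
    tab <- enumerate_field_models(fam_blocks, y_train,
                                  max_N = cfg$pls$max_N,
                                  block_scale = cfg$block_scale,
                                  method = cfg$pls$method,
                                  prefix = paste0(toupper(fam), "-"))
    say("search[", fam, "]: ", nrow(tab), " models, best q2 = ",
        sprintf("%.3f", max(tab$q2, na.rm = TRUE)))
    search_tabs[[fam]] <- tab
    models <- attr(tab, "models")
    ok <- which(!is.na(tab$q2))
    bi <- ok[which.max(tab$q2[ok])]
    bm <- models[[bi]]
    best[[fam]] <- list(label = tab$fields[bi], model = bm)
    X_all <- .descriptor_rows(blocks, ids, bm$descriptors)
    pred_tab[[paste0(fam, "_pred")]] <- round(predict(bm, X_all), 4)
    pred_tab[[paste0(fam, "_resid")]] <-
      round(pred_tab$pE - pred_tab[[paste0(fam, "_pred")]], 4)
    sel <- pred_tab$role == "test"
    reports[[fam]] <- validation_report(pred_tab$pE[sel],
                                        pred_tab[[paste0(fam, "_pred")]][sel],
                                        train_mean, q2 = bm$q2)
  }

  ## --- outputs --------------------------------------------------------
  search_all <- do.call(rbind, lapply(names(search_tabs), function(f) {
    t <- search_tabs[[f]]
    for (L in c("S", "E", "H", "D", "A"))
      if (is.null(t[[paste0("pct_", L)]])) t[[paste0("pct_", L)]] <- NA_real_
    num <- vapply(t, is.numeric, TRUE)
    t[num] <- lapply(t[num], round, 3)
    cbind(family = f, t[c("fields", "q2", "N", "SEP", "SEE", "r2_ncv", "F",
                          paste0("pct_", c("S", "E", "H", "D", "A")),
                          "error")])
  }))
  write.csv(search_all, file.path(out_dir, "model_search.csv"),
            row.names = FALSE, na = "")
  pred_out <- pred_tab
  pred_out$pE <- round(pred_out$pE, 4)
  write.csv(pred_out, file.path(out_dir, "predictions.csv"),
            row.names = FALSE)
  val <- lapply(names(reports), function(f) {
    r <- reports[[f]]
    t <- r$tropsha
    list(family = f, best = best[[f]]$label,
         n_components = best[[f]]$model$n_components,
         q2 = best[[f]]$model$q2, SEP = best[[f]]$model$SEP,
         r2_ncv = best[[f]]$model$r2_ncv, SEE = best[[f]]$model$SEE,
         F = best[[f]]$model$F,
         contributions = as.list(best[[f]]$model$contributions),
         SD = r$SD, PRESS = r$PRESS, r2_pred = r$r2_pred,
         r2 = t$r2, k = t$k, k_primed = t$k_primed, r0_sq = t$r0_sq,
         r0_sq_primed = t$r0_sq_primed, rm2 = t$rm2,
         criteria = t$criteria, tropsha_pass = t$pass)
  })
  names(val) <- names(reports)
  jsonlite::write_json(val, file.path(out_dir, "validation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  val_csv <- do.call(rbind, lapply(val, function(v)
    data.frame(family = v$family, best = v$best, N = v$n_components,
               q2 = round(v$q2, 3), r2_ncv = round(v$r2_ncv, 3),
               SEE = round(v$SEE, 3), F = round(v$F, 3),
               SD = round(v$SD, 4), PRESS = round(v$PRESS, 4),
               r2_pred = round(v$r2_pred, 3), r2 = round(v$r2, 3),
               k_primed = round(v$k_primed, 3),
               r0_sq_primed = round(v$r0_sq_primed, 3),
               rm2 = round(v$rm2, 3), tropsha_pass = v$tropsha_pass)))
  write.csv(val_csv, file.path(out_dir, "validation.csv"), row.names = FALSE)
  overall <- names(best)[which.max(vapply(best, function(b) b$model$q2, 0))]
  export_contours(best[[overall]]$model, file.path(out_dir, "contours"),
                  favored_pct = cfg$contours$favored_pct,
                  disfavored_pct = cfg$contours$disfavored_pct,
                  mol = mols[[1]])
  say("contours: exported for ", best[[overall]]$label)
  jsonlite::write_json(cfg, file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(list(molecules = mols, activities = act, truth = truth,
                 lattice = lattice, blocks = blocks,
                 search = search_tabs, best = best, validation = reports,
                 predictions = pred_tab, out_dir = out_dir,
                 config = cfg, test_ids = test_ids))
}
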