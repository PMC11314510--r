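#' Run the full trait-based risk analysis
#'
#' Orchestrates the analysis end to end: ingest a trait CSV (or simulate a
#' cohort), impute absence for binary presence-type traits, z-scale the
#' continuous traits, screen traits and trait pairs, build the two maximal
#' models and reduce them by forward stepwise AIC, choose classification
#' cutoffs by the Index of Union with the sensitivity-priority override,
#' score every species under both models, and triage the Data Deficient
#' species. Every stage writes its output into `out_dir`, and a manifest
#' records the configuration, seed, package version and input checksum so
#' a run can be re-executed from its manifest alone.
#'
#' @param config A list with either `csv` (path to a trait CSV) or
#'   `cohort` (a [cohort_config()]); optional entries `alpha` (default
#'   0.05), `min_sensitivity` (default 0.70), `seed` (default 1) and
#'   `triage_only` (logical; when `TRUE`, `risks` — a data frame as in
#'   [triage_dd()], default the packaged DD reference table — is triaged
#'   with the published cutoffs and no models are fitted).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the stage results (`matrix`, `screen`,
#'   `pairs`, `mams`, `cutoffs`, `risks`, `triage`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  alpha <- config$alpha %||% 0.05
  min_se <- config$min_sensitivity %||% 0.70
  seed <- config$seed %||% 1L

  manifest <- list(package_version = as.character(utils::packageVersion("mossrisk")),
                   seed = seed, alpha = alpha, min_sensitivity = min_se)

  if (isTRUE(config$triage_only)) {
    risks <- config$risks %||% dd_reference_table()
    report <- triage_dd(risks)
    jsonlite::write_json(
      list(counts = as.list(report$counts),
           percentages = as.list(report$percentages),
           n_species = report$n_species, excluded = report$excluded),
      file.path(out_dir, "triage.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(report$species, file.path(out_dir, "risk.csv"),
                     row.names = FALSE, na = "")
    manifest$mode <- "triage_only"
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(list(triage = report, manifest = manifest)))
  }

  # ingest ------------------------------------------------------------
  if (!is.null(config$csv)) {
    tm <- read_trait_matrix(config$csv)
    manifest$input <- list(csv = config$csv,
                           md5 = unname(tools::md5sum(config$csv)))
  } else if (!is.null(config$cohort)) {
    cc <- config$cohort
    cc$seed <- seed
    sim <- generate_cohort(cc)
    tm <- sim$matrix
    if (!is.null(config$dd_fraction)) {
      tm <- make_dd_holdout(tm, config$dd_fraction, seed = seed + 1L)$matrix
    }
    manifest$input <- list(simulated = TRUE, n_species = cc$n_species,
                           dd_fraction = config$dd_fraction)
  } else {
    stop("config must provide 'csv' or 'cohort'", call. = FALSE)
  }
  tm <- impute_binary_absence(tm)
  for (trait in intersect(tm$registry$name[tm$registry$kind == "continuous"],
                          names(tm$data))) {
    ok <- tryCatch({tm <- zscale(tm, trait); TRUE},
                   error = function(e) FALSE)
    if (!ok) warning("could not z-scale '", trait, "'", call. = FALSE)
  }

  # screening ----------------------------------------------------------
  screen <- screen_traits(tm, alpha)
  utils::write.csv(screen, file.path(out_dir, "screening.csv"),
                   row.names = FALSE, na = "")
  pairs <- screen_trait_pairs(tm, alpha = alpha)
  utils::write.csv(pairs, file.path(out_dir, "trait_pairs.csv"),
                   row.names = FALSE, na = "")

  # model building ------------------------------------------------------
  specs <- build_maximal_models(screen, pairs)
  mams <- lapply(specs, stepwise_forward_aic, tm = tm)
  for (id in names(mams)) {
    m <- mams[[id]]
    jsonlite::write_json(
      list(model_id = m$model_id, selected = m$selected_predictors,
           n = m$n, aic = m$fit$aic,
           coefficients = mam_coefficient_table(m),
           trace = m$trace),
      file.path(out_dir, paste0(tolower(id), ".json")),
      auto_unbox = TRUE, digits = NA)
  }

  # cutoffs -------------------------------------------------------------
  cutoffs <- lapply(mams, function(m) {
    roc <- roc_curve(m$fit$fitted_probabilities, m$fit$response)
    sel <- select_cutoff(index_of_union(roc), min_se)
    sel
  })
  for (id in names(cutoffs)) {
    s <- cutoffs[[id]]
    jsonlite::write_json(
      list(model_id = id, chosen_cutoff = s$chosen_cutoff,
           rule_applied = s$rule_applied, rank = s$rank,
           sensitivity = s$sensitivity, specificity = s$specificity,
           auc = s$auc),
      file.path(out_dir, paste0("cutoff_", tolower(id), ".json")),
      auto_unbox = TRUE, digits = NA)
  }

  # scoring -------------------------------------------------------------
  all_rows <- seq_len(nrow(tm$data))
  risk_of <- function(m) {
    if (!length(m$selected_predictors)) {
      return(rep(stats::plogis(m$fit$coefficients[[1]]), nrow(tm$data)))
    }
    nd <- lapply(m$selected_predictors, function(tr)
      trait_design_column(tm, tr, all_rows))
    names(nd) <- m$selected_predictors
    if (any(vapply(nd, is.null, TRUE))) {
      stop("cannot build scoring design for ", m$model_id, call. = FALSE)
    }
    unname(stats::predict(m$fit$glm, newdata = as.data.frame(nd),
                          type = "response"))
  }
  risks <- data.frame(species = tm$data$species,
                      iucn_category = tm$data$iucn_category,
                      risk_mam1 = risk_of(mams$M1),
                      risk_mam2 = risk_of(mams$M2),
                      stringsAsFactors = FALSE)
  # MAM2 applies only where sporophyte morphology was recorded
  risks$risk_mam2[!has_sporophyte_traits(tm)] <- NA
  risks$class_mam1 <- classify_risk(risks$risk_mam1,
                                    cutoffs$M1$chosen_cutoff)
  risks$class_mam2 <- classify_risk(risks$risk_mam2,
                                    cutoffs$M2$chosen_cutoff)
  both_na <- is.na(risks$class_mam1) & is.na(risks$class_mam2)
  risks$verdict <- NA_character_
  risks$verdict[!both_na] <- risk_verdict(risks$class_mam1[!both_na],
                                          risks$class_mam2[!both_na])
  utils::write.csv(risks, file.path(out_dir, "risk.csv"),
                   row.names = FALSE, na = "")

  # DD triage -----------------------------------------------------------
  dd <- risks[tm$data$threat_status == "DD", , drop = FALSE]
  triage <- NULL
  if (nrow(dd)) {
    triage <- triage_dd(dd[c("species", "risk_mam1", "risk_mam2")],
                        cutoffs$M1$chosen_cutoff, cutoffs$M2$chosen_cutoff)
    jsonlite::write_json(
      list(counts = as.list(triage$counts),
           percentages = as.list(triage$percentages),
           n_species = triage$n_species, excluded = triage$excluded),
      file.path(out_dir, "triage.json"), auto_unbox = TRUE, digits = NA)
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(matrix = tm, screen = screen, pairs = pairs, mams = mams,
                 cutoffs = cutoffs, risks = risks, triage = triage,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
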