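#' Published risk-model parameters
#'
#' Loads the published minimum-adequate-model coefficients, scaling
#' constants and cutoffs packaged with mossrisk (versioned JSON under
#' `extdata/`), so species can be scored without refitting.
#'
#' MAM1 (every species): intercept -0.79; plant sex +0.54 for monoicous;
#' sporophyte presence -1.18; substrate breadth -0.83 per SD with scaling
#' mean 1.69, SD 0.94; cutoff 0.21. MAM2 (sporophyte-bearing species with
#' recorded morphology): intercept -1.65; seta length -0.61 per SD with
#' scaling mean 14 mm, SD 13.32 mm; substrate breadth -0.90 per SD with
#' scaling mean 1.8, SD 0.98; cutoff 0.18.
#'
#' @param model `"MAM1"` or `"MAM2"`.
#' @return A `risk_model_params` list: `model_id`, `intercept`,
#'   `coefficients` (named), `scaling` (named list of `c(mean, sd)`) and
#'   `cutoff`.
#' @export
mam_published_params <- function(model = c("MAM1", "MAM2")) {
  model <- match.arg(model)
  path <- system.file("extdata", "mam_published_params.json",
                      package = "mossrisk", mustWork = TRUE)
  all <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- all[[model]]
  structure(list(model_id = model,
                 intercept = p$intercept,
                 coefficients = unlist(p$coefficients),
                 scaling = lapply(p$scaling, function(s)
                   c(mean = s[["mean"]], sd = s[["sd"]])),
                 cutoff = p$cutoff),
            class = "risk_model_params")
}

#' Risk-model parameters from a fitted minimum adequate model
#'
#' @param mam A `mam_result` from [stepwise_forward_aic()].
#' @param tm The [trait_matrix()] the model was fitted on (source of the
#'   z-scaling parameters for continuous predictors).
#' @param cutoff Classification cutoff, e.g. from [select_cutoff()].
#' @param model_id `"MAM1"` or `"MAM2"`.
#' @return A `risk_model_params` list as in [mam_published_params()].
#' @export
mam_params_from_fit <- function(mam, tm, cutoff, model_id = mam$model_id) {
  co <- mam$fit$coefficients
  coefs <- co[-1]
  names(coefs) <- mam$selected_predictors
  scaling <- tm$scaling[intersect(names(tm$scaling), mam$selected_predictors)]
  structure(list(model_id = model_id, intercept = unname(co[1]),
                 coefficients = coefs, scaling = scaling, cutoff = cutoff),
            class = "risk_model_params")
}

#' Extinction risk under MAM1 (plant sex, sporophyte presence, substrate breadth)
#'
#' Evaluates
#' `plogis(intercept + b_sex [monoicous] + b_sporo [present] + b_breadth (breadth - mean)/sd)`.
#' All arguments are vectorized; a missing input yields a missing risk
#' (never zero).
#'
#' @param plant_sex `"dioicous"` or `"monoicous"`.
#' @param sporophyte_presence `"absent"` or `"present"`.
#' @param substrate_breadth Number of distinct substrates occupied (>= 1),
#'   raw count.
#' @param params A `risk_model_params` with `model_id = "MAM1"`.
#' @return Probability of being threatened, in (0, 1), or `NA`.
#' @export
#' @examples
#' score_mam1("dioicous", "absent", 1.69)   # ~0.31
#' score_mam1("monoicous", "present", 1.69) # ~0.19
score_mam1 <- function(plant_sex, sporophyte_presence, substrate_breadth,
                       params = mam_published_params("MAM1")) {
  stopifnot(params$model_id %in% c("MAM1", "M1"))
  sex_ok <- plant_sex %in% c("dioicous", "monoicous") | is.na(plant_sex)
  spo_ok <- sporophyte_presence %in% c("absent", "present") |
    is.na(sporophyte_presence)
  if (!all(sex_ok) || !all(spo_ok)) {
    stop("plant_sex must be dioicous/monoicous and sporophyte_presence ",
         "absent/present", call. = FALSE)
  }
  cf <- function(nm) {
    if (nm %in% names(params$coefficients)) params$coefficients[[nm]] else 0
  }
  eta <- params$intercept +
    cf("plant_sex") * (plant_sex == "monoicous") +
    cf("sporophyte_presence") * (sporophyte_presence == "present")
  if (cf("substrate_breadth") != 0) {
    sc <- params$scaling[["substrate_breadth"]]
    if (is.null(sc)) stop("params lack substrate_breadth scaling", call. = FALSE)
    eta <- eta + cf("substrate_breadth") *
      (substrate_breadth - sc[["mean"]]) / sc[["sd"]]
  } else {
    # breadth still gates scoreability even when the model dropped it
    eta <- eta + 0 * substrate_breadth
  }
  unname(stats::plogis(eta))
}

#' Extinction risk under MAM2 (seta length, substrate breadth)
#'
#' Evaluates
#' `plogis(intercept + b_seta (seta - mean)/sd + b_breadth (breadth - mean)/sd)`
#' for sporophyte-bearing species with recorded seta length. Vectorized;
#' missing inputs yield missing risks.
#'
#' @param seta_length_mm Seta length in mm (>= 0).
#' @param substrate_breadth Number of distinct substrates occupied (>= 1).
#' @param params A `risk_model_params` with `model_id = "MAM2"`.
#' @return Probability of being threatened, in (0, 1), or `NA`.
#' @export
#' @examples
#' score_mam2(14, 1.8)  # ~0.16 at the scaling means
score_mam2 <- function(seta_length_mm, substrate_breadth,
                       params = mam_published_params("MAM2")) {
  stopifnot(params$model_id %in% c("MAM2", "M2"))
  if (any(seta_length_mm < 0, na.rm = TRUE)) {
    stop("seta_length_mm must be non-negative", call. = FALSE)
  }
  cf <- function(nm) {
    if (nm %in% names(params$coefficients)) params$coefficients[[nm]] else 0
  }
  eta <- params$intercept + 0 * seta_length_mm + 0 * substrate_breadth
  for (term in list(c("seta_length", "seta_length_mm"),
                    c("substrate_breadth", "substrate_breadth"))) {
    if (cf(term[1]) != 0) {
      sc <- params$scaling[[term[1]]]
      if (is.null(sc)) stop("params lack ", term[1], " scaling", call. = FALSE)
      x <- get(term[2])
      eta <- eta + cf(term[1]) * (x - sc[["mean"]]) / sc[["sd"]]
    }
  }
  unname(stats::plogis(eta))
}

#' Classify a risk score against a cutoff
#'
#' A species is called threatened when its risk reaches the cutoff
#' (`risk >= cutoff`, boundary inclusive).
#'
#' @param risk Risk probabilities in `[0, 1]` (may contain `NA`).
#' @param cutoff Cutoff probability in `[0, 1]`.
#' @return Character vector `"threatened"` / `"non-threatened"` (`NA`
#'   propagates).
#' @export
classify_risk <- function(risk, cutoff) {
  stopifnot(cutoff >= 0, cutoff <= 1,
            all(risk >= 0 & risk <= 1, na.rm = TRUE))
  ifelse(risk >= cutoff, "threatened", "non-threatened")
}

#' Combine two model classifications into a triage verdict
#'
#' All available classifications threatened gives Threatened; all available
#' non-threatened gives Non-threatened; disagreement between the two
#' models gives Possibly Threatened. A species scored by a single model
#' takes that model's verdict directly. Both classifications missing is an
#' error.
#'
#' @param class_mam1,class_mam2 `"threatened"`, `"non-threatened"` or `NA`;
#'   vectorized.
#' @return Character vector in `{"Threatened", "Possibly Threatened",
#'   "Non-threatened"}`.
#' @export
risk_verdict <- function(class_mam1, class_mam2) {
  n <- max(length(class_mam1), length(class_mam2))
  class_mam1 <- rep_len(class_mam1, n)
  class_mam2 <- rep_len(class_mam2, n)
  if (any(is.na(class_mam1) & is.na(class_mam2))) {
    stop("at least one model classification must be present", call. = FALSE)
  }
  thr <- function(x) !is.na(x) & x == "threatened"
  non <- function(x) !is.na(x) & x == "non-threatened"
  ifelse(thr(class_mam1) & is.na(class_mam2), "Threatened",
  ifelse(thr(class_mam2) & is.na(class_mam1), "Threatened",
  ifelse(non(class_mam1) & is.na(class_mam2), "Non-threatened",
  ifelse(non(class_mam2) & is.na(class_mam1), "Non-threatened",
  ifelse(thr(class_mam1) & thr(class_mam2), "Threatened",
  ifelse(non(class_mam1) & non(class_mam2), "Non-threatened",
         "Possibly Threatened"))))))
}

#' The packaged Data Deficient reference table
#'
#' The 44 Data Deficient moss species published with their per-model risk
#' scores and triage verdicts. Risk scores are the printed values; species
#' scored by a single model have `NA` for the other.
#'
#' @return Data frame: `species`, `risk_mam1`, `risk_mam2`,
#'   `published_verdict`.
#' @export
dd_reference_table <- function() {
  path <- system.file("extdata", "dd_species_scores.csv",
                      package = "mossrisk", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Triage species into threat verdicts from per-model risks
#'
#' Applies the two cutoffs and the verdict combination rule to per-species
#' risk scores and aggregates counts and percentages per verdict. Species
#' with both risks missing are excluded and listed in the report.
#'
#' @param risks Data frame with columns `species`, `risk_mam1`,
#'   `risk_mam2` (either risk may be `NA`); defaults to the packaged DD
#'   reference table.
#' @param cutoff_mam1,cutoff_mam2 Classification cutoffs (defaults: the
#'   published 0.21 and 0.18).
#' @return A `triage_report`: list with `species` (per-species risks,
#'   classes and verdict), `counts` and `percentages` (named by verdict,
#'   counts summing to the number of scoreable species), `n_species` and
#'   `excluded` (unscoreable species names).
#' @export
#' @examples
#' rep <- triage_dd()
#' rep$counts  # Threatened 24, Possibly Threatened 13, Non-threatened 7
triage_dd <- function(risks = dd_reference_table(),
                      cutoff_mam1 = mam_published_params("MAM1")$cutoff,
                      cutoff_mam2 = mam_published_params("MAM2")$cutoff) {
  stopifnot(all(c("species", "risk_mam1", "risk_mam2") %in% names(risks)))
  scoreable <- !(is.na(risks$risk_mam1) & is.na(risks$risk_mam2))
  excluded <- risks$species[!scoreable]
  df <- risks[scoreable, , drop = FALSE]
  df$class_mam1 <- classify_risk(df$risk_mam1, cutoff_mam1)
  df$class_mam2 <- classify_risk(df$risk_mam2, cutoff_mam2)
  df$verdict <- risk_verdict(df$class_mam1, df$class_mam2)
  lv <- c("Threatened", "Possibly Threatened", "Non-threatened")
  counts <- table(factor(df$verdict, levels = lv))
  structure(list(species = df,
                 counts = stats::setNames(as.integer(counts), lv),
                 percentages = stats::setNames(
                   as.numeric(100 * counts / nrow(df)), lv),
                 n_species = nrow(df),
                 cutoffs = c(MAM1 = cutoff_mam1, MAM2 = cutoff_mam2),
                 excluded = excluded),
            class = "triage_report")
}

#' @export
print.triage_report <- function(x, ...) {
  cat("Triage of", x$n_species, "species (cutoffs",
      paste(sprintf("%s = %.2f", names(x$cutoffs), x$cutoffs),
            collapse = ", "), ")\n")
  for (v in names(x$counts)) {
    cat(sprintf("  %-20s %3d (%.0f%%)\n", v, x$counts[[v]],
                x$percentages[[v]]))
  }
  if (length(x$excluded)) {
    cat("  excluded (no scoreable model):",
        paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Score every species in a trait matrix with two risk models
#'
#' MAM1 risks are computed for species with plant sex, sporophyte presence
#' and substrate breadth recorded; MAM2 risks additionally require a
#' recorded seta length (sporophyte morphology). Species lacking substrate
#' breadth cannot be scored by either model and appear with two missing
#' risks.
#'
#' @param tm A [trait_matrix()] holding raw-unit trait values.
#' @param params1,params2 `risk_model_params` for the two models.
#' @return Data frame `species`, `iucn_category`, `risk_mam1`, `risk_mam2`.
#' @export
score_species <- function(tm,
                          params1 = mam_published_params("MAM1"),
                          params2 = mam_published_params("MAM2")) {
  stopifnot(inherits(tm, "trait_matrix"))
  d <- tm$data
  get <- function(cl) if (cl %in% names(d)) d[[cl]] else rep(NA, nrow(d))
  r1 <- score_mam1(get("plant_sex"), get("sporophyte_presence"),
                   get("substrate_breadth"), params1)
  seta <- get("seta_length")
  r2 <- score_mam2(ifelse(is.na(seta), NA_real_, seta),
                   get("substrate_breadth"), params2)
  data.frame(species = d$species, iucn_category = d$iucn_category,
             risk_mam1 = r1, risk_mam2 = r2, stringsAsFactors = FALSE)
}
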