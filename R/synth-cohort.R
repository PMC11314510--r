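#' Configuration for a synthetic moss cohort
#'
#' Describes the generative model used by [generate_cohort()]: a cohort of
#' species whose threat status follows a logistic model on a small set of
#' functional traits, with the trait-trait dependencies the analysis
#' assumes (plant sex with vegetative reproduction, plant sex with
#' sporophyte presence, seta length with seta shape) and block missingness
#' of the sporophyte-morphology traits.
#'
#' Defaults emulate the study cohort: 723 species, roughly 22% threatened,
#' true risk coefficients equal to the published minimum-adequate-model
#' estimates (plant sex +0.54, sporophyte presence -1.18, substrate
#' breadth -0.83 per SD, seta length -0.61 per SD, baseline logit -0.79),
#' sporophyte-morphology traits recorded for roughly 544 species and
#' substrate data for roughly 700.
#'
#' @param n_species Number of species (>= 2).
#' @param seed Integer seed; generation is deterministic given the config.
#' @param baseline_logit Intercept of the threat model (logit scale).
#' @param true_coefficients Named logit-scale coefficients. Recognized
#'   names: `plant_sex` (monoicous vs dioicous), `sporophyte_presence`
#'   (present vs absent), `substrate_breadth` (per SD), `seta_length`
#'   (per SD). Unlisted predictors have zero effect.
#' @param sex_monoicous_prob Marginal probability of monoicy.
#' @param dependence_odds Named odds ratios: `sex_vegetative` and
#'   `sex_sporophyte` are odds of the trait for monoicous vs dioicous
#'   species; `setalength_setashape` is the odds multiplier on "curved"
#'   per unit log seta length.
#' @param marginal_rates Marginal probabilities of vegetative reproduction,
#'   sporophyte presence, persistent protonema, pendent capsule, cylindric
#'   capsule, ellipsoidal spore, papillose spore.
#' @param continuous_params Named list `trait -> c(mean, sd)` on the raw
#'   scale; traits are drawn log-normal with these moments (lengths are
#'   positive and right-skewed). Substrate breadth is 1 + Poisson with the
#'   configured mean.
#' @param sporophyte_missing_rate Probability that a species' sporophyte
#'   morphology block is masked in the visible matrix (on top of the
#'   structural absence for sporophyte-lacking species).
#' @param breadth_missing_rate Probability that substrate data are missing.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_species = 723,
                          seed = 1,
                          baseline_logit = -0.79,
                          true_coefficients = c(plant_sex = 0.54,
                                                sporophyte_presence = -1.18,
                                                substrate_breadth = -0.83,
                                                seta_length = -0.61),
                          sex_monoicous_prob = 0.40,
                          dependence_odds = c(sex_vegetative = 0.5,
                                              sex_sporophyte = 2.0,
                                              setalength_setashape = 2.0),
                          marginal_rates = c(vegetative_reproduction = 0.35,
                                             sporophyte_presence = 0.78,
                                             persistent_protonema = 0.10,
                                             capsule_pendent = 0.30,
                                             capsule_cylindric = 0.45,
                                             spore_ellipsoidal = 0.25,
                                             spore_papillose = 0.55),
                          continuous_params = list(
                            seta_length = c(mean = 14, sd = 13.32),
                            capsule_length = c(mean = 2.2, sd = 1.3),
                            stem_length = c(mean = 25, sd = 30),
                            leaf_length = c(mean = 2.0, sd = 1.1),
                            spore_diameter = c(mean = 15, sd = 8),
                            substrate_breadth = c(mean = 1.8, sd = NA)),
                          sporophyte_missing_rate = 0.04,
                          breadth_missing_rate = 0.032) {
  stopifnot(n_species >= 2,
            sex_monoicous_prob > 0, sex_monoicous_prob < 1,
            all(dependence_odds > 0),
            all(marginal_rates > 0), all(marginal_rates < 1),
            sporophyte_missing_rate >= 0, sporophyte_missing_rate < 1,
            breadth_missing_rate >= 0, breadth_missing_rate < 1)
  structure(as.list(environment()), class = "cohort_config")
}

# Closed-form 2x2 solver: group-conditional Bernoulli rates (p0, p1) with
# given marginal m = (1-w) p0 + w p1 and odds ratio q = odds(p1)/odds(p0),
# where w is the probability of group 1.
conditional_rates <- function(marginal, group_prob, odds_ratio) {
  m <- marginal; w <- group_prob; q <- odds_ratio
  if (abs(q - 1) < 1e-12) return(c(p0 = m, p1 = m))
  a <- (1 - w) * (q - 1)
  b <- (1 - w) + w * q - m * (q - 1)
  cc <- -m
  disc <- sqrt(b^2 - 4 * a * cc)
  roots <- c((-b + disc) / (2 * a), (-b - disc) / (2 * a))
  p0 <- roots[roots > 0 & roots < 1][1]
  if (is.na(p0)) stop("no valid conditional rate solution", call. = FALSE)
  p1 <- q * p0 / (1 + (q - 1) * p0)
  c(p0 = p0, p1 = p1)
}

# Log-normal draws with given raw-scale mean and sd
rlnorm_moments <- function(n, mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Generate a synthetic cohort with known risk structure
#'
#' Draws a species-by-trait matrix from the generative model described in
#' [cohort_config()]: plant sex is Bernoulli; vegetative reproduction and
#' sporophyte presence are drawn conditionally on sex with the configured
#' odds ratios (closed-form 2x2 solver); continuous traits are log-normal
#' with the configured raw-scale moments; substrate breadth is
#' 1 + Poisson; seta shape follows a logistic model on log seta length;
#' threat status is Bernoulli with logit equal to the baseline plus the
#' configured coefficients times the predictors (continuous predictors
#' entered as z-scores against their true generating moments). Sporophyte
#' morphology is structurally missing for sporophyte-lacking species and a
#' further random block is masked at the configured rate.
#'
#' @param config A [cohort_config()].
#' @return List with `matrix` (a [trait_matrix()], the visible data) and
#'   `truth` (list: the config, the complete unmasked data frame with the
#'   per-species threat probability and masking indicators, and the z-score
#'   moments used for each continuous predictor).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_species
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  monoicous <- stats::rbinom(n, 1, config$sex_monoicous_prob)

  rv <- conditional_rates(config$marginal_rates[["vegetative_reproduction"]],
                          config$sex_monoicous_prob,
                          config$dependence_odds[["sex_vegetative"]])
  vegetative <- stats::rbinom(n, 1, ifelse(monoicous == 1, rv["p1"], rv["p0"]))

  rs <- conditional_rates(config$marginal_rates[["sporophyte_presence"]],
                          config$sex_monoicous_prob,
                          config$dependence_odds[["sex_sporophyte"]])
  sporophyte <- stats::rbinom(n, 1, ifelse(monoicous == 1, rs["p1"], rs["p0"]))

  cp <- config$continuous_params
  seta <- rlnorm_moments(n, cp$seta_length[["mean"]], cp$seta_length[["sd"]])
  capsule <- rlnorm_moments(n, cp$capsule_length[["mean"]], cp$capsule_length[["sd"]])
  stem <- rlnorm_moments(n, cp$stem_length[["mean"]], cp$stem_length[["sd"]])
  leaf <- rlnorm_moments(n, cp$leaf_length[["mean"]], cp$leaf_length[["sd"]])
  spore <- rlnorm_moments(n, cp$spore_diameter[["mean"]], cp$spore_diameter[["sd"]])
  breadth_lambda <- cp$substrate_breadth[["mean"]] - 1
  breadth <- 1 + stats::rpois(n, breadth_lambda)

  # seta shape: odds of a curved seta scale with log seta length
  slope <- log(config$dependence_odds[["setalength_setashape"]])
  shape_intercept <- -slope * mean(log(seta))  # centers curved near 50%
  curved <- stats::rbinom(n, 1, stats::plogis(shape_intercept + slope * log(seta)))

  pendent <- stats::rbinom(n, 1, config$marginal_rates[["capsule_pendent"]])
  cylindric <- stats::rbinom(n, 1, config$marginal_rates[["capsule_cylindric"]])
  ellips <- stats::rbinom(n, 1, config$marginal_rates[["spore_ellipsoidal"]])
  papill <- stats::rbinom(n, 1, config$marginal_rates[["spore_papillose"]])
  proto <- stats::rbinom(n, 1, config$marginal_rates[["persistent_protonema"]])

  # threat model: z-scores taken against the true generating moments
  z_moments <- list(
    substrate_breadth = c(mean = 1 + breadth_lambda, sd = sqrt(breadth_lambda)),
    seta_length = c(mean = cp$seta_length[["mean"]], sd = cp$seta_length[["sd"]]))
  beta <- config$true_coefficients
  co <- function(nm) if (nm %in% names(beta)) beta[[nm]] else 0
  z_breadth <- (breadth - z_moments$substrate_breadth[["mean"]]) /
    z_moments$substrate_breadth[["sd"]]
  z_seta <- (seta - z_moments$seta_length[["mean"]]) / z_moments$seta_length[["sd"]]
  eta <- config$baseline_logit + co("plant_sex") * monoicous +
    co("sporophyte_presence") * sporophyte +
    co("substrate_breadth") * z_breadth + co("seta_length") * z_seta
  p_threat <- stats::plogis(eta)
  if (mean(p_threat) > 0.95) {
    warning("degenerate config: nearly all species expected threatened",
            call. = FALSE)
  }
  threatened <- stats::rbinom(n, 1, p_threat)

  masked <- stats::rbinom(n, 1, config$sporophyte_missing_rate) == 1
  breadth_missing <- stats::rbinom(n, 1, config$breadth_missing_rate) == 1

  complete <- data.frame(
    species = sprintf("synthsp_%04d", seq_len(n)),
    iucn_category = ifelse(threatened == 1, "EN", "LC"),
    plant_sex = ifelse(monoicous == 1, "monoicous", "dioicous"),
    sporophyte_presence = ifelse(sporophyte == 1, "present", "absent"),
    vegetative_reproduction = ifelse(vegetative == 1, "present", "absent"),
    capsule_length = capsule,
    capsule_shape = ifelse(cylindric == 1, "cylindric", "ovoid"),
    capsule_on_seta = ifelse(pendent == 1, "pendent", "erect"),
    seta_length = seta,
    seta_shape = ifelse(curved == 1, "curved", "straight"),
    spore_diameter = spore,
    spore_shape = ifelse(ellips == 1, "ellipsoidal", "spherical"),
    spore_ornamentation = ifelse(papill == 1, "papillose", "smooth"),
    persistent_protonema = ifelse(proto == 1, "present", "absent"),
    leaf_length = leaf,
    stem_length = stem,
    substrate_breadth = as.numeric(breadth),
    stringsAsFactors = FALSE
  )
  complete$threat_probability <- p_threat
  complete$sporophyte_block_masked <- masked
  complete$breadth_masked <- breadth_missing

  visible <- complete[setdiff(names(complete),
                              c("threat_probability", "sporophyte_block_masked",
                                "breadth_masked"))]
  morph <- sporophyte_morphology_traits()
  hide <- masked | sporophyte == 0
  for (cl in morph) visible[[cl]][hide] <- NA
  visible$substrate_breadth[breadth_missing] <- NA

  tm <- trait_matrix(visible)
  list(matrix = tm,
       truth = list(config = config, complete_data = complete,
                    z_moments = z_moments,
                    conditional_rates = list(vegetative = rv, sporophyte = rs)))
}

#' Mask a random subset of species as Data Deficient
#'
#' Rewrites the IUCN category of a random subset of records to DD,
#' producing a triage prediction set with known true statuses (kept in the
#' returned truth table) for verdict-validation experiments.
#'
#' @param tm A [trait_matrix()].
#' @param fraction Fraction of records to mask, in (0, 1).
#' @param seed Integer seed.
#' @return List with `matrix` (statuses masked) and `truth` (data frame
#'   `species`, `true_category`, `true_status` for the masked records).
#' @export
make_dd_holdout <- function(tm, fraction, seed = 1) {
  stopifnot(inherits(tm, "trait_matrix"), fraction > 0, fraction < 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- nrow(tm$data)
  k <- stats::rbinom(1, n, fraction)
  if (k == 0) {
    warning("fraction too small: no records selected for the DD holdout",
            call. = FALSE)
    return(list(matrix = tm,
                truth = data.frame(species = character(),
                                   true_category = character(),
                                   true_status = character())))
  }
  idx <- sample.int(n, k)
  truth <- data.frame(species = tm$data$species[idx],
                      true_category = tm$data$iucn_category[idx],
                      true_status = tm$data$threat_status[idx],
                      stringsAsFactors = FALSE)
  tm$data$iucn_category[idx] <- "DD"
  tm$data$threat_status[idx] <- "DD"
  list(matrix = tm, truth = truth)
}
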