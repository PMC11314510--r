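# Build the single-column design for one trait: continuous traits enter as
# z-scores (estimated from non-DD records unless already scaled), binary and
# categorical traits as factors with the registry's first attribute as the
# reference level. Returns NULL when the trait has a single observed level.
trait_design_column <- function(tm, trait, rows) {
  kind <- registry_kind(tm$registry, trait)
  x <- tm$data[[trait]][rows]
  if (kind == "continuous") {
    if (!trait %in% names(tm$scaling)) {
      use <- x[!is.na(x)]
      if (length(unique(use)) < 2) return(NULL)
      x <- (x - mean(use)) / stats::sd(use)
    }
    if (length(unique(x[!is.na(x)])) < 2) return(NULL)
    return(x)
  }
  levels <- if (kind == "binary") c("absent", "present")
            else registry_attributes(tm$registry, trait)
  f <- factor(x, levels = levels)
  if (length(unique(f[!is.na(f)])) < 2) return(NULL)
  f
}

#' Univariate trait screening against threat status
#'
#' Fits one binary logistic model per registered trait
#' (`threat ~ trait`) on the non-DD records, continuous traits entered as
#' z-scores and categorical traits with the registry's first attribute as
#' the reference level. This is the first-pass filter that decides which
#' traits enter the maximal models.
#'
#' No multiple-testing correction is applied across the screens.
#'
#' @param tm A [trait_matrix()] with binarized statuses.
#' @param alpha Significance level for the `significant` flag (default
#'   0.05).
#' @return Data frame of class `screen_result`, one row per registry trait
#'   present in the matrix (registry order): `trait`, `level` (the
#'   non-reference level the estimate refers to), `estimate`, `ci_low`,
#'   `ci_high`, `p_value`, `significant`, `n_used`, `estimable`. The
#'   `alpha` used is stored as an attribute.
#' @export
screen_traits <- function(tm, alpha = 0.05) {
  stopifnot(inherits(tm, "trait_matrix"), alpha > 0, alpha < 1)
  rows <- which(tm$data$threat_status != "DD")
  y <- as.numeric(tm$data$threat_status[rows])
  traits <- intersect(tm$registry$name, names(tm$data))
  res <- lapply(traits, function(trait) {
    blank <- data.frame(trait = trait, level = NA_character_,
                        estimate = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_value = NA_real_,
                        significant = FALSE, n_used = NA_integer_,
                        estimable = FALSE, stringsAsFactors = FALSE)
    x <- trait_design_column(tm, trait, rows)
    if (is.null(x)) return(blank)
    fit <- tryCatch(fit_logistic(y, data.frame(x = x)),
                    error = function(e) NULL)
    if (is.null(fit) || length(fit$coefficients) < 2) return(blank)
    ci <- wald_ci(fit, 1 - alpha)
    lev <- if (is.factor(x)) levels(x)[nlevels(x)] else "per SD"
    data.frame(trait = trait, level = lev,
               estimate = unname(fit$coefficients[2]),
               ci_low = ci$low[2], ci_high = ci$high[2],
               p_value = unname(fit$p_values[2]),
               significant = unname(fit$p_values[2]) < alpha,
               n_used = fit$n, estimable = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "alpha") <- alpha
  class(out) <- c("screen_result", class(out))
  out
}

#' Trait-trait association screening
#'
#' Tests the trait pairs whose dependence would distort a joint model:
#' binary/categorical pairs by Pearson's chi-squared (no continuity
#' correction), binary-continuous pairs by a logistic fit of the binary
#' trait on the natural log of the continuous one.
#'
#' @param tm A [trait_matrix()].
#' @param pairs List of 2-element character vectors; default
#'   `plant_sex ~ vegetative_reproduction`,
#'   `plant_sex ~ sporophyte_presence` and
#'   `seta_length ~ seta_shape`.
#' @param alpha Significance level for the `significant` flag.
#' @return Data frame: `trait_a`, `trait_b`, `type`
#'   (`"chisq"`/`"logit_log"`), `statistic`, `df`, `estimate` (slope, for
#'   logit fits), `p_value`, `significant`.
#' @export
screen_trait_pairs <- function(tm,
                               pairs = list(
                                 c("plant_sex", "vegetative_reproduction"),
                                 c("plant_sex", "sporophyte_presence"),
                                 c("seta_length", "seta_shape")),
                               alpha = 0.05) {
  stopifnot(inherits(tm, "trait_matrix"))
  rows <- which(tm$data$threat_status != "DD")
  res <- lapply(pairs, function(pr) {
    kinds <- vapply(pr, function(t) registry_kind(tm$registry, t), "")
    if (all(kinds != "continuous")) {
      ct <- chisq_association(tm$data[[pr[1]]][rows], tm$data[[pr[2]]][rows])
      data.frame(trait_a = pr[1], trait_b = pr[2], type = "chisq",
                 statistic = ct$statistic, df = ct$df, estimate = NA_real_,
                 p_value = ct$p_value, significant = ct$p_value < alpha,
                 stringsAsFactors = FALSE)
    } else {
      cont <- pr[kinds == "continuous"]
      bin <- pr[kinds != "continuous"]
      if (length(cont) != 1 || length(bin) != 1) {
        stop("pair must be binary-binary or binary-continuous: ",
             paste(pr, collapse = " ~ "), call. = FALSE)
      }
      x <- tm$data[[cont]][rows]
      if (cont %in% names(tm$scaling)) {  # log needs raw units, not z-scores
        p <- tm$scaling[[cont]]
        x <- x * p[["sd"]] + p[["mean"]]
      }
      if (any(x[!is.na(x)] <= 0)) {
        stop("non-positive values in '", cont, "' under log transform",
             call. = FALSE)
      }
      lv <- if (registry_kind(tm$registry, bin) == "binary")
        c("absent", "present") else registry_attributes(tm$registry, bin)
      yb <- as.numeric(factor(tm$data[[bin]][rows], levels = lv)) - 1
      fit <- fit_logistic(yb, data.frame(logx = log(x)))
      data.frame(trait_a = pr[1], trait_b = pr[2], type = "logit_log",
                 statistic = unname(fit$z_values[2]), df = NA_integer_,
                 estimate = unname(fit$coefficients[2]),
                 p_value = unname(fit$p_values[2]),
                 significant = unname(fit$p_values[2]) < alpha,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, res)
}
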