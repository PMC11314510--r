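#' Build the two maximal model specifications
#'
#' Species descriptions record sporophyte morphology only for
#' sporophyte-bearing specimens, so a single joint model would discard
#' every sporophyte-lacking species. Two maximal models are therefore
#' specified from the screening results: model M1 takes the significant
#' non-sporophyte-morphology traits plus the binary sporophyte-presence
#' trait, and can score every species; model M2 takes all significant
#' traits except sporophyte presence, restricted to species with recorded
#' sporophyte morphology. Traits whose association screening shows them to
#' be proxies of another candidate (a binary trait significantly predicted
#' by a continuous candidate, such as seta shape by seta length) are
#' excluded from M2 with a recorded reason.
#'
#' @param screen A [screen_traits()] result.
#' @param pair_results A [screen_trait_pairs()] result, or `NULL` to skip
#'   correlation-based exclusions.
#' @return List of two `model_spec` objects (`M1`, `M2`), each a list with
#'   `model_id`, `candidates` (registry order) and `forced_exclusions`
#'   (named character vector of reasons).
#' @export
build_maximal_models <- function(screen, pair_results = NULL) {
  sig <- screen$trait[which(screen$significant)]
  if (!length(sig)) {
    warning("no significant traits: both specs are intercept-only",
            call. = FALSE)
  }
  morph <- sporophyte_morphology_traits()

  excl <- character()
  if (!is.null(pair_results)) {
    proxy <- pair_results[pair_results$type == "logit_log" &
                            pair_results$significant, , drop = FALSE]
    reg <- moss_trait_registry()
    for (i in seq_len(nrow(proxy))) {
      pr <- unlist(proxy[i, c("trait_a", "trait_b")])
      kinds <- vapply(pr, function(t) registry_kind(reg, t), "")
      # the non-continuous member of a logit_log pair is the proxy to drop
      binary_member <- pr[[which(kinds != "continuous")[1]]]
      other <- setdiff(pr, binary_member)
      excl[binary_member] <- paste0("association with ", other,
                                    " (p = ", signif(proxy$p_value[i], 2), ")")
    }
  }

  m1 <- setdiff(sig, morph)
  if (!"sporophyte_presence" %in% m1 &&
      "sporophyte_presence" %in% screen$trait) {
    m1 <- c(m1, "sporophyte_presence")
  }
  m2 <- setdiff(sig, c("sporophyte_presence", names(excl)))
  reg_order <- function(x) x[order(match(x, moss_trait_registry()$name))]
  if (!length(setdiff(m2, setdiff(m1, "sporophyte_presence")))) {
    warning("M2 candidates add no sporophyte-morphology traits over M1",
            call. = FALSE)
  }
  list(
    M1 = structure(list(model_id = "M1", candidates = reg_order(m1),
                        forced_exclusions = character()),
                   class = "model_spec"),
    M2 = structure(list(model_id = "M2", candidates = reg_order(m2),
                        forced_exclusions = excl),
                   class = "model_spec")
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Maximal model ", x$model_id, ": ",
      if (length(x$candidates)) paste(x$candidates, collapse = " + ")
      else "(intercept only)", "\n", sep = "")
  if (length(x$forced_exclusions)) {
    cat("  excluded: ",
        paste(names(x$forced_exclusions), x$forced_exclusions,
              sep = " - ", collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}

# Assemble response + design for a spec on the complete-case subset.
spec_model_frame <- function(spec, tm) {
  rows <- which(tm$data$threat_status != "DD")
  design <- list()
  for (trait in spec$candidates) {
    col <- trait_design_column(tm, trait, rows)
    if (is.null(col)) next  # constant trait cannot enter
    design[[trait]] <- col
  }
  df <- if (length(design)) as.data.frame(design) else
    data.frame(row.names = seq_along(rows))
  y <- as.numeric(tm$data$threat_status[rows])
  keep <- stats::complete.cases(df) & !is.na(y)
  list(y = y[keep], design = df[keep, , drop = FALSE],
       n_dropped = sum(!keep))
}

#' Forward stepwise AIC selection of a minimum adequate model
#'
#' Starting from the intercept-only model on the complete-case subset for
#' the spec's candidates, each step fits all one-predictor extensions and
#' adds the candidate with the lowest AIC provided it strictly improves the
#' current AIC; selection stops otherwise. AIC ties are broken by candidate
#' order in the spec (registry order), making selection deterministic.
#' Candidates that trigger separation are skipped with a warning.
#'
#' @param spec A `model_spec` from [build_maximal_models()].
#' @param tm A [trait_matrix()].
#' @return A `mam_result`: list with `model_id`, `selected_predictors`,
#'   `fit` (the final [fit_logistic()] on the selected set), `trace` (data
#'   frame of step, candidate added, AIC; AIC strictly decreases) and `n`
#'   (complete-case records used).
#' @export
stepwise_forward_aic <- function(spec, tm) {
  stopifnot(inherits(spec, "model_spec"), inherits(tm, "trait_matrix"))
  mf <- spec_model_frame(spec, tm)
  if (!length(mf$y) || length(unique(mf$y)) < 2) {
    stop("complete-case subset lacks both classes", call. = FALSE)
  }
  candidates <- names(mf$design)
  selected <- character()
  current <- fit_logistic(mf$y, data.frame())
  trace <- data.frame(step = 0L, added = "(intercept)", aic = current$aic,
                      stringsAsFactors = FALSE)
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    aics <- vapply(remaining, function(cand) {
      f <- tryCatch(
        fit_logistic(mf$y, mf$design[c(selected, cand)]),
        mossrisk_separation = function(e) {
          warning("candidate '", cand, "' skipped: ", conditionMessage(e),
                  call. = FALSE)
          NULL
        },
        error = function(e) NULL)
      if (is.null(f)) Inf else f$aic
    }, numeric(1))
    best <- which(aics < current$aic - 0)  # strict improvement
    if (!length(best)) break
    # lowest AIC; ties broken by candidate order (order of `remaining`)
    pick <- remaining[which.min(aics)]
    selected <- c(selected, pick)
    current <- fit_logistic(mf$y, mf$design[selected])
    trace <- rbind(trace, data.frame(step = nrow(trace), added = pick,
                                     aic = current$aic))
  }
  structure(list(model_id = spec$model_id, selected_predictors = selected,
                 fit = current, trace = trace, n = length(mf$y),
                 design = mf$design),
            class = "mam_result")
}

#' @export
print.mam_result <- function(x, ...) {
  cat("Minimum adequate model ", x$model_id, " (n = ", x$n, ")\n", sep = "")
  cat("  selected: ",
      if (length(x$selected_predictors))
        paste(x$selected_predictors, collapse = " + ") else "(intercept only)",
      "\n  AIC = ", round(x$fit$aic, 2), "\n", sep = "")
  invisible(x)
}

#' Coefficient table for a minimum adequate model
#'
#' @param mam A `mam_result`.
#' @param level Confidence level for the half-width column.
#' @return Data frame in the published layout: term, estimate, 95% CI
#'   half-width, z and p.
#' @export
mam_coefficient_table <- function(mam, level = 0.95) {
  ci <- wald_ci(mam$fit, level)
  data.frame(term = mam$fit$predictor_names,
             estimate = unname(mam$fit$coefficients),
             ci_half_width = ci$half_width,
             z_value = unname(mam$fit$z_values),
             p_value = unname(mam$fit$p_values),
             row.names = NULL)
}
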