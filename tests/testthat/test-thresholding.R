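test_that("ROC points match hand counts and behave at the extremes", {
  scores <- c(0.9, 0.8, 0.4, 0.2)
  labels <- c(1, 0, 1, 0)
  roc <- roc_curve(scores, labels)
  at <- function(t) roc[roc$threshold == t, ]
  expect_equal(at(0.4)$sensitivity, 1.0)
  expect_equal(at(0.4)$specificity, 0.5)
  expect_equal(at(0)$sensitivity, 1)
  expect_equal(at(1)$sensitivity, 0)

  sep <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_true(any(sep$sensitivity == 1 & sep$specificity == 1))

  expect_error(roc_curve(scores, c(1, 1, 1, 1)), "both classes")

  # every emitted point recomputable from its confusion matrix
  set.seed(40)
  s <- runif(50); l <- rbinom(50, 1, 0.4)
  r <- roc_curve(s, l)
  for (i in sample(nrow(r), 10)) {
    t <- r$threshold[i]
    expect_equal(r$sensitivity[i], sum(s >= t & l == 1) / sum(l == 1))
    expect_equal(r$specificity[i], sum(s < t & l == 0) / sum(l == 0))
  }
})

test_that("trapezoidal AUC equals brute-force pair concordance, including ties", {
  expect_equal(auc_trapezoid(roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))), 1)
  expect_equal(auc_trapezoid(roc_curve(rep(0.5, 10), rep(c(0, 1), 5))), 0.5)
  roc <- roc_curve(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0))
  expect_equal(auc_trapezoid(roc), 0.75)

  set.seed(41)
  for (r in 1:25) {
    s <- round(runif(40), 2)  # rounding forces ties
    l <- rbinom(40, 1, 0.5)
    if (length(unique(l)) < 2) next
    expect_lt(abs(auc_trapezoid(roc_curve(s, l)) -
                    mossrisk:::auc_concordance(s, l)), 1e-12)
  }

  # independent reference implementation
  set.seed(42)
  s <- runif(100); l <- rbinom(100, 1, 0.3)
  expect_equal(auc_trapezoid(roc_curve(s, l)),
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-10)
})

test_that("Index of Union ranking matches exhaustive evaluation and its tie-breaks", {
  roc <- structure(data.frame(
    threshold = c(0.1, 0.2, 0.3, 0.4, 0.5),
    sensitivity = c(0.95, 0.85, 0.70, 0.55, 0.40),
    specificity = c(0.30, 0.50, 0.70, 0.80, 0.90)),
    class = c("roc_points", "data.frame"))
  auc <- 0.70
  rk <- index_of_union(roc, auc)
  iu_brute <- abs(roc$sensitivity - auc) + abs(roc$specificity - auc)
  expect_equal(rk$iu, sort(iu_brute))
  expect_equal(rk$threshold[1], 0.3)  # Se = Sp = AUC gives IU = 0, rank 1
  expect_equal(rk$iu[1], 0)

  # equal IU, gaps 0.2 vs 0.1: the smaller |Se - Sp| gap ranks first
  # both points have IU = 0.2 against AUC 0.7; |Se - Sp| gaps 0.2 vs 0.1
  roc2 <- structure(data.frame(threshold = c(0.2, 0.4),
                               sensitivity = c(0.8, 0.75),
                               specificity = c(0.6, 0.85)),
                    class = c("roc_points", "data.frame"))
  rk2 <- index_of_union(roc2, auc = 0.7)
  expect_equal(rk2$iu[1], rk2$iu[2])
  expect_equal(rk2$threshold[1], 0.4)
})

test_that("cutoff selection keeps the IU optimum when sensitive enough, otherwise walks the ranking", {
  mk <- function(th, se, sp) {
    r <- data.frame(rank = seq_along(th), threshold = th, iu = seq_along(th),
                    sensitivity = se, specificity = sp)
    attr(r, "auc") <- 0.71
    r
  }
  # IU optimum too insensitive: walk to the third-ranked cutoff
  walk <- select_cutoff(mk(c(0.30, 0.27, 0.21), c(0.53, 0.62, 0.75),
                           c(0.74, 0.68, 0.51)), 0.70)
  expect_equal(walk$chosen_cutoff, 0.21)
  expect_equal(walk$rule_applied, "sensitivity_override")
  expect_equal(walk$rank, 3L)

  # IU optimum already sensitive enough: accepted as is
  keep <- select_cutoff(mk(0.18, 0.75, 0.62), 0.70)
  expect_equal(keep$chosen_cutoff, 0.18)
  expect_equal(keep$rule_applied, "iu_optimal")

  # nothing qualifies: rank-1 fallback with a warning
  expect_warning(fb <- select_cutoff(mk(c(0.5, 0.4), c(0.3, 0.5),
                                        c(0.9, 0.8)), 0.70),
                 "no cutoff")
  expect_equal(fb$chosen_cutoff, 0.5)

  # never skips a higher-ranked qualifying cutoff
  sel <- select_cutoff(mk(c(0.3, 0.25, 0.2), c(0.72, 0.80, 0.90),
                          c(0.7, 0.6, 0.5)), 0.70)
  expect_equal(sel$rank, 1L)
})

test_that("two-graph ROC curves are monotone and the crossing is interpolated", {
  set.seed(43)
  s <- runif(80); l <- rbinom(80, 1, 0.4)
  roc <- roc_curve(s, l)
  tg <- two_graph_roc(roc)
  se <- tg$value[tg$curve == "sensitivity"]
  sp <- tg$value[tg$curve == "specificity"]
  expect_true(all(diff(se) <= 0))
  expect_true(all(diff(sp) >= 0))

  roc3 <- structure(data.frame(threshold = c(0, 0.5, 1),
                               sensitivity = c(1, 0.4, 0),
                               specificity = c(0, 0.6, 1)),
                    class = c("roc_points", "data.frame"))
  # linear interpolation between (0, +1) and (0.5, -0.2): crossing at 5/12
  expect_equal(attr(two_graph_roc(roc3), "crossing"), 0.5 * (1 / 1.2))

  roc2 <- structure(data.frame(threshold = c(0, 1), sensitivity = c(1, 1),
                               specificity = c(0, 0)),
                    class = c("roc_points", "data.frame"))
  tg2 <- two_graph_roc(roc2)
  expect_equal(nrow(tg2), 4)
  expect_true(is.na(attr(tg2, "crossing")))
})
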