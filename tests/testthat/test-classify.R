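# Decision rules (banded single-variable and two-stage mixed), threshold
# fitting, and confusion-table evaluation.

test_that("the banded rule honours inclusive boundaries", {
  r0 <- threshold_rule("PP_avg", 0, 0)
  expect_identical(classify_single(c(0, -0.001), r0), c("excess", "deficient"))

  # the published fitted criteria: the band is [beta, alpha)
  r <- threshold_rule("PP_avg", -0.216, -0.572)
  expect_identical(classify_single(-0.4, r), "intermediate")
  expect_identical(classify_single(-0.216, r), "excess")
  expect_identical(classify_single(-0.5721, r), "deficient")
  expect_identical(classify_single(-0.572, r), "intermediate")

  expect_error(threshold_rule("x", -1, 0), "alpha")
})

test_that("the mixed model resolves the intermediate band with the secondary", {
  m <- mixed_threshold_model(threshold_rule("PP_avg", -0.216, -0.572),
                             threshold_rule("PP_max", -0.314, -0.314))
  # primary decides outside the band regardless of the secondary
  expect_identical(classify_mixed(0.5, -5, m), "excess")
  expect_identical(classify_mixed(-3, 5, m), "deficient")
  # inside the band the secondary's gamma = delta = -0.314 rule decides
  expect_identical(classify_mixed(-0.4, -0.2, m), "excess")
  expect_identical(classify_mixed(-0.4, -0.314, m), "excess")  # inclusive
  expect_identical(classify_mixed(-0.4, -0.4, m), "deficient")

  # degenerate reduction: alpha = beta and gamma = delta = anything
  md <- mixed_threshold_model(threshold_rule("PP_avg", 0.1, 0.1),
                              threshold_rule("PP_max", 0, 0))
  z <- seq(-2, 2, by = 0.05)
  expect_identical(classify_mixed(z, -z, md),
                   ifelse(classify_single(z, md$primary) == "excess",
                          "excess", "deficient"))

  # a banded secondary needs an explicit tie-break policy
  expect_error(mixed_threshold_model(threshold_rule("a", 0, -1),
                                     threshold_rule("b", 0.5, -0.5)),
               "tie")
  mt <- mixed_threshold_model(threshold_rule("a", 0, -1),
                              threshold_rule("b", 0.5, -0.5),
                              tie_break = "midpoint")
  expect_identical(classify_mixed(-0.5, 0.1, mt), "excess")   # >= midpoint 0
  expect_identical(classify_mixed(-0.5, -0.1, mt), "deficient")
})

test_that("every input receives a label when gamma equals delta", {
  m <- mixed_threshold_model(threshold_rule("p", 0.8, -0.9),
                             threshold_rule("s", -0.2, -0.2))
  set.seed(21)
  z1 <- stats::rnorm(500); z2 <- stats::rnorm(500)
  lab <- classify_mixed(z1, z2, m)
  expect_true(all(lab %in% c("deficient", "excess")))
})

test_that("threshold fitting separates separable data exactly", {
  z <- c(-3, -2.5, -2, 2, 2.5, 3)
  y <- rep(c("deficient", "excess"), each = 3)
  m <- fit_thresholds(z, stats::rnorm(6), y)
  expect_equal(attr(m, "train_accuracy"), 1)
  expect_equal(m$primary$alpha, m$primary$beta)  # smallest band tie-break
  expect_gt(m$primary$alpha, -2); expect_lte(m$primary$alpha, 2)
})

test_that("the mixed search always contains the single-threshold optimum", {
  # search-space nesting: alpha = beta is in the grid, so the fitted mixed
  # model is never worse on the training data; verified against a brute-force
  # single-threshold search on small cohorts
  set.seed(33)
  for (i in 1:20) {
    n <- 24
    y <- sample(rep(c("deficient", "excess"), n / 2))
    z1 <- stats::rnorm(n) + (y == "excess") * 1.2
    z2 <- stats::rnorm(n) + (y == "excess") * 0.8
    mixed <- fit_thresholds(z1, z2, y)
    # brute force over every single cutpoint on the primary
    cuts <- c(-Inf, sort(z1), Inf)
    accs <- vapply(cuts, function(a)
      mean(ifelse(z1 >= a, "excess", "deficient") == y), numeric(1))
    expect_gte(attr(mixed, "train_accuracy") + 1e-12, max(accs))
    # never below the majority-class rate
    expect_gte(attr(mixed, "train_accuracy"), max(table(y)) / n)
  }
})

test_that("an informative secondary strictly improves a constructed cohort", {
  # primary separates the tails; the secondary is informative exactly inside
  # the primary's overlap region
  y <- rep(c("deficient", "excess"), each = 10)
  z1 <- c(seq(-3, -1.5, length.out = 5), seq(-0.5, 0.5, length.out = 5),
          seq(-0.5, 0.5, length.out = 5), seq(1.5, 3, length.out = 5))
  z2 <- c(stats::rnorm(5, 0, 0.01), rep(-1, 5), rep(1, 5), stats::rnorm(5, 0, 0.01))
  mixed <- fit_thresholds(z1, z2, y)
  cuts <- c(-Inf, sort(z1), Inf)
  best_single <- max(vapply(cuts, function(a)
    mean(ifelse(z1 >= a, "excess", "deficient") == y), numeric(1)))
  expect_gt(attr(mixed, "train_accuracy"), best_single)
  expect_equal(attr(mixed, "train_accuracy"), 1)
})

test_that("threshold fitting rejects degenerate inputs", {
  expect_error(fit_thresholds(1:5, 1:5, rep("excess", 5)), "both classes")
  expect_error(fit_threshold_single(1:5, rep("deficient", 5)), "both classes")
})

test_that("confusion tables count by (expert, predicted) and validate labels", {
  t1 <- confusion(c("deficient", "excess"), c("deficient", "excess"))
  expect_equal(sum(diag(t1)), 2)
  expect_equal(sum(t1) - sum(diag(t1)), 0)

  # rebuild the published concordance table from its counts and recover it
  truth <- rep(c("deficient", "deficient", "excess", "excess"),
               c(26, 17, 13, 44))
  pred <- rep(c("deficient", "excess", "deficient", "excess"),
              c(26, 17, 13, 44))
  tab <- confusion(truth, pred)
  expect_identical(unclass(tab)[, ],
                   unclass(confusion_from_counts(26, 17, 13, 44))[, ])

  # relabel symmetry: swapping both vectors transposes consistently
  swap <- function(x) ifelse(x == "excess", "deficient", "excess")
  tab2 <- confusion(swap(truth), swap(pred))
  expect_equal(tab2["excess", "excess"], tab["deficient", "deficient"])
  expect_equal(tab2["deficient", "excess"], tab["excess", "deficient"])

  expect_error(confusion(c("deficient", "weird"), c("excess", "excess")),
               "unknown label")
  expect_error(confusion("excess", c("excess", "excess")), "equal length")
})

test_that("accuracy and MCC follow their formulas and conventions", {
  perfect <- confusion_from_counts(10, 0, 0, 12)
  expect_equal(accuracy(perfect), 1)
  expect_equal(mcc(perfect), 1)

  # all-one-class prediction: MCC 0 by convention
  onecol <- confusion_from_counts(0, 10, 0, 12)
  expect_equal(mcc(onecol), 0)

  # symmetric under simultaneous class swap
  tab <- confusion_from_counts(20, 6, 13, 31)
  swapped <- confusion_from_counts(31, 13, 6, 20)
  expect_equal(mcc(tab), mcc(swapped), tolerance = 1e-12)

  expect_error(accuracy(confusion_from_counts(0, 0, 0, 0)), "empty")
})

test_that("MCC is bounded and near zero for uninformative predictions", {
  set.seed(41)
  vals <- replicate(200, {
    t <- confusion_from_counts(sample(0:30, 1), sample(0:30, 1),
                               sample(0:30, 1), sample(0:30, 1))
    if (sum(t) == 0) 0 else mcc(t)
  })
  expect_true(all(abs(vals) <= 1 + 1e-12))
  # random predictions independent of truth: MCC centred on 0
  mccs <- replicate(300, {
    y <- sample(c("deficient", "excess"), 60, replace = TRUE, prob = c(.4, .6))
    p <- sample(c("deficient", "excess"), 60, replace = TRUE, prob = c(.5, .5))
    mcc(confusion(y, p))
  })
  expect_lt(abs(mean(mccs)), 0.05)
})

test_that("model JSON round-trips the fitted criteria", {
  m <- mixed_threshold_model(threshold_rule("PP_avg", -0.216, -0.572),
                             threshold_rule("PP_max", -0.314, -0.314))
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path,
                   standardization = list(primary = list(center = 10, scale = 2)),
                   seed = 7)
  back <- read_model_json(path)
  expect_equal(back$primary$alpha, -0.216)
  expect_equal(back$primary$beta, -0.572)
  expect_equal(back$secondary$alpha, -0.314)
  expect_identical(back$primary$variable, "PP_avg")
  expect_equal(attr(back, "standardization")$primary$center, 10)
})
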