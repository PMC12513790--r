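test_that("the evidence ladder follows the odds-of-pathogenicity algebra", {
  # even prior: very strong odds are just the posterior odds
  expect_equal(evidence_ladder(0.5, 0.99)$op_vs, 99)
  lad <- evidence_ladder(0.1, 0.99)
  expect_equal(lad$op_vs, 891)
  expect_equal(unname(lad$pathogenic["supporting"]), 891^(1 / 8))
  expect_equal(unname(lad$pathogenic["supporting"]), 2.337, tolerance = 1e-3)
  expect_equal(unname(lad$pathogenic["moderate"]), 5.464, tolerance = 1e-3)
  expect_equal(unname(lad$pathogenic["strong"]), 29.850, tolerance = 1e-4)
  expect_equal(unname(lad$benign["supporting"]), 1 / 2.337, tolerance = 1e-3)
})

test_that("successive squaring connects the ladder levels exactly", {
  for (prior in c(0.04, 0.1, 0.44)) {
    lad <- evidence_ladder(prior)
    p <- lad$pathogenic
    expect_equal(unname(p["supporting"])^2, unname(p["moderate"]))
    expect_equal(unname(p["moderate"])^2, unname(p["strong"]))
    expect_equal(unname(p["strong"])^2, unname(p["very_strong"]))
    expect_equal(unname(p["supporting"])^8, lad$op_vs, tolerance = 1e-9)
    expect_equal(unname(lad$benign), unname(1 / p))
  }
  expect_error(evidence_ladder(0), "prior")
  expect_error(evidence_ladder(0.5, 0.3), "posterior_vs")
})

test_that("identical reference sets give a flat likelihood ratio of 1", {
  withr::with_seed(4, x <- rnorm(100))
  model <- fit_lr_curve(x, x, n_boot = 50, seed = 2)
  expect_true(all(abs(model$lr - 1) < 1e-12))
  # paired bootstrap index streams make every resampled ratio 1 as well
  expect_true(all(model$lr_lo <= 1 + 1e-12 & model$lr_hi >= 1 - 1e-12))
})

test_that("the KDE ratio recovers the analytic two-Gaussian likelihood ratio", {
  withr::with_seed(6, {
    p <- rnorm(2000, 2, 1)
    b <- rnorm(2000, 0, 1)
  })
  model <- fit_lr_curve(p, b, n_boot = 100, seed = 9)
  at <- predict_lr(model, c(0, 1, 2))
  truth <- exp(2 * c(0, 1, 2) - 2)
  expect_true(all(at$lr / truth < 1.5 & at$lr / truth > 1 / 1.5))
  # the band brackets the point estimate
  expect_true(all(at$lr_lo <= at$lr & at$lr <= at$lr_hi))
})

test_that("reference floors and degenerate inputs are rejected", {
  expect_error(fit_lr_curve(rnorm(5), rnorm(100)), "at least 10")
  expect_error(fit_lr_curve(rnorm(100), rnorm(3)), "at least 10")
})

test_that("scores beyond the reference span clamp to the boundary ratio", {
  withr::with_seed(13, {
    p <- rnorm(200, 2)
    b <- rnorm(200, 0)
  })
  model <- fit_lr_curve(p, b, n_boot = 50, seed = 5)
  out <- predict_lr(model, c(model$span[1] - 10, model$span[2] + 10))
  expect_true(all(out$clamped))
  expect_equal(out$lr[1], model$lr[1])
  expect_equal(out$lr[2], model$lr[length(model$lr)])
})

fake_lr_model <- function(lr_value, lo = lr_value, hi = lr_value) {
  structure(list(predictor = "toy", orientation = "higher_pathogenic",
                 grid = c(0, 1), lr = rep(lr_value, 2),
                 lr_lo = rep(lo, 2), lr_hi = rep(hi, 2), span = c(0, 1),
                 bandwidth = "nrd0", n_boot = 0, band = c(0.05, 0.95),
                 seed = 1, lr_ceiling = 1e6, n_path = 10, n_benign = 10),
            class = "LrModel")
}

test_that("classification looks up the ladder exactly as specified", {
  lad <- evidence_ladder(0.1, 0.99)
  sc <- data.frame(variant = "p.A1V", score = 0.5)
  expect_equal(as.character(classify_variants(fake_lr_model(1), lad, sc)$level),
               "indeterminate")
  # lr 10 sits between the moderate (5.464) and strong (29.85) thresholds
  expect_equal(as.character(classify_variants(fake_lr_model(10), lad, sc)$level),
               "PP3_moderate")
  # lr 0.3 sits between the benign supporting (0.428) and moderate (0.183)
  expect_equal(as.character(classify_variants(fake_lr_model(0.3), lad, sc)$level),
               "BP4_supporting")
  expect_equal(as.character(classify_variants(fake_lr_model(1000), lad, sc)$level),
               "PP3_very_strong")
  # the conservative band edge drives the call, not the point estimate
  wide <- fake_lr_model(10, lo = 2, hi = 20)
  expect_equal(as.character(classify_variants(wide, lad, sc)$level),
               "indeterminate")
})

test_that("swapping the reference sets swaps PP3 and BP4 calls exactly", {
  withr::with_seed(19, {
    p <- rnorm(300, 2)
    b <- rnorm(300, 0)
    test_scores <- data.frame(variant = sprintf("v%d", 1:80),
                              score = runif(80, -2, 4))
  })
  lad <- evidence_ladder(0.1)
  m1 <- fit_lr_curve(p, b, n_boot = 200, seed = 7)
  m2 <- fit_lr_curve(b, p, n_boot = 200, seed = 7)
  c1 <- as.character(classify_variants(m1, lad, test_scores)$level)
  c2 <- as.character(classify_variants(m2, lad, test_scores)$level)
  # map PP3_x <-> BP4_x and compare
  flip <- function(x) ifelse(x == "indeterminate", x,
                             ifelse(grepl("^PP3", x),
                                    sub("PP3", "BP4", x),
                                    sub("BP4", "PP3", x)))
  expect_identical(c2, flip(c1))
})

test_that("classification is monotone given a monotone likelihood curve", {
  grid <- seq(-1, 4, length.out = 256)
  lr <- exp(2 * grid - 2)
  model <- structure(list(predictor = "toy",
                          orientation = "higher_pathogenic",
                          grid = grid, lr = lr, lr_lo = 0.8 * lr,
                          lr_hi = 1.25 * lr, span = range(grid),
                          bandwidth = "nrd0", n_boot = 0,
                          band = c(0.05, 0.95), seed = 1, lr_ceiling = 1e6,
                          n_path = 10, n_benign = 10),
                     class = "LrModel")
  s <- seq(-1, 4, length.out = 200)
  calls <- classify_variants(model, evidence_ladder(0.1),
                             data.frame(variant = sprintf("v%d", 1:200),
                                        score = s))
  lv <- as.integer(calls$level)  # ordered factor: BP4_very_strong .. PP3_very_strong
  expect_true(all(diff(lv) >= 0))
  expect_lt(min(lv), 5)  # reaches benign evidence at the low end
  expect_gt(max(lv), 5)  # and pathogenic evidence at the high end
})

test_that("pathogenic-evidence yield grows with class separation", {
  frac_supported <- vapply(c(0, 1, 2, 3), function(dmu) {
    sim <- simulate_scores(400, 400, path_mean = dmu, seed = 31 + dmu)
    sc <- as.data.frame(sim$scores)
    is_p <- sim$truth$label == "pathogenic"
    model <- fit_lr_curve(sc$score[is_p], sc$score[!is_p],
                          n_boot = 150, seed = 11)
    calls <- classify_variants(model, evidence_ladder(0.1),
                               sc[is_p, c("variant", "score")])
    mean(grepl("^PP3", calls$level))
  }, 1)
  expect_true(all(diff(frac_supported) >= 0))
  expect_lt(frac_supported[1], 0.05)
  expect_gt(frac_supported[4], 0.25)
})

test_that("call compositions sum to one per category", {
  lad <- evidence_ladder(0.1)
  calls <- rbind(classify_variants(fake_lr_model(10), lad,
                                   data.frame(variant = c("a", "b"),
                                              score = c(0.1, 0.2))),
                 classify_variants(fake_lr_model(0.3), lad,
                                   data.frame(variant = "c", score = 0.3)),
                 classify_variants(fake_lr_model(1), lad,
                                   data.frame(variant = "d", score = 0.4)))
  comp <- summarise_calls(calls, rep("toyset", 4))
  expect_equal(sum(comp$fraction), 1)
  expect_equal(comp$fraction[comp$level == "PP3_moderate"], 0.5)
  expect_equal(comp$fraction[comp$level == "BP4_supporting"], 0.25)
  expect_equal(comp$fraction[comp$level == "indeterminate"], 0.25)
  # category lookup by variant data frame
  comp2 <- summarise_calls(calls,
                           data.frame(variant = c("a", "b", "c", "d"),
                                      category = c("g1", "g1", "g2", "g2")))
  expect_equal(as.numeric(tapply(comp2$fraction, comp2$category, sum)),
               c(1, 1))
  expect_error(summarise_calls(calls,
                               data.frame(variant = "a", category = "g")),
               "no category")
})
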