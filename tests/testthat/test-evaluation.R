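test_that("metric differences reproduce hand-computed mean and RMSE", {
  p <- c(a = 13, b = 24); a <- c(a = 10, b = 20)   # differences {3, 4}
  md <- metric_differences(p, a)
  expect_equal(md$mean_difference, 3.5)
  expect_equal(md$rmse, sqrt(12.5))

  same <- metric_differences(c(a = 5, b = 7), c(a = 5, b = 7))
  expect_equal(same$mean_difference, 0)
  expect_equal(same$rmse, 0)

  sgn <- metric_differences(c(a = 0, b = 4), c(a = 2, b = 2))  # {-2, 2}
  expect_equal(sgn$mean_difference, 0)
  expect_equal(sgn$rmse, 2)

  expect_error(metric_differences(c(a = 1), c(b = 1)), class = "kbdvh_pairing_error")

  # brute-force RMSE oracle over random inputs
  set.seed(14)
  for (rep in 1:10) {
    n <- sample(2:30, 1)
    pv <- stats::setNames(rnorm(n), paste0("p", 1:n))
    av <- stats::setNames(rnorm(n), paste0("p", 1:n))
    md <- metric_differences(pv, av)
    expect_equal(md$rmse, sqrt(mean((pv - av)^2)), tolerance = 1e-12)
    expect_equal(md$mean_difference, mean(pv - av), tolerance = 1e-12)
  }
})

test_that("linear fit is exact on affine relations and flags degeneracy", {
  axis <- seq(0, 50, by = 0.1)
  vf <- pmin(1, pmax(0, 1 - axis / 50))
  a <- dvh_curve(axis, vf, "s", kind = "achieved")

  fit <- dvh_linear_fit(a, a)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  half <- dvh_curve(axis, vf * 0.5, "s", kind = "predicted")
  fit2 <- dvh_linear_fit(half, a)
  expect_equal(fit2$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit2$r_squared, 1, tolerance = 1e-12)

  # affine relations with offsets across random monotone curves
  set.seed(15)
  for (rep in 1:5) {
    v <- rev(cummax(rev(pmin(1, sort(runif(length(axis)), decreasing = TRUE)))))
    v[1] <- 1
    base <- dvh_curve(axis, v, kind = "achieved")
    aff <- dvh_curve(axis, pmin(1, pmax(0, 0.1 + 0.8 * v)), kind = "predicted")
    expect_equal(dvh_linear_fit(aff, base)$r_squared, 1, tolerance = 1e-10)
  }

  flat <- dvh_curve(axis, c(1, rep(1, length(axis) - 1)), kind = "achieved")
  expect_error(dvh_linear_fit(a, flat), class = "kbdvh_degenerate_fit_error")

  # differing axes: coarser curve interpolated onto the finer
  coarse <- dvh_curve(seq(0, 50, by = 1), pmax(0, 1 - seq(0, 50) / 50),
                      kind = "predicted")
  fit3 <- dvh_linear_fit(coarse, a)
  expect_equal(fit3$slope, 1, tolerance = 1e-9)
})

test_that("report aggregation is deterministic and order-invariant", {
  rows <- expand.grid(plan_id = c("p1", "p2"), oar_class = c("heart", "lung"),
                      metric = c("mean_gy", "V20"), stringsAsFactors = FALSE)
  set.seed(16)
  rows$achieved <- runif(nrow(rows), 5, 30)
  rows$predicted <- rows$achieved + rnorm(nrow(rows))

  axis <- seq(0, 50, by = 0.5)
  mk_curve <- function(scale, kind) dvh_curve(axis, pmax(0, 1 - axis / 50)^scale,
                                              kind = kind)
  pairs <- list(
    list(plan_id = "p1", structure = "heart",
         predicted = mk_curve(1.1, "predicted"), achieved = mk_curve(1, "achieved")),
    list(plan_id = "p2", structure = "heart",
         predicted = mk_curve(1, "predicted"), achieved = mk_curve(1, "achieved"))
  )
  rep1 <- build_report(rows, pairs)
  rep2 <- build_report(rows[sample(nrow(rows)), ], rev(pairs))
  expect_identical(rep1$metrics, rep2$metrics)
  expect_identical(rep1$fits, rep2$fits)
  expect_equal(rep1$n_plans, 2)
  expect_true(all(rep1$fits$r_squared >= 0 & rep1$fits$r_squared <= 1))

  # perfect prediction: zero means/RMSEs, unit R^2
  rows0 <- rows; rows0$predicted <- rows0$achieved
  pairs0 <- list(list(plan_id = "p1", structure = "heart",
                      predicted = mk_curve(1, "predicted"),
                      achieved = mk_curve(1, "achieved")))
  rep0 <- build_report(rows0, pairs0)
  expect_true(all(rep0$metrics$mean_difference == 0))
  expect_true(all(rep0$metrics$rmse == 0))
  expect_equal(rep0$fits$r_squared, 1, tolerance = 1e-12)

  # degenerate achieved curve reported as NA, not fatal
  flatpair <- list(list(plan_id = "p1", structure = "odd",
                        predicted = mk_curve(1, "predicted"),
                        achieved = dvh_curve(axis, rep(1, length(axis)),
                                             kind = "achieved")))
  repd <- build_report(rows, flatpair)
  expect_true(is.na(repd$fits$r_squared[1]))

  # text and CSV rendering
  d <- tempfile()
  paths <- write_report(rep1, d)
  expect_true(all(file.exists(paths)))
  txt <- readLines(paths["text"])
  expect_match(txt[1], "N = 2 plans")
  back <- read.csv(paths["metrics"])
  expect_equal(back$rmse, rep1$metrics$rmse, tolerance = 1e-6)
})
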