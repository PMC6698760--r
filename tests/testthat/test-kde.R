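test_that("reference-rule bandwidths follow h = sigma * n^(-1/6)", {
  set.seed(4)
  tt <- rnorm(1000); tt <- (tt - mean(tt)) / sd(tt) * 2.0  # sd exactly 2
  xx <- rnorm(1000, 30, 5)
  h <- fit_bandwidths(tt, xx)
  expect_equal(h$h_t, 2.0 * 1000^(-1 / 6), tolerance = 1e-12)
  expect_equal(h$h_t, 0.6325, tolerance = 1e-4)
  expect_equal(h$h_x, sd(xx) * 1000^(-1 / 6), tolerance = 1e-12)

  # scale equivariance: scaling t by c scales h_t by exactly c
  h3 <- fit_bandwidths(tt * 3.5, xx)
  expect_equal(h3$h_t, 3.5 * h$h_t, tolerance = 1e-12)
  expect_equal(h3$h_x, h$h_x, tolerance = 1e-12)

  expect_error(fit_bandwidths(1, 1), class = "kbdvh_degenerate_training_error")
  expect_error(fit_bandwidths(rep(1, 10), rnorm(10)),
               class = "kbdvh_degenerate_training_error")
  expect_error(fit_bandwidths(rnorm(10), rep(2, 10)),
               class = "kbdvh_degenerate_training_error")
  # the error names the offending coordinate
  expect_match(tryCatch(fit_bandwidths(rep(1, 10), rnorm(10)),
                        error = conditionMessage), "coordinate t")
})

test_that("LSCV bandwidths are finite, positive, and scale-consistent", {
  set.seed(5)
  tt <- rnorm(300, 0, 5); xx <- rnorm(300, 20, 4)
  h <- fit_bandwidths(tt, xx, method = "lscv")
  expect_true(h$h_t > 0 && h$h_x > 0 && is.finite(h$h_t) && is.finite(h$h_x))
  # for Gaussian data LSCV should land within a factor ~3 of the reference rule
  href <- fit_bandwidths(tt, xx)
  expect_lt(abs(log(h$h_t / href$h_t)), log(3))
  expect_lt(abs(log(h$h_x / href$h_x)), log(3))
})

test_that("conditional density matches the literal double kernel sum", {
  mdl <- toy_model(n = 150)
  axis <- kde_dose_axis(mdl)
  for (tq in c(-8, 0, 10, 25, 39)) {
    expect_lt(max(abs(conditional_density(mdl, tq, axis) -
                      brute_force_conditional(mdl, tq, axis))), 1e-9)
  }
  # far outside the training range: clamped, not zero
  d_far <- conditional_density(mdl, 1e5, axis)
  d_edge <- conditional_density(mdl, max(mdl$train_t), axis)
  expect_equal(d_far, d_edge, tolerance = 1e-12)
})

test_that("degenerate conditional cases behave as closed forms dictate", {
  axis <- seq(0, 60, by = 0.05)
  # all mass at one dose: a Gaussian centered there, for any query t
  one <- kde_model("one", c(5, 5), c(30, 30), h_t = 1, h_x = 1.5, x_max = 60)
  d <- conditional_density(one, -3, axis)
  expect_equal(d, dnorm(axis, 30, 1.5) + dnorm(-axis, 30, 1.5), tolerance = 1e-12)
  expect_equal(kbdvh:::trapz(axis, d), 1, tolerance = 1e-6)

  # pairs {(0,10),(0,20)}: symmetric about 15 Gy
  sym <- kde_model("sym", c(0, 0), c(10, 20), h_t = 1, h_x = 1, x_max = 60)
  ds <- conditional_density(sym, 0, axis)
  expect_equal(ds[axis == 10], ds[axis == 20], tolerance = 1e-12)
  i15 <- which(axis == 15)
  expect_equal(ds[i15 - 40], ds[i15 + 40], tolerance = 1e-10)
})

test_that("marginalized prediction equals the average of conditionals", {
  mdl <- toy_model(n = 100)
  # all query distances equal: identical to the conditional at that t
  pd <- predict_dose_density(mdl, rep(12, 50), dx = 0.1)
  cd <- conditional_density(mdl, 12, pd$dose_axis)
  expect_equal(pd$density, cd / kbdvh:::trapz(pd$dose_axis, cd), tolerance = 1e-12)

  # two distances: pointwise arithmetic mean of the two conditionals
  pd2 <- predict_dose_density(mdl, c(0, 20), dx = 0.1)
  m2 <- (conditional_density(mdl, 0, pd2$dose_axis) +
         conditional_density(mdl, 20, pd2$dose_axis)) / 2
  expect_equal(pd2$density, m2 / kbdvh:::trapz(pd2$dose_axis, m2), tolerance = 1e-12)

  # many arbitrary (tied and untied) distances vs the naive average
  set.seed(8)
  q <- c(rnorm(40, 15, 12), rep(3, 10))
  pd3 <- predict_dose_density(mdl, q, dx = 0.1)
  naive <- rowMeans(vapply(q, function(tq)
    brute_force_conditional(mdl, tq, pd3$dose_axis),
    numeric(length(pd3$dose_axis))))
  naive <- naive / kbdvh:::trapz(pd3$dose_axis, naive)
  expect_lt(max(abs(pd3$density - naive)), 1e-9)

  expect_equal(kbdvh:::trapz(pd3$dose_axis, pd3$density), 1, tolerance = 1e-9)
  expect_error(predict_dose_density(mdl, numeric(0)),
               class = "kbdvh_model_input_error")
})

test_that("training pools plans, records counts, and is deterministic", {
  set.seed(9)
  mk <- function(n, id) distance_dose_samples("lung", rnorm(n, 20, 8),
                                              pmax(0, rnorm(n, 15, 6)),
                                              plan_id = id)
  m <- train_model(list(mk(100, "a"), mk(100, "b")))
  expect_length(m$train_t, 200)
  expect_equal(m$n_train_plans, 2L)
  expect_equal(m$dose_domain[2], ceiling(max(m$train_x) * 1.1 / 0.1) * 0.1)
  expect_gte(m$dose_domain[2], max(m$train_x))

  # identical inputs -> byte-identical serialized model
  p1 <- tempfile(); p2 <- tempfile()
  s <- mk(50, "a")
  write_kde_model(train_model(list(s)), p1)
  write_kde_model(train_model(list(s)), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)), readBin(p2, "raw", file.size(p2)))

  expect_error(train_model(list()), class = "kbdvh_model_input_error")
  zero <- distance_dose_samples("z", rnorm(10), rep(0, 10))
  expect_error(train_model(list(zero)), class = "kbdvh_degenerate_training_error")
})

test_that("permutation of training pairs changes nothing beyond round-off", {
  mdl <- toy_model(n = 80)
  set.seed(10)
  perm <- sample(80)
  mdl2 <- kde_model(mdl$oar_class, mdl$train_t[perm], mdl$train_x[perm],
                    mdl$h_t, mdl$h_x, x_max = mdl$dose_domain[2])
  axis <- kde_dose_axis(mdl)
  expect_equal(conditional_density(mdl2, 7, axis),
               conditional_density(mdl, 7, axis), tolerance = 1e-12)
  q <- runif(30, -5, 30)
  expect_equal(predict_dose_density(mdl2, q)$density,
               predict_dose_density(mdl, q)$density, tolerance = 1e-12)
})

test_that("model JSON round-trips and rejects foreign versions", {
  mdl <- toy_model(n = 60)
  p <- tempfile(fileext = ".json")
  write_kde_model(mdl, p)
  back <- read_kde_model(p)
  expect_equal(back$train_t, mdl$train_t)
  expect_equal(back$train_x, mdl$train_x)
  expect_equal(back$h_t, mdl$h_t)
  expect_equal(back$dose_domain, mdl$dose_domain)

  bad <- tempfile(fileext = ".json")
  writeLines('{"version":"other-9","oar_class":"x"}', bad)
  expect_error(read_kde_model(bad), class = "kbdvh_version_error")
  expect_error(read_kde_model(tempfile()), class = "kbdvh_io_error")
})

test_that("KDE estimate converges to the true conditional density", {
  mu <- function(t) 50 / (1 + exp((t - 10) / 4))
  sigma <- 2
  t0 <- 8
  axis <- seq(0, 60, by = 0.1)
  truth <- dnorm(axis, mu(t0), sigma)
  l1_for_n <- function(n, seed) {
    set.seed(seed)
    tt <- runif(n, -10, 30)
    xx <- pmax(0, rnorm(n, mu(tt), sigma))
    h <- fit_bandwidths(tt, xx)
    m <- kde_model("c", tt, xx, h$h_t, h$h_x, x_max = 60)
    kbdvh:::trapz(axis, abs(conditional_density(m, t0, axis) - truth))
  }
  meds <- vapply(c(100, 1000, 10000), function(n)
    median(vapply(1:7, function(s) l1_for_n(n, s), 0.0)), 0.0)
  expect_true(all(diff(meds) < 0))
})
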