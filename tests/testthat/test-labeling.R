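test_that("glucose discretization covers 70-250 in 180 one-mg/dL classes", {
  expect_equal(discretize_glucose(70), 0L)
  expect_equal(discretize_glucose(149.5), 79L)
  expect_equal(discretize_glucose(249.999), 179L)
  # every class is reachable and the class space has exactly 180 levels
  classes <- discretize_glucose(seq(70.5, 249.5, by = 1))
  expect_identical(classes, 0:179)
  expect_equal(length(unique(classes)), 180)
})

test_that("out-of-range values clip to boundary classes with a warning", {
  expect_warning(cls <- discretize_glucose(255), "clipped")
  expect_equal(cls, 179L)
  expect_warning(cls <- discretize_glucose(60), "clipped")
  expect_equal(cls, 0L)
  expect_error(discretize_glucose(NaN), "finite")
})

test_that("inverse mapping returns bin centres within half a bin", {
  for (cls in c(0L, 79L, 179L)) {
    centre <- class_to_glucose(cls)
    expect_equal(discretize_glucose(centre), cls)
    expect_lte(abs(centre - (70 + cls + 0.5)), 0.5)
  }
  expect_equal(class_to_glucose(0), 70.5)
  expect_equal(class_to_glucose(179), 249.5)
})

test_that("interior soft labels have the printed centre weight and linear decay", {
  v <- soft_label(90, radius = 2)
  expect_equal(v[91], 0.5)  # centre weight exactly 0.5
  expect_equal(v[89:93], c(1 / 12, 1 / 6, 1 / 2, 1 / 6, 1 / 12))
  expect_equal(sum(v), 1, tolerance = 1e-12)
  # mass outside the +/- radius support is exactly zero
  expect_true(all(v[-(89:93)] == 0))
})

test_that("boundary soft labels renormalize the surviving neighbours", {
  v0 <- soft_label(0, radius = 2)
  expect_equal(v0[1], 0.5)
  expect_equal(v0[2:3], c(1 / 3, 1 / 6))
  expect_equal(sum(v0), 1, tolerance = 1e-12)

  v1 <- soft_label(1, radius = 2)
  expect_equal(v1[2], 0.5)
  expect_equal(sum(v1), 1, tolerance = 1e-12)
  expect_equal(v1[1], v1[3])  # symmetric distance-1 neighbours

  v179 <- soft_label(179, radius = 2)
  expect_equal(v179[180], 0.5)
  expect_equal(sum(v179), 1, tolerance = 1e-12)

  for (r in 0:4) {
    v <- soft_label(5, radius = r)
    expect_equal(sum(v), 1, tolerance = 1e-12)
    expect_equal(which.max(v), 6)
  }
  expect_error(soft_label(5, radius = -1), "radius")
})

test_that("KL loss matches closed forms and a direct-summation oracle", {
  t1 <- c(1, 0)
  expect_equal(kl_loss(t1, t1), 0)
  expect_equal(kl_loss(t1, c(0.5, 0.5)), log(2), tolerance = 1e-12)

  soft <- soft_label(90)
  unif <- rep(1 / 180, 180)
  oracle <- 0
  for (i in seq_along(soft)) {
    if (soft[i] > 0) oracle <- oracle + soft[i] * log(soft[i] / unif[i])
  }
  expect_equal(kl_loss(soft, unif), oracle, tolerance = 1e-14)
  expect_gte(kl_loss(soft, unif), 0)
  expect_equal(kl_loss(soft, soft), 0)
  expect_error(kl_loss(c(1, 0), c(1, 0, 0)), "length")
})

test_that("class balancing downsamples to the occupied-class mean", {
  labels <- tibble::tibble(
    class = rep(c(0L, 1L, 2L), times = c(10, 2, 3)),
    id = 1:15
  )
  out <- balance_classes(labels, seed = 5)
  counts <- table(out$class)
  expect_equal(as.integer(counts[["0"]]), 5)  # floor(15 / 3)
  expect_equal(as.integer(counts[["1"]]), 2)
  expect_equal(as.integer(counts[["2"]]), 3)
  # deterministic per seed
  expect_identical(balance_classes(labels, seed = 5), out)

  even <- tibble::tibble(class = rep(0:2, each = 4))
  expect_identical(balance_classes(even, seed = 1), even)
  single <- tibble::tibble(class = rep(7L, 6))
  expect_identical(balance_classes(single, seed = 1), single)
})

test_that("balancing never increases counts nor drops below min(count, mean)", {
  set.seed(8)
  labels <- tibble::tibble(class = sample(0:9, 400, replace = TRUE,
                                          prob = (1:10)^2))
  before <- table(factor(labels$class, levels = 0:9))
  out <- balance_classes(labels, seed = 3)
  after <- table(factor(out$class, levels = 0:9))
  m <- floor(mean(table(labels$class)))
  expect_true(all(after <= before))
  expect_true(all(after >= pmin(before, m)))
})

test_that("auxiliary features implement the difference-quotient rate", {
  hist <- tibble::tibble(time = c(0, 3600, 7200),
                         glucose_mgdl = c(90, 100, 120))
  aux <- aux_features(hist, current_time = 10800)
  expect_equal(aux$prev_glucose_mgdl, 120)
  expect_equal(aux$prev2_glucose_mgdl, 100)
  expect_equal(aux$interval_minutes, 60)
  expect_equal(aux$interval2_minutes, 60)
  expect_equal(aux$rate_mgdl_per_min, 20 / 60)
  expect_equal(aux$level_class, 1L)
  expect_false(aux$padded)
  expect_equal(ncol(ppglucose:::scale_aux(aux)), 6)
})

test_that("auxiliary features handle equal values, padding and levels", {
  flat <- tibble::tibble(time = c(0, 3600), glucose_mgdl = c(100, 100))
  expect_equal(aux_features(flat, 7200)$rate_mgdl_per_min, 0)

  one <- tibble::tibble(time = 0, glucose_mgdl = 65)
  aux <- aux_features(one, 3600)
  expect_true(aux$padded)
  expect_equal(aux$prev2_glucose_mgdl, 65)
  expect_equal(aux$rate_mgdl_per_min, 0)
  expect_equal(aux$level_class, 0L)  # hypoglycemic below 70

  expect_equal(glucose_level_class(c(65, 70, 180, 181)), c(0L, 1L, 1L, 2L))
  expect_error(aux_features(one, 0), "prior")
})
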