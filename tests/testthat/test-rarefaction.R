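test_that("field subsampling keeps whole populations and is seed-reproducible", {
  f <- get_fixture()
  set.seed(1)
  sub <- subsample_field(f$ss, 5L)
  arch <- sub$meta[sub$meta$region == "archipelago", ]
  expect_equal(length(unique(arch$population_id)), 5L)
  # whole populations: every retained population keeps its full size
  full_sizes <- table(f$ss$meta$population_id)
  expect_equal(unname(table(arch$population_id)[unique(arch$population_id)]),
               unname(full_sizes[unique(arch$population_id)]))
  # non-archipelago records ride along untouched
  expect_equal(sum(sub$meta$region != "archipelago"), 5L)  # 3 Morocco + 2 outgroup
  set.seed(1)
  sub2 <- subsample_field(f$ss, 5L)
  expect_identical(sub$meta, sub2$meta)
  # full-effort subsample is the identity on archipelago populations
  set.seed(2)
  sub_all <- subsample_field(f$ss, 36L)
  expect_equal(nrow(sub_all$meta), nrow(f$ss$meta))
  expect_error(subsample_field(f$ss, 37L), "between 1 and 36")
})

test_that("genetic subsampling covers 0..G and is seed-reproducible", {
  chars <- c(133L, 448L, 990L, 1290L)
  expect_identical(subsample_genetic(chars, 0L), integer(0))
  set.seed(3)
  g1 <- subsample_genetic(chars, 2L)
  expect_length(g1, 2L)
  expect_true(all(g1 %in% chars))
  set.seed(3)
  expect_identical(subsample_genetic(chars, 2L), g1)
  expect_error(subsample_genetic(chars, 5L), "between 0 and 4")
})

test_that("curve bookkeeping: levels, replicates, terminal values, determinism", {
  cd <- get_fixture_cd("A")
  st <- rarefaction_settings(ancestral = "A", seed = 11)
  gc_curve <- rarefaction_curves(cd, "genetic", st)
  expect_equal(sort(unique(gc_curve$level)), 0:4)
  expect_equal(max(gc_curve$replicate), 25L)
  expect_true(all(gc_curve$value[gc_curve$level == 4L] == cd$full_min))
  # level 0: no genetic information, events = occupied units - 1
  expect_true(all(gc_curve$value[gc_curve$level == 0L] == 5L))
  fc <- rarefaction_curves(cd, "field", st)
  expect_equal(max(fc$replicate), 180L)
  expect_equal(sort(unique(fc$level)), 1:36)
  expect_true(all(fc$value[fc$level == 36L] == cd$full_min))
  # identical seed, identical curves
  gc2 <- rarefaction_curves(cd, "genetic", st)
  expect_identical(gc_curve, gc2)
  # mean curves nondecreasing within Monte-Carlo tolerance of one event
  # (individual replicates can dip when the gap-carrying haplotype re-joins
  # a different class under a changed character subset; see the vignette)
  mg <- tapply(gc_curve$value, gc_curve$level, mean)
  expect_true(all(diff(mg) >= -1))
  mf <- tapply(fc$value, fc$level, mean)
  expect_true(all(diff(mf) >= -1))
})

test_that("accumulation fits recover known curves exactly", {
  x <- 1:10
  fit <- fit_accumulation(x, 2 * x / (1 + 0.1 * x))
  expect_equal(fit$model, "saturating")
  expect_equal(fit$a, 2, tolerance = 1e-6)
  expect_equal(fit$b, 0.1, tolerance = 1e-6)
  expect_equal(fit$asymptote, 20, tolerance = 1e-5)
  # a perfectly linear curve falls back to an infinite asymptote
  lin <- fit_accumulation(x, 1.5 * x)
  expect_equal(lin$model, "linear")
  expect_identical(lin$asymptote, Inf)
  # strict mode reports non-convergence instead
  strict <- fit_accumulation(x, 1.5 * x, method = "strict")
  expect_false(strict$converged)
  # constant curve: the saturated limit of the model
  expect_equal(fit_accumulation(x, rep(7, 10))$asymptote, 7)
  # all-zero curve: asymptote zero, converged
  z <- fit_accumulation(x, rep(0, 10))
  expect_equal(z$asymptote, 0)
  expect_true(z$converged)
  # asymptote never sits below the fitted curve
  y <- c(1, 3, 4, 4.5, 5, 5.2, 5.4, 5.45, 5.5, 5.5)
  f2 <- fit_accumulation(x, y)
  if (f2$model == "saturating")
    expect_gte(f2$asymptote, max(f2$a * x / (1 + f2$b * x)))
})

test_that("trimming retains the documented replicate count and handles Inf", {
  pool <- haplocol:::pool_asymptotes(c(1:23, Inf, Inf), del = 0.05, level = 0.95)
  expect_equal(pool$n_retained, 24L)  # ceil(25 * 0.95)
  expect_equal(pool$status, "ok")
  expect_true(is.finite(pool$point))
  expect_identical(pool$ci_high, Inf)  # an infinite retained value caps the CI
  expect_lte(pool$ci_low, pool$point)
  pool180 <- haplocol:::pool_asymptotes(rep(c(10, 20), 90), del = 0.05, level = 0.95)
  expect_equal(pool180$n_retained, 171L)
  # mostly-infinite pools are undetermined
  und <- haplocol:::pool_asymptotes(c(rep(Inf, 20), 1:5), del = 0.05, level = 0.95)
  expect_equal(und$status, "undetermined")
  expect_true(is.na(und$point))
})

test_that("estimates are reproducible and respect the observed minimum", {
  cd <- get_fixture_cd("A")
  st <- rarefaction_settings(ancestral = "A", seed = 7)
  est <- estimate_colonization(cd, st)
  est2 <- estimate_colonization(cd, st)
  expect_identical(est, est2)
  g <- est$genetic
  expect_equal(g$n_replicates, 25L)
  expect_equal(est$field$n_replicates, 180L)
  if (g$status == "ok") {
    expect_gte(g$point, cd$full_min)
    expect_lte(g$ci_low, g$point)
    expect_gte(g$ci_high, g$point)  # point sits inside its own replicate CI
  }
  # swapping the nesting order exchanges the correction structure
  est_sw <- estimate_colonization(cd, rarefaction_settings(ancestral = "A", seed = 7,
                                                           swap_nesting = TRUE))
  expect_equal(est_sw$genetic$n_replicates, 180L)
})
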