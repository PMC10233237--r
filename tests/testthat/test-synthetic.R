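# Synthetic cohort generators: templates, factors, patients, controls,
# clinical tables, and their determinism.

test_that("templates satisfy the mask contracts deterministically", {
  t1 <- make_template(c(30L, 36L, 30L))
  expect_gt(t1$brain$n_voxels, 0)
  expect_true(all(t1$reference$voxel_index %in% t1$brain$voxel_index))

  # doubling the grid increases the mask voxel count
  t2 <- make_template(c(60L, 72L, 60L))
  expect_gt(t2$brain$n_voxels, t1$brain$n_voxels)

  # same spec twice -> identical masks
  t3 <- make_template(c(30L, 36L, 30L))
  expect_identical(t1$brain$indicator, t3$brain$indicator)
  expect_identical(t1$reference$voxel_index, t3$reference$voxel_index)

  expect_error(make_template(c(8L, 30L, 30L)), "at least 16")
  # a reference pushed outside the brain is rejected
  expect_error(make_template(c(30L, 36L, 30L), reference_offset = c(0, 0, -1.2)),
               "outside")
})

test_that("factors are orthonormal, zero-mean, and smoothness-controlled", {
  tmpl <- small_template()
  fac <- make_factors(tmpl$brain, 5, 2.5, seed = 2)
  G <- fac %*% t(fac)
  expect_lt(max(abs(G - diag(5))), 1e-8)
  expect_lt(max(abs(rowMeans(fac))), 1e-10)

  # the white-noise limit is still orthonormal
  fac0 <- make_factors(tmpl$brain, 3, 0, seed = 2)
  expect_lt(max(abs(fac0 %*% t(fac0) - diag(3))), 1e-8)

  # lag-1 spatial autocorrelation increases with the smoothing sigma
  lag1 <- function(f) {
    arr <- unflatten_row(f, tmpl$brain)
    inside <- tmpl$brain$indicator[-dim(arr)[1], , ] &
      tmpl$brain$indicator[-1, , ]
    cor(arr[-dim(arr)[1], , ][inside], arr[-1, , ][inside])
  }
  ac_smooth <- lag1(make_factors(tmpl$brain, 1, 3, seed = 4)[1, ])
  ac_rough <- lag1(make_factors(tmpl$brain, 1, 0, seed = 4)[1, ])
  expect_gt(ac_smooth, ac_rough + 0.3)

  expect_error(make_factors(tmpl$brain, tmpl$brain$n_voxels + 1L), "smaller")
})

test_that("simulate_patients obeys the noiseless limit and defaults", {
  tmpl <- small_template()
  fac <- make_factors(tmpl$brain, 2, 2, seed = 3)
  cents <- rbind(c(5, 0), c(0, 5))
  pats <- simulate_patients(fac, tmpl$brain, cents, n_per_cluster = c(2L, 2L),
                            loading_sd = 0, noise_sd = 0, baseline = 10, seed = 1)
  # each masked image equals its centroid's exact linear combination
  got <- pats$volumes[[1]]$data[tmpl$brain$voxel_index]
  expect_equal(got, 10 + 5 * fac[1, ], tolerance = 1e-12)
  expect_equal(pats$labels, c(1L, 1L, 2L, 2L))

  # default subtype sizes total 52 patients
  gt <- default_ground_truth()
  fac6 <- make_factors(tmpl$brain, 6, 2, seed = 5)
  pats52 <- simulate_patients(fac6, tmpl$brain, gt$centroids,
                              loading_sd = gt$loading_sd, seed = 2)
  expect_length(pats52$volumes, 52L)
  expect_equal(as.integer(table(pats52$labels)), c(21L, 19L, 7L, 5L))

  # same seed -> bit-identical cohort
  a <- simulate_patients(fac, tmpl$brain, cents, c(2L, 2L), seed = 9)
  b <- simulate_patients(fac, tmpl$brain, cents, c(2L, 2L), seed = 9)
  expect_identical(a$volumes[[3]]$data, b$volumes[[3]]$data)

  expect_error(simulate_patients(fac, tmpl$brain, cents, c(0L, 2L)), "positive")
  expect_error(simulate_patients(fac, tmpl$brain, cents[, 1, drop = FALSE]),
               "centroid dimension")
})

test_that("controls carry no factor loading and are seed-deterministic", {
  tmpl <- small_template()
  ctrls <- simulate_controls(tmpl$brain, n = 4, noise_sd = 0.1, seed = 7)
  expect_length(ctrls, 4L)
  rows <- t(vapply(ctrls, function(v) v$data[tmpl$brain$voxel_index],
                   numeric(tmpl$brain$n_voxels)))
  fac <- make_factors(tmpl$brain, 3, 2, seed = 8)
  # projection of centered control images onto factors is pure noise scale
  proj <- (rows - 10) %*% t(fac)
  expect_lt(max(abs(proj)), 0.1 * sqrt(tmpl$brain$n_voxels)) # >5 sd margin

  expect_identical(simulate_controls(tmpl$brain, 3, seed = 1)[[2]]$data,
                   simulate_controls(tmpl$brain, 3, seed = 1)[[2]]$data)
  expect_error(simulate_controls(tmpl$brain, 1), "at least 2")
})

test_that("clinical outcomes follow the planted linear model", {
  withr::local_seed(10)
  loadings <- matrix(rnorm(2000 * 6), 2000, 6) %*% diag(sqrt(c(9, 7, 5, 4, 3, 2)))
  betas <- rbind(planted = c(0.5, -0.3, 0, 0, 0, 0))
  cl <- simulate_clinical(loadings, betas, missing_rate = 0, seed = 4,
                          units = list(planted = c(0, 1)))
  fit <- fit_multivariable(scale(loadings), cl$planted, "planted")
  expect_lt(max(abs(unname(fit$betas[1:2]) - c(0.5, -0.3))), 0.06)
  expect_lt(max(abs(unname(fit$betas[3:6]))), 0.06)
  expect_lt(abs(fit$r2 - 0.34), 0.05)

  # null betas: outcome independent of loadings
  cl0 <- simulate_clinical(loadings, rbind(null = rep(0, 6)), missing_rate = 0,
                           seed = 5, units = list(null = c(0, 1)))
  expect_lt(fit_multivariable(scale(loadings), cl0$null, "null")$r2, 0.05)
})

test_that("missingness is applied per cell at the stated rate", {
  withr::local_seed(11)
  loadings <- matrix(rnorm(52 * 6), 52, 6)
  betas <- do.call(rbind, rep(list(c(0.3, rep(0, 5))), 10))
  rownames(betas) <- paste0("v", 1:10)
  cl <- simulate_clinical(loadings, betas, missing_rate = 0.3, seed = 6)
  frac <- mean(is.na(as.matrix(cl[, paste0("v", 1:10)])))
  # 520 cells at rate 0.3: binomial sd ~ 0.02
  expect_equal(frac, 0.3, tolerance = 0.07)
  # expected complete rows per outcome ~ 52 * 0.7 = 36.4
  expect_equal(mean(colSums(!is.na(cl[, paste0("v", 1:10)]))), 36.4,
               tolerance = 5)

  expect_identical(simulate_clinical(loadings, betas, seed = 3),
                   simulate_clinical(loadings, betas, seed = 3))
})

test_that("the assembled cohort is internally consistent and deterministic", {
  co <- small_cohort()
  expect_length(co$patient_volumes, sum(c(8, 7, 3, 3)))
  expect_length(co$control_volumes, 10L)
  expect_equal(nrow(co$clinical), 21L)
  expect_equal(co$clinical$subject_id,
               vapply(co$patient_volumes, function(v) v$subject_id, character(1)))
  expect_lt(max(abs(co$truth$factor_maps %*% t(co$truth$factor_maps) - diag(4))),
            1e-8)

  co2 <- simulate_cohort(n_per_cluster = c(8L, 7L, 3L, 3L), n_controls = 10L,
                         shape = c(16L, 18L, 16L), k_factors = 4L, seed = 42L)
  expect_identical(co$patient_volumes[[5]]$data, co2$patient_volumes[[5]]$data)
  expect_identical(co$clinical, co2$clinical)
})

test_that("write_cohort produces a readable on-disk bundle", {
  co <- small_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_length(list.files(file.path(dir, "patients")), 21L)
  expect_length(list.files(file.path(dir, "controls")), 10L)
  expect_true(file.exists(file.path(dir, "clinical.csv")))
  truth <- jsonlite::read_json(file.path(dir, "truth", "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$cluster_labels, co$truth$cluster_labels)
  m <- read_mask(file.path(dir, "brain_mask.nii.gz"))
  expect_identical(m$voxel_index, co$mask$voxel_index)
  v <- read_volume(list.files(file.path(dir, "patients"), full.names = TRUE)[1])
  expect_equal(dim(v$data), co$mask$dim)
})
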