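# Quadrature oracle for the zero-truncated normal: integrates the
# truncated density directly, independent of the sampler and of the
# closed-form moments.
quad_truncnorm <- function(mean_nN, sd_nN) {
  z <- stats::integrate(function(x) stats::dnorm(x, mean_nN, sd_nN),
                        0, Inf, rel.tol = 1e-10)$value
  m1 <- stats::integrate(function(x) x * stats::dnorm(x, mean_nN, sd_nN),
                         0, Inf, rel.tol = 1e-10)$value / z
  m2 <- stats::integrate(function(x) x^2 * stats::dnorm(x, mean_nN, sd_nN),
                         0, Inf, rel.tol = 1e-10)$value / z
  list(mean = m1, sd = sqrt(m2 - m1^2))
}

test_that("built-in specs carry the published statistics, symmetric lookup", {
  specs <- builtin_force_specs()
  eses <- lookup_force_spec("ES-ES", specs = specs)
  expect_equal(eses$mean_nN, 1.94)
  expect_equal(eses$sd_nN, 0.54)
  expect_equal(eses$n_published, 60L)
  xts <- lookup_force_spec("XEN-TS", specs = specs)
  expect_equal(xts$mean_nN, 0.46)
  expect_equal(xts$sd_nN, 0.24)
  expect_equal(xts$n_published, 148L)
  # unordered pair: both orders resolve to the same spec
  expect_identical(lookup_force_spec("TS-ES", specs = specs),
                   lookup_force_spec("ES-TS", specs = specs))
  # Cdh1 knockdown is a fourfold reduction of wild-type ES-ES
  kd <- lookup_force_spec("ES-ES", condition = "Cdh1-KD", specs = specs)
  expect_equal(kd$mean_nN, 1.94 / 4)
  expect_equal(kd$sd_nN, 0.54 / 4)
  # substrate specs present with printed n
  expect_equal(lookup_force_spec("ES-Ecad", specs = specs)$n_published, 42L)
  expect_equal(lookup_force_spec("TS-Pcad", specs = specs)$n_published, 37L)
})

test_that("force sampling is seeded, non-negative, and sized", {
  spec <- lookup_force_spec("ES-XEN")  # sd > mean: truncation active
  s1 <- sample_forces(spec, n = 500, seed = 7)
  s2 <- sample_forces(spec, n = 500, seed = 7)
  expect_identical(s1$forces_nN, s2$forces_nN)
  expect_true(all(s1$forces_nN >= 0))
  expect_length(s1$forces_nN, 500)
  expect_length(sample_forces(spec, n = 0, seed = 1)$forces_nN, 0)
  expect_error(sample_forces(spec, n = -1, seed = 1), "non-negative")
  s3 <- sample_forces(spec, n = 500, seed = 8)
  expect_false(identical(s1$forces_nN, s3$forces_nN))
})

test_that("generated samples recover the truncated-normal oracle moments", {
  specs <- builtin_force_specs()
  for (key in names(specs)) {
    spec <- specs[[key]]
    orc <- quad_truncnorm(spec$mean_nN, spec$sd_nN)
    s <- summarize_forces(sample_forces(spec, n = 10000, seed = 42))
    expect_lt(abs(s$mean - orc$mean) / orc$mean, 0.01, label = key)
    expect_lt(abs(s$sd - orc$sd) / orc$sd, 0.03, label = key)
    # closed-form moments agree with quadrature
    cf <- truncnorm_moments(spec$mean_nN, spec$sd_nN)
    expect_equal(cf$mean, orc$mean, tolerance = 1e-8)
    expect_equal(cf$sd, orc$sd, tolerance = 1e-8)
  }
})

test_that("sample summaries are exact on hand-computed cases", {
  expect_equal(summarize_forces(c(1, 1, 1)),
               list(mean = 1, sd = 0, n = 3L))
  s <- summarize_forces(c(0, 2))
  expect_equal(s$mean, 1)
  expect_equal(s$sd, sqrt(2))
  expect_equal(s$n, 2L)
  expect_error(summarize_forces(numeric(0)), "empty")
  one <- summarize_forces(3.2)
  expect_true(is.na(one$sd))
})

test_that("force tables round-trip through CSV", {
  samples <- list(sample_forces(lookup_force_spec("ES-ES"), seed = 1),
                  sample_forces(lookup_force_spec("XEN-TS"), seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_force_table(samples, path)
  df <- read_force_table(path)
  expect_equal(nrow(df), 60 + 148)
  expect_named(df, c("pair_id", "condition", "force_nN", "seed",
                     "replicate"))
  expect_equal(df$force_nN[df$pair_id == "ES-ES"],
               samples[[1]]$forces_nN)
  expect_error(read_force_table(file.path(tempdir(), "nope.csv")),
               "not found")
})

test_that("configuration overrides replace or add force specs", {
  cfg <- default_config()
  cfg$forces <- list(
    list(pair = "TS-ES", mean_nN = 0.9, sd_nN = 0.2, n = 30),
    list(pair = "XEN-XEN", mean_nN = 0.3, sd_nN = 0.1, n = 12,
         condition = "Cdh6-KD"))
  specs <- config_force_specs(cfg)
  # unordered pair id resolves to the built-in slot and replaces it
  expect_equal(specs[["ES-TS|WT"]]$mean_nN, 0.9)
  expect_equal(specs[["ES-TS|WT"]]$n_published, 30L)
  # new knockdown condition appended alongside the built-ins
  expect_equal(specs[["XEN-XEN|Cdh6-KD"]]$mean_nN, 0.3)
  expect_equal(specs[["XEN-XEN|WT"]]$mean_nN, 0.55)
  # no overrides: identical to the built-ins
  expect_identical(config_force_specs(default_config()),
                   builtin_force_specs())
})

test_that("force pools cover the six pairs at published sizes", {
  pools <- build_force_pools(seed = 3)
  expect_setequal(names(pools), c("ES-ES", "ES-TS", "ES-XEN", "TS-TS",
                                  "TS-XEN", "XEN-XEN"))
  expect_equal(lengths(pools)[["TS-TS"]], 177L)
  expect_equal(lengths(pools)[["ES-XEN"]], 134L)
  expect_true(all(unlist(pools) >= 0))
})
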