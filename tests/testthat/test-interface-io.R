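test_that("empty configuration yields the shipped defaults", {
  cfg <- load_config()
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$model, "lipid")
  expect_equal(cfg$solver$order, 0.8)
  expect_equal(cfg$solver$t_end, 6)
  expect_equal(cfg$sweep$gamma_c, 0.70)
  expect_identical(load_config(""), cfg)
})

test_that("unknown or out-of-range configuration keys are rejected by name", {
  expect_error(load_config("solvr:\n  order: 0.5\n"), "unknown config key: solvr")
  expect_error(load_config("solver:\n  oder: 0.5\n"), "solver.oder")
  expect_error(load_config("solver:\n  order: 2.5\n"), "solver.order")
  expect_error(load_config("lipid:\n  theta: 1.5\n"), "lipid.theta")
  expect_error(load_config("profile: banana\n"), "profile")
  # therapeutic lipid run cannot carry an order above 1
  expect_error(load_config("solver:\n  order: 1.5\n"), "order <= 1")
  # but the toxic transform admits it
  cfg <- load_config("solver:\n  order: 1.5\nsweep:\n  transform: true\n")
  expect_equal(cfg$solver$order, 1.5)
})

test_that("configuration round-trips through YAML and hashes canonically", {
  cfg <- load_config("solver:\n  order: 0.6\nlipid:\n  beta: 0.3\n")
  back <- load_config(dump_config(cfg))
  expect_identical(unclass(back), unclass(cfg))
  h1 <- config_hash(cfg)
  h2 <- config_hash(load_config("lipid:\n  beta: 0.3\nsolver:\n  order: 0.6\n"))
  expect_identical(h1, h2)   # key order is cosmetic
  h3 <- config_hash(load_config("solver:\n  order: 0.65\n"))
  expect_false(identical(h1, h3))
  expect_match(h1, "^[0-9a-f]{32}$")
})

test_that("fixtures start from the printed profiles and jitter deterministically", {
  fx <- make_fixtures(0)
  expect_length(fx, 4L)
  expect_equal(vapply(fx, `[[`, numeric(1), "ldl"), c(160, 140, 90, 160))
  expect_equal(vapply(fx, `[[`, numeric(1), "hdl"), c(50, 50, 60, 40))
  a <- make_fixtures(10, seed = 42)
  b <- make_fixtures(10, seed = 42)
  expect_identical(a, b)
  expect_false(identical(make_fixtures(10, seed = 43)[[5]], a[[5]]))
  # jitter stays within +/-10% of a printed profile
  base <- cbind(ldl = c(160, 140, 90, 160), hdl = c(50, 50, 60, 40))
  for (p in a[-(1:4)]) {
    rel <- abs(sweep(base, 2, c(p$ldl, p$hdl), "/") - 1)
    expect_true(any(rel[, 1] <= 0.1 + 1e-12 & rel[, 2] <= 0.1 + 1e-12))
  }
  expect_error(make_fixtures(-1), "non-negative")
})

test_that("fixture generation does not disturb the session RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(make_fixtures(5, seed = 7))
  expect_identical(.Random.seed, before)
})

test_that("trajectory outputs carry the documented headers and provenance", {
  dir <- withr::local_tempdir()
  cfg <- load_config()
  sim <- simulate_patient(patient_profile(160, 50), order = 0.8,
                          t_end = 1, step = 0.01)
  paths <- write_outputs(sim, dir, cfg)
  header <- readLines(paths[["csv"]], n = 1L)
  expect_identical(header, "t,HDL,Ox,LDL,MDA")
  meta <- jsonlite::read_json(paths[["json"]])
  expect_equal(meta$kind, "lipid_sim")
  expect_equal(meta$config_hash, unname(config_hash(cfg)))
  expect_equal(meta$params$beta, 0.2)
  expect_true(!is.null(meta$reconstructions$hdl_channel_sign))
  ps <- simulate_plaque(plaque_params(), order = 0.9, t_end = 1, step = 0.01)
  p2 <- write_outputs(ps, dir, cfg)
  expect_identical(readLines(p2[["csv"]], n = 1L), "t,h,mineral")
})

test_that("reruns with one configuration are byte-identical up to the timestamp", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    fde_cli(c("simulate", "--profile", "140:50", "--order", "0.7",
              "--out-dir", d))
  }
  expect_identical(readLines(file.path(d1, "lipid.csv")),
                   readLines(file.path(d2, "lipid.csv")))
  strip_ts <- function(f) grep("\"created\"", readLines(f),
                               invert = TRUE, value = TRUE)
  expect_identical(strip_ts(file.path(d1, "lipid.json")),
                   strip_ts(file.path(d2, "lipid.json")))
})

test_that("the CLI drives bands, sweep and fixtures end to end", {
  dir <- withr::local_tempdir()
  fde_cli(c("bands", "--out-dir", dir))
  bands <- utils::read.csv(file.path(dir, "bands.csv"))
  expect_equal(nrow(bands), 9L)
  fde_cli(c("sweep", "--gamma-min", "0.4", "--gamma-max", "0.8",
            "--gamma-step", "0.2", "--out-dir", dir))
  rep <- jsonlite::read_json(file.path(dir, "sweep.json"))
  expect_equal(length(rep$grid), 3L)
  expect_false(isTRUE(rep$transform_enabled))
  fde_cli(c("fixtures", "--n-extra", "2", "--out-dir", dir, "--seed", "5"))
  fx <- utils::read.csv(file.path(dir, "fixtures.csv"))
  expect_equal(nrow(fx), 6L)
  expect_error(fde_cli(c("frobnicate")), "unknown subcommand")
  expect_error(fde_cli(c("simulate", "--order")), "needs a value")
})
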