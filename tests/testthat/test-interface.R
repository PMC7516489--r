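make_mock_run <- function(dir, seed = 5, jitter = NULL) {
  cfg <- list(
    dataset = file.path(dir, "sim", "dataset.csv"),
    domain = list(lower = -1, upper = 1),
    levels = list(
      list(mean_order = 10, alpha_bounds = c(1, 40), jitter = jitter),
      list(mean_order = 4, alpha_bounds = c(1, 40), jitter = jitter)),
    alpha_grid = 60,
    scenario = "mock",
    seed = seed)
  run_simulate(cfg, file.path(dir, "sim"), seed = seed)
  cfg
}

test_that("configs round-trip through YAML with field-path validation", {
  dir <- withr::local_tempdir()
  cfg <- list(dataset = "d.csv",
              levels = list(list(mean_order = 3, alpha_bounds = c(1, 10))),
              alpha_grid = 50, quadrature = "midpoint", band_k = 1)
  path <- file.path(dir, "cfg.yaml")
  yaml::write_yaml(cfg, path)
  cfg2 <- read_run_config(path)
  expect_equal(cfg2$levels[[1]]$mean_order, 3)
  expect_equal(cfg2$levels[[1]]$alpha_bounds, c(1, 10))
  expect_error(validate_run_config(list(levels = list(list()))),
               "levels\\[1\\].mean_order")
  expect_error(validate_run_config(list(
    levels = list(list(mean_order = 2, alpha_bounds = c(5, 1))))),
    "levels\\[1\\].alpha_bounds")
  expect_error(validate_run_config(list(
    levels = list(list(mean_order = 2)), alpha_grid = 2)),
    "alpha_grid")
})

test_that("simulation artifacts are deterministic given config and seed", {
  dir <- withr::local_tempdir()
  make_mock_run(dir, seed = 7)
  bytes1 <- readLines(file.path(dir, "sim", "dataset.csv"))
  make_mock_run(dir, seed = 7)
  expect_identical(readLines(file.path(dir, "sim", "dataset.csv")), bytes1)
  truth <- jsonlite::fromJSON(file.path(dir, "sim", "truth.json"))
  expect_equal(truth$truth$rho[2], 3)
})

test_that("fit artifacts carry the full parameter inventory and reproduce", {
  dir <- withr::local_tempdir()
  cfg <- make_mock_run(dir, seed = 5)
  run_fit(cfg, file.path(dir, "fit"))
  sm <- jsonlite::fromJSON(file.path(dir, "fit", "summary.json"))
  pars <- sm$parameters$parameter
  expect_length(grep("^beta1", pars), 10)
  expect_length(grep("^beta2", pars), 4)
  expect_setequal(grep("^beta", pars, invert = TRUE, value = TRUE),
                  c("sigma1", "alpha1", "sigma2", "rho1", "alpha2"))
  expect_true(is.finite(sm$log_evidence))
  bytes <- readLines(file.path(dir, "fit", "posterior.csv"))
  run_fit(cfg, file.path(dir, "fit2"))
  expect_identical(readLines(file.path(dir, "fit2", "posterior.csv")), bytes)
})

test_that("inadmissible trend orders fail with the constraint message", {
  dir <- withr::local_tempdir()
  cfg <- make_mock_run(dir, seed = 5)
  cfg$levels[[2]]$mean_order <- 8
  expect_error(run_fit(cfg, file.path(dir, "fit")),
               "second moments of sigma_t are not defined")
})

test_that("prediction at training pivots reproduces the data column", {
  dir <- withr::local_tempdir()
  tt <- tiny_two_level(seed = 13)
  dpath <- file.path(dir, "dataset.csv")
  write_mufi_csv(tt$dataset, dpath)
  cfg <- list(
    dataset = dpath,
    domain = list(lower = -1, upper = 1),
    levels = list(
      list(mean_order = 2, alpha_bounds = c(0.5, 20), jitter = 0),
      list(mean_order = 1, alpha_bounds = c(0.5, 20), jitter = 0)),
    alpha_grid = 40,
    query = list(points = as.list(tt$dataset$x[[2]][, 1])))
  fit <- run_fit(cfg, file.path(dir, "out"))
  run_predict(cfg, file.path(dir, "out"), fit = fit)
  pred <- utils::read.csv(file.path(dir, "out", "predictions.csv"))
  expect_equal(pred$mean, tt$dataset$z[[2]], tolerance = 1e-8)
  expect_equal(pred$lower, pred$mean - pred$sd)
})

test_that("empty query lists yield a header-only prediction file", {
  dir <- withr::local_tempdir()
  cfg <- make_mock_run(dir, seed = 5)
  cfg$query <- list(points = list())
  fit <- run_fit(cfg, file.path(dir, "out"))
  run_predict(cfg, file.path(dir, "out"), fit = fit)
  lines <- readLines(file.path(dir, "out", "predictions.csv"))
  expect_length(lines, 1)
  expect_match(lines, "^x1,mean,sd,lower,upper$")
})

test_that("predicting without fit artifacts is a clear error", {
  dir <- withr::local_tempdir()
  cfg <- make_mock_run(dir, seed = 5)
  cfg$query <- list(linspace = list(from = -1, to = 1, n = 5))
  expect_error(run_predict(cfg, file.path(dir, "nowhere")),
               "run the fit first")
})

test_that("the command-line entry point drives a full simulate run", {
  dir <- withr::local_tempdir()
  cli <- system.file("cli", "mufi.R", package = "mufigp")
  expect_true(nzchar(cli))
  cfgp <- file.path(dir, "cfg.yaml")
  yaml::write_yaml(list(scenario = "mock",
                        levels = list(list(mean_order = 10,
                                           alpha_bounds = c(1, 40)))),
                   cfgp)
  out <- system2("Rscript",
                 c(cli, "simulate", "--config", cfgp, "--seed", "3",
                   "--out", file.path(dir, "cli_out")),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(dir, "cli_out", "dataset.csv")))
})
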