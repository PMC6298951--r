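test_that("stream seeds are deterministic, distinct and 31-bit", {
  s1 <- derive_seed(1, 3, "train")
  expect_identical(s1, derive_seed(1, 3, "train"))
  expect_false(s1 == derive_seed(1, 3, "post"))
  expect_false(s1 == derive_seed(2, 3, "train"))
  seeds <- unlist(lapply(1:50, function(s)
    lapply(c("listener", "pre", "train", "post"), derive_seed,
           master_seed = 1, subject = s)))
  expect_true(all(seeds >= 0 & seeds < 2^31 - 1))
  expect_equal(anyDuplicated(seeds), 0)
  expect_error(derive_seed(1, 1, "warmup"), "phase")
})

test_that("simulated listeners are reproducible and idiosyncratic", {
  a <- simulate_listener(1, master_seed = 9)
  b <- simulate_listener(1, master_seed = 9)
  expect_identical(a$world$gain_db, b$world$gain_db)
  expect_identical(a$observer$sigma_prior, b$observer$sigma_prior)
  c2 <- simulate_listener(2, master_seed = 9)
  expect_false(identical(a$world$gain_db, c2$world$gain_db))
  expect_false(a$observer$sigma_prior == c2$observer$sigma_prior)
})

test_that("run_experiment writes a complete, reproducible run", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- experiment_config(2, n_subjects = 1, master_seed = 3,
                           learning_opts = list(n_trials = 36))
  res <- run_experiment(cfg, out_dir = dir1)
  run_experiment(cfg, out_dir = dir2)
  expect_equal(nrow(res$trials), 116 + 36 + 116)
  expect_equal(unname(table(res$trials$phase)[c("pre", "train", "post")]),
               c(116L, 36L, 116L), ignore_attr = TRUE)
  for (f in c("trials_S01.csv", "weights_S01.csv", "fits.csv",
              "sign_tests.json", "manifest.json")) {
    expect_true(file.exists(file.path(dir1, f)))
  }
  # byte-identical artifacts on re-run
  for (f in c("trials_S01.csv", "fits.csv", "manifest.json")) {
    expect_identical(readBin(file.path(dir1, f), "raw", 1e6),
                     readBin(file.path(dir2, f), "raw", 1e6))
  }
  manifest <- jsonlite::read_json(file.path(dir1, "manifest.json"))
  expect_equal(manifest$config$master_seed, 3)
  expect_equal(length(manifest$subject_seeds), 1)
})

test_that("analysis of a written run reproduces the inline results", {
  dir <- withr::local_tempdir()
  cfg <- experiment_config(2, n_subjects = 1, master_seed = 4,
                           learning_opts = list(n_trials = 36))
  res <- run_experiment(cfg, out_dir = dir)
  rean <- analyze_run(dir)
  expect_equal(rean$fits, res$fits)
  expect_equal(rean$sign_tests, res$sign_tests)
  expect_null(rean$windowed) # 36-trial training session is shorter than a window
})

test_that("analysis rejects malformed trial tables by name", {
  dir <- withr::local_tempdir()
  cfg <- experiment_config(2, n_subjects = 1, master_seed = 5,
                           learning_opts = list(n_trials = 36))
  run_experiment(cfg, out_dir = dir)
  tr <- readr::read_csv(file.path(dir, "trials_S01.csv"), show_col_types = FALSE)
  names(tr)[names(tr) == "resp_el_deg"] <- "response"
  readr::write_csv(tr, file.path(dir, "trials_S01.csv"))
  expect_error(analyze_run(dir), "resp_el_deg")
  expect_error(analyze_run(withr::local_tempdir()), "manifest")
})

test_that("a hand-written identity trial table yields a unit-gain fit", {
  dir <- withr::local_tempdir()
  el <- c(-30, 0, 40, 20, -10, 55)
  tr <- tibble::tibble(subject_id = "S01", phase = "pre", trial = seq_along(el),
                       stim_kind = "LP6", target_az_deg = 0, target_el_deg = el,
                       resp_az_deg = 0, resp_el_deg = el,
                       confidence = 1, degenerate_flag = FALSE)
  readr::write_csv(tr, file.path(dir, "trials_S01.csv"))
  jsonlite::write_json(list(config = list()), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  out <- analyze_run(dir)
  expect_equal(out$fits$gain, 1)
  expect_equal(out$fits$bias, 0)
  expect_equal(out$fits$mae, 0)
})
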