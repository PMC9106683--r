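make_profile_csv <- function(path, drop_col = NULL, dup_row = FALSE) {
  rows <- expand.grid(stage = c("S0", "S1"), replicate = c("r1", "r2"),
                      horizon = c("A", "B", "C"), stringsAsFactors = FALSE)
  rows <- rows[order(rows$stage, rows$replicate), ]
  rows$top_cm <- rep(c(0, 10, 20), times = 4)
  rows$bottom_cm <- rows$top_cm + 10
  rows$soc_g_kg <- 60 - rows$top_cm
  rows$bd_g_cm3 <- 0.8 + 0.01 * rows$top_cm
  rows$crack_cm <- ifelse(rows$stage == "S0", 0, 2)
  if (!is.null(drop_col)) rows[[drop_col]] <- NULL
  if (dup_row) rows <- rbind(rows, rows[1, ])
  utils::write.csv(rows, path, row.names = FALSE)
  path
}

test_that("read_profiles groups rows into validated ensembles", {
  path <- make_profile_csv(withr::local_tempfile(fileext = ".csv"))
  ens <- read_profiles(path)
  expect_named(ens, c("S0", "S1"))
  expect_length(ens$S0$profiles, 2)
  expect_length(ens$S1$profiles, 2)
  expect_equal(nrow(ens$S1$profiles$r1$horizons), 3)
  expect_equal(ens$S1$profiles$r2$crack_depth, 2)
})

test_that("read_profiles raises schema and data errors", {
  no_bd <- make_profile_csv(withr::local_tempfile(fileext = ".csv"),
                            drop_col = "bd_g_cm3")
  expect_error(read_profiles(no_bd), "schema error", class = "schema_error")

  dup <- make_profile_csv(withr::local_tempfile(fileext = ".csv"),
                          dup_row = TRUE)
  expect_error(read_profiles(dup), "duplicate", class = "data_error")

  expect_error(read_profiles(withr::local_tempfile(fileext = ".csv")),
               "not found", class = "schema_error")
})

test_that("read_profiles warns about unrecognized columns and keeps optional ones", {
  path <- withr::local_tempfile(fileext = ".csv")
  d <- utils::read.csv(make_profile_csv(path))
  d$n_g_kg <- d$soc_g_kg / 10
  d$comment <- "x"
  utils::write.csv(d, path, row.names = FALSE)
  expect_warning(ens <- read_profiles(path), "comment")
  expect_equal(ens$S0$profiles$r1$horizons$n, c(6, 5, 4))
})

test_that("read_literature normalizes units and flags bad rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "study_id,degradation_label,depth_top_cm,depth_bottom_cm,carbon_kind,carbon_g_kg,bd_g_cm3,region",
    "s1,intact,0,10,SOM,40,1.0,Nagqu",
    "s1,bare soil,0,10,SOC,20,1.1,Nagqu"), path)
  recs <- read_literature(path)
  expect_equal(recs$carbon_kind, c("SOM", "SOC"))
  expect_true(all(is.na(recs$mapped_stage)))

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("study_id,degradation_label,depth_top_cm,depth_bottom_cm", empty)
  expect_equal(nrow(read_literature(empty)), 0)

  no_depth <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("study_id,degradation_label,depth_top_cm,depth_bottom_cm",
               "s1,intact,0,"), no_depth)
  expect_error(read_literature(no_depth), "missing depth", class = "data_error")

  bad_num <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("study_id,degradation_label,depth_top_cm,depth_bottom_cm,carbon_kind,carbon_g_kg",
               "s1,intact,0,10,SOC,abc"), bad_num)
  expect_error(read_literature(bad_num), "unparseable numeric",
               class = "data_error")
})

test_that("write_results round-trips at declared precision with config echo", {
  res <- data.frame(stage = c("S1", "S2"),
                    total_loss = c(1.23456789, pi),
                    closure_p = c(0.5, 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_results(res, path, header_lines = config_echo <- c("line one"))
  back <- utils::read.csv(path, comment.char = "#")
  expect_equal(back$total_loss, round(res$total_loss, 6))
  expect_equal(back$stage, res$stage)
  expect_true(startsWith(readLines(path, n = 1), "#"))

  empty <- res[0, ]
  write_results(empty, path)
  expect_equal(nrow(utils::read.csv(path, comment.char = "#")), 0)
})

test_that("run_config validates fields and reads YAML with a mapping path", {
  expect_error(run_config(depth_limit = -1), class = "config_error")
  expect_error(run_config(alpha = 1.2), class = "config_error")
  expect_error(run_config(vsc_recovery = 0), class = "config_error")

  dir <- withr::local_tempdir()
  map_path <- file.path(dir, "map.csv")
  utils::write.csv(default_stage_mapping(), map_path, row.names = FALSE)
  cfg_path <- file.path(dir, "cfg.yml")
  writeLines(c("depth_limit: 20", "alpha: 0.01", "stage_mapping: map.csv"),
             cfg_path)
  cfg <- read_run_config(cfg_path)
  expect_equal(cfg$depth_limit, 20)
  expect_equal(cfg$alpha, 0.01)
  expect_equal(cfg$som_to_soc_factor, 2.0)
  expect_equal(nrow(cfg$stage_mapping), nrow(default_stage_mapping()))
  writeLines("bogus_key: 1", cfg_path)
  expect_error(read_run_config(cfg_path), class = "config_error")
})
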