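test_that("the pipeline produces metrics, labels and artifacts for a patient", {
  out <- tempfile()
  pr <- run_pipeline(1, configs = c("C", "G"),
                     config = solver_config("fast"), out_dir = out)
  expect_equal(nrow(pr$labels), 2L)
  expect_equal(nrow(pr$grafts), 6L)
  expect_true(all(pr$diagnostics$converged))
  for (f in c("graft_metrics.csv", "graft_metrics.full.csv",
              "stenosis_metrics.csv", "perfusion.csv",
              "classification.json", "manifest.json"))
    expect_true(file.exists(file.path(out, f)), info = f)
  man <- jsonlite::fromJSON(file.path(out, "manifest.json"))
  expect_equal(man$patient, 1L)
  expect_equal(man$solver$dx_cm, 0.5)
  expect_true(all(c("timings_s", "convergence", "output_md5") %in%
                    names(man)))
  ## totals row per configuration equals the exact territory sum
  tabs <- emit_patient_table(pr)
  g <- tabs$graft_table
  for (cf in c("C", "G")) {
    tot <- g$regional_perfusion_ml_min[g$config == cf & g$total]
    parts <- pr$perfusion[[cf]]
    expect_equal(tot, sum(parts$perfusion_ml_min[!parts$total]))
  }
})

test_that("identical pipeline runs are byte-identical (determinism)", {
  o1 <- tempfile(); o2 <- tempfile()
  invisible(run_pipeline(2, configs = "B", config = solver_config("fast"),
                         out_dir = o1))
  invisible(run_pipeline(2, configs = "B", config = solver_config("fast"),
                         out_dir = o2))
  f1 <- file.path(o1, "graft_metrics.full.csv")
  f2 <- file.path(o2, "graft_metrics.full.csv")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("emit_patient_table rejects incomplete runs", {
  pr <- run_pipeline(1, configs = "C", config = solver_config("fast"))
  pr$labels <- pr$labels[0, ]
  expect_error(emit_patient_table(pr), "missing configurations")
})

test_that("emit_summary reproduces the cohort aggregations with statistics", {
  labels <- classify_grid(reference_graft_grid())
  out <- emit_summary(labels, selection = reference_selection_counts(),
                      path_prefix = tempfile())
  s <- out$summary
  expect_equal(unname(s$counts), c(14L, 9L, 37L))
  an <- s$category_rates[s$category_rates$category == "anaortic", ]
  expect_equal(an$flagged / an$n_configs, 7 / 8)
  expect_equal(nrow(out$selection_tests), nrow(reference_selection_counts()))
})

test_that("the command-line interface answers stats and classify queries", {
  cli <- system.file("cli", "graftflow", package = "graftflow")
  expect_true(file.exists(cli))
  out <- system2("Rscript", c(cli, "stats", "--table", "57,23,41,39"),
                 stdout = TRUE)
  res <- jsonlite::fromJSON(paste(out, collapse = ""))
  expect_equal(res$test, "chi-squared")
  expect_equal(round(res$p, 3), 0.015)
  f <- tempfile(fileext = ".csv")
  write.csv(reference_graft_grid(), f, row.names = FALSE)
  fo <- tempfile(fileext = ".json")
  system2("Rscript", c(cli, "classify", "--metrics", f, "--out", fo))
  labs <- jsonlite::fromJSON(fo)
  expect_equal(sum(labs$label == "unsatisfactory"), 14L)
})
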