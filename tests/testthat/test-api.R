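# User-facing facade and command line.

test_that("log_forward_pass returns the finalized history with activations", {
  h <- traced_history("fig4a")
  expect_s3_class(h, "model_history")
  expect_equal(length(h$groups), 6)
  expect_equal(length(h$entries), 9)
  expect_true(all(vapply(h$entries, function(e) !is.null(e$saved), logical(1))))
})

test_that("which_layers restricts activation payloads but never metadata", {
  fx <- make_fixture("nested_mod", seed = 1)
  h <- log_forward_pass(fx$model, fx$input, which_layers = "relu", seed = 1)
  saved <- Filter(function(e) !is.null(e$saved), h$entries)
  expect_true(all(vapply(saved, `[[`, "", "layer_type") == "relu"))
  expect_length(saved, 3)
  # metadata present for unsaved layers too
  lin <- resolve_layer_key(h, "linear_1_2")
  expect_null(lin$saved)
  expect_equal(lin$module_stack, c("stem", "stem.0"))
  # selectors may also be module addresses or full labels
  h2 <- log_forward_pass(fx$model, fx$input,
                         which_layers = c("stem.0", "add_1_8"), seed = 1)
  expect_length(Filter(function(e) !is.null(e$saved), h2$entries), 2)
  # unresolvable selectors raise
  expect_error(log_forward_pass(fx$model, fx$input, which_layers = "nope_9"),
               "unknown layer key")
  # empty selector: metadata-only
  h3 <- log_forward_pass(fx$model, fx$input, which_layers = NULL, seed = 1)
  expect_true(all(vapply(h3$entries, function(e) is.null(e$saved), logical(1))))
})

test_that("get_model_metadata matches log_forward_pass metadata field for field", {
  fx <- make_fixture("fig4b", seed = 3)
  h1 <- log_forward_pass(fx$model, fx$input, seed = 3)
  h2 <- get_model_metadata(fx$model, fx$input, seed = 3)
  strip <- function(h) {
    h$elapsed <- NULL; h$model_output <- NULL; h$param_store <- NULL
    h$saved_ids <- NULL
    h$entries <- lapply(h$entries, function(e) {
      e$duration <- NULL; e$saved <- NULL; e
    })
    h
  }
  expect_identical(strip(h1), strip(h2))
  expect_true(all(vapply(h2$entries, function(e) is.null(e$saved), logical(1))))
})

test_that("the two-step workflow selects layers from metadata and re-logs them", {
  fx <- make_fixture("nested_mod", seed = 1)
  meta <- get_model_metadata(fx$model, fx$input, seed = 1)
  targets <- select_layers(meta, function(e)
    e$layer_type == "relu" && "linear" %in% e$parent_types)
  labels <- vapply(targets, `[[`, "", "layer_label")
  h <- log_forward_pass(fx$model, fx$input, which_layers = labels, seed = 1)
  saved <- Filter(function(e) !is.null(e$saved), h$entries)
  expect_setequal(vapply(saved, `[[`, "", "layer_label"), labels)
})

test_that("show_model_graph writes a non-empty rendering without saving activations", {
  fx <- make_fixture("nested_mod", seed = 1)
  out <- withr::local_tempfile(fileext = ".dot")
  dot <- show_model_graph(fx$model, fx$input, out = out, seed = 1)
  expect_true(file.exists(out) && file.size(out) > 0)
  expect_valid_dot(readLines(out))
  # depth sweep: non-decreasing node counts with depth
  counts <- vapply(c(1, 2, 4), function(d) {
    src <- show_model_graph(fx$model, fx$input, nesting_depth = d, seed = 1)
    length(grep("\\[.*label=", src))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("facade results are deterministic given model, input and seed", {
  fx <- make_fixture("internal_rand", seed = 6)
  h1 <- log_forward_pass(fx$model, fx$input, seed = 6)
  h2 <- log_forward_pass(fx$model, fx$input, seed = 6)
  expect_identical(h1$model_output, h2$model_output)
  expect_identical(lapply(h1$entries, `[[`, "saved"),
                   lapply(h2$entries, `[[`, "saved"))
})

test_that("the CLI front end covers graph, log, meta and validate", {
  td <- withr::local_tempdir()
  g <- file.path(td, "g.dot")
  expect_equal(cli_main(c("graph", "fixture:fig4a", "--rolled", "--seed", "1",
                          "--out", g)), 0L)
  expect_true(any(grepl("(×2)", readLines(g), fixed = TRUE)))

  j <- file.path(td, "h.json")
  adir <- file.path(td, "acts")
  expect_equal(cli_main(c("log", "fixture:feedforward", "--seed", "2",
                          "--out", j, "--activations", adir)), 0L)
  js <- jsonlite::fromJSON(j, simplifyVector = FALSE)
  expect_equal(length(js$entries), 5)
  man <- jsonlite::fromJSON(file.path(adir, "manifest.json"))
  expect_equal(length(man), 5)

  m <- file.path(td, "meta.json")
  expect_equal(cli_main(c("meta", "fixture:single_op", "--seed", "1",
                          "--out", m)), 0L)
  expect_true(file.exists(m))

  expect_equal(cli_main(c("validate", "fixture:fig4b", "--seed", "1")), 0L)
  expect_equal(cli_main(character(0)), 2L)
  expect_equal(cli_main(c("graph", "fixture:does_not_exist")), 2L)
})

test_that("the CLI reads YAML config files mirroring its options", {
  td <- withr::local_tempdir()
  cfg <- file.path(td, "cfg.yaml")
  out <- file.path(td, "cfg.dot")
  writeLines(c("rolled: true", "seed: 1", sprintf("out: %s", out)), cfg)
  expect_equal(cli_main(c("graph", "fixture:fig4a", "--config", cfg)), 0L)
  expect_true(any(grepl("(×2)", readLines(out), fixed = TRUE)))
})
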