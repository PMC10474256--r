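# Layer nomenclature, module addresses and the ModelHistory lookup surface.

test_that("labels follow {type}_{type_num}_{total_num} with pass suffixes", {
  h <- traced_history("fig4a")
  expect_equal(unname(vapply(h$groups, `[[`, "", "label")),
               c("input_1_1", "cos_1_2", "linear_1_3", "add_1_4", "sin_1_5",
                 "output_1_6"))
  expect_equal(resolve_layer_key(h, "cos_1_2:2")$pass_num, 2L)

  h1 <- traced_history("single_op")
  expect_equal(vapply(h1$groups, `[[`, "", "label")[[2]], "tanh_1_2")

  # a repeated type gets an incremented type ordinal and the right total
  h2 <- traced_history("feedforward")
  lin2 <- resolve_layer_key(h2, "linear_2")
  expect_equal(lin2$layer_label, "linear_2_4")
})

test_that("module addresses resolve at every nesting level that applies", {
  h <- traced_history("alexnet")
  expect_equal(resolve_layer_key(h, "features.3")$layer_label, "conv2d_2_5")
  mp3 <- resolve_layer_key(h, "features.12")
  expect_equal(mp3$layer_type, "maxpool2d")
  expect_equal(mp3$layer_type_num, 3L)
  # also the output of the whole features block
  expect_equal(resolve_layer_key(h, "features")$id, mp3$id)
  expect_setequal(mp3$module_addresses, c("features.12", "features"))
  # model with no modules: no addresses anywhere
  h2 <- traced_history("branching_div")
  expect_true(all(vapply(h2$entries, function(e)
    length(e$module_addresses) == 0, logical(1))))
})

test_that("layer keys resolve by label, truncated label, address and ordinal", {
  h <- traced_history("alexnet")
  expect_equal(h[[-5]]$id, h$entries[[length(h$entries) - 4]]$id)
  expect_equal(h[[1]]$layer_label, "input_1_1")
  expect_equal(resolve_layer_key(h, "conv2d_2")$layer_label, "conv2d_2_5")
  expect_error(resolve_layer_key(h, "relu_99"), "unknown layer key")
  # round trip over every entry and all of its aliases
  for (e in h$entries) {
    expect_equal(resolve_layer_key(h, e$layer_label_w_pass)$id, e$id)
    for (a in e$module_addresses) {
      expect_equal(resolve_layer_key(h, a)$id, e$id)
    }
  }
  # truncated labels are unique by construction
  truncs <- vapply(h$groups, function(g)
    sprintf("%s_%d", h$entries[[g$members[1]]]$layer_type,
            h$entries[[g$members[1]]]$layer_type_num), "")
  expect_equal(anyDuplicated(truncs), 0L)
})

test_that("numeric indexing respects the saved-layer subset", {
  fx <- make_fixture("feedforward", seed = 1)
  h <- log_forward_pass(fx$model, fx$input, which_layers = c("relu"), seed = 1)
  expect_equal(length(h), 1L)
  expect_equal(h[[1]]$layer_type, "relu")
  expect_equal(h[[-1]]$layer_type, "relu")
  # metadata-only histories index over all layers
  h2 <- get_model_metadata(fx$model, fx$input, seed = 1)
  expect_equal(length(h2), 5L)
})

test_that("select_layers answers structural queries in execution order", {
  h <- traced_history("alexnet")
  pools_after_relu <- select_layers(h, function(e)
    e$layer_type == "maxpool2d" && "relu" %in% e$parent_types)
  expect_length(pools_after_relu, 3)
  convs <- select_layers(h, function(e) e$layer_type == "conv2d")
  expect_length(convs, 5)
  expect_equal(vapply(convs, `[[`, integer(1), "layer_type_num"), 1:5)
  expect_length(select_layers(h, function(e) FALSE), 0)
})

test_that("summary totals equal per-entry sums", {
  h <- traced_history("nested_mod")
  ops <- Filter(function(e) !e$is_input && !e$is_output, h$entries)
  expect_equal(h$totals$n_tensors, length(ops))
  expect_equal(h$totals$tensor_bytes,
               sum(vapply(ops, `[[`, numeric(1), "bytes")))
  txt <- summarize_model(h)
  expect_match(txt[1], "NestedNet")
  expect_match(paste(txt, collapse = " "), as.character(h$totals$n_layers))

  # closed form: linear 10 -> 10 with bias has 110 parameters
  w <- nl_parameter(array(0, c(10, 10)))
  b <- nl_parameter(array(0, 10))
  hh <- log_forward_pass(function(x) nn_linear(x, w, b), array(1, c(1, 10)))
  expect_equal(hh$totals$n_params, 110)
})

test_that("tidy and glance give the broom-style tabular views", {
  h <- traced_history("fig4a")
  td <- tidy(h)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 9)
  expect_equal(td$label[1], "input_1_1")
  g <- glance(h)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_layers, 6L)
  expect_equal(g$n_entries, 9L)
})

test_that("the JSON export round-trips entries, edges and groups", {
  h <- traced_history("branching_div")
  js <- jsonlite::fromJSON(export_history_json(h), simplifyVector = FALSE)
  expect_equal(length(js$entries), length(h$entries))
  expect_equal(length(js$groups), length(h$groups))
  expect_equal(js$entries[[5]]$label, "div_1_5")
  args <- vapply(js$edges, `[[`, "", "arg")
  expect_true(all(c("0", "1") %in% args))
})
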