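# Tracing core: wrapping/restoration, logging semantics, module hooks,
# observational transparency.

test_that("wrapping then restoring leaves every routine identical to its original", {
  s <- netlens:::new_trace_session()
  n <- netlens:::wrap_framework_functions(s)
  expect_gt(n, 0)
  # independent count: the curated registry listing
  expect_equal(n, length(framework_ops()))
  expect_gt(length(residual_wrappers()), 0)
  netlens:::restore_framework_functions(s)
  expect_equal(residual_wrappers(), character(0))
  # idempotent
  netlens:::restore_framework_functions(s)
  expect_equal(residual_wrappers(), character(0))
})

test_that("an elementwise op on a traced tensor appends exactly one record", {
  r <- run_traced_forward(function(x) nn_cos(x), array(1:4 / 4, c(2, 2)))
  h <- r$history
  ops <- Filter(function(e) !e$is_input && !e$is_output, h$entries)
  expect_length(ops, 1)
  expect_equal(ops[[1]]$op_name, "cos")
  expect_true(all(vapply(h$entries, function(e) e$duration >= 0, logical(1))))
})

test_that("division records tensor parents at positions 0 and 1", {
  r <- run_traced_forward(function(x) nn_div(nn_cos(x), nn_sin(x)),
                          array(1:4 / 4, c(2, 2)))
  div <- Filter(function(e) e$op_name == "div", r$history$entries)[[1]]
  args <- vapply(div$parents, function(p) as.integer(p$arg), integer(1))
  expect_equal(sort(args), c(0L, 1L))
  # the numerator (cos) is arg 0
  num_id <- div$parents[[which(args == 0)]]$id
  expect_equal(r$history$entries[[num_id]]$op_name, "cos")
})

test_that("tensors created from shape constants are flagged internally generated", {
  r <- run_traced_forward(function(x) nn_add(x, nn_ones(c(2, 2))),
                          array(0, c(2, 2)))
  ones <- Filter(function(e) e$op_name == "ones", r$history$entries)[[1]]
  expect_true(ones$is_internally_generated)
  expect_false(ones$descends_from_input)
  add <- Filter(function(e) e$op_name == "add", r$history$entries)[[1]]
  expect_false(add$is_internally_generated)
})

test_that("identity model yields exactly an input and an output entry", {
  r <- run_traced_forward(function(x) x, array(1, c(2, 2)))
  h <- r$history
  expect_length(h$entries, 2)
  expect_true(h$entries[[1]]$is_input)
  expect_true(h$entries[[2]]$is_output)
  expect_equal(h$entries[[2]]$parents[[1]]$id, h$entries[[1]]$id)
})

test_that("module hooks record nested stacks and per-pass module addresses", {
  # flat model: no modules, empty stacks everywhere
  r <- run_traced_forward(function(x) nn_tanh(x), array(1, c(2, 2)))
  expect_true(all(vapply(r$history$entries, function(e)
    length(e$module_stack) == 0, logical(1))))

  # nested model: an op inside a sequential records both nesting levels
  h <- traced_history("nested_mod")
  lin <- resolve_layer_key(h, "linear_1_2")
  expect_equal(lin$module_stack, c("stem", "stem.0"))

  # module executed twice: distinct pass annotations
  h2 <- traced_history("module_reuse")
  relus <- Filter(function(e) e$layer_type == "relu", h2$entries)
  addrs <- unlist(lapply(relus, `[[`, "module_addresses"))
  expect_setequal(addrs, c("act:1", "act:2"))
})

test_that("traced output is bit-identical to untraced output and trace is restored", {
  for (nm in c("branching_div", "fig4b", "internal_rand")) {
    fx <- make_fixture(nm, seed = 7)
    set.seed(7)
    untraced <- fx$model(fx$input)
    r <- run_traced_forward(fx$model, fx$input, config = list(seed = 7))
    expect_identical(r$output, untraced)
    expect_equal(residual_wrappers(), character(0))
  }
})

test_that("after restoration a forward pass produces no records", {
  fx <- make_fixture("feedforward", seed = 1)
  r <- run_traced_forward(fx$model, fx$input)
  n_before <- length(r$history$entries)
  out <- fx$model(fx$input)   # untraced
  expect_equal(length(r$history$entries), n_before)
  expect_null(attr(out, "nl_barcode"))
})

test_that("an exception inside the model propagates after full restoration", {
  bad <- function(x) { y <- nn_cos(x); stop("deliberate failure") }
  expect_error(run_traced_forward(bad, array(1, c(2, 2))), "deliberate failure")
  expect_equal(residual_wrappers(), character(0))
  # and a fresh session still works
  r <- run_traced_forward(function(x) nn_sin(x), array(1, c(2, 2)))
  expect_length(r$history$entries, 3)
})

test_that("every tensor parent resolves to an earlier entry (barcode soundness)", {
  for (nm in c("fig4a", "branching_div", "tuple_out", "buffer_model")) {
    h <- traced_history(nm)
    pos <- stats::setNames(seq_along(h$entries), names(h$entries))
    for (e in h$entries) {
      for (p in e$parents) {
        expect_true(p$id %in% names(h$entries))
        expect_lt(pos[p$id], pos[e$id])
      }
    }
  }
})

test_that("in-place ops create a fresh entry whose parent is the mutated tensor's entry", {
  h <- traced_history("inplace_op")
  relu <- resolve_layer_key(h, "relu_1")
  expect_true(relu$in_place)
  expect_length(relu$parents, 1)
  expect_equal(h$entries[[relu$parents[[1]]$id]]$op_name, "add")
  expect_equal(relu$layer_type, "relu")   # alias shared with out-of-place form
})

test_that("multi-output ops yield one entry per returned tensor with output indices", {
  h <- traced_history("tuple_out")
  chunks <- Filter(function(e) e$op_name == "chunk", h$entries)
  expect_length(chunks, 2)
  expect_setequal(vapply(chunks, `[[`, integer(1), "output_index"), 0:1)
  expect_equal(chunks[[1]]$duration, chunks[[2]]$duration)
  expect_equal(chunks[[1]]$shape, c(2, 2))
})

test_that("buffers become origin entries flagged is_buffer", {
  h <- traced_history("buffer_model")
  buf <- Filter(function(e) e$is_buffer, h$entries)
  expect_length(buf, 1)
  expect_equal(buf[[1]]$layer_label, "buffer_1_2")
  expect_false(buf[[1]]$descends_from_input)
})
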