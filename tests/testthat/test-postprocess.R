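# Graph post-processing: orphan trimming, distances, branch inference,
# containment repair, recurrence grouping and rolling.  Reachability checks
# use the hand-rolled BFS oracle from the helpers, not the implementation's
# own graph backend.

test_that("orphan trimming removes exactly the dead internal branch", {
  h <- traced_history("orphan_ops")
  expect_equal(unname(vapply(h$entries, `[[`, "", "op_name")),
               c("input", "relu", "output"))
  # post-condition sweep with the BFS oracle
  ed <- history_edges(h)
  from_input <- bfs_reachable(ed, "input_1_1", forward = TRUE)
  to_output <- bfs_reachable(ed, "output_1_3", forward = FALSE)
  for (e in h$entries) {
    expect_true(e$layer_label_w_pass %in% union(from_input, to_output))
  }
})

test_that("pure feedforward chains lose nothing to trimming", {
  h <- traced_history("feedforward")
  expect_length(h$trimmed, 0)
  expect_length(h$entries, 5)
})

test_that("dead-end entries that descend from the input survive trimming", {
  h <- traced_history("cond_branch")
  expect_true("gt_1_4" %in% vapply(h$entries, `[[`, "", "layer_label"))
})

test_that("graph distances are shortest directed path lengths", {
  h <- traced_history("fig4a")
  expect_equal(resolve_layer_key(h, "input_1_1")$dist_from_input, 0L)
  expect_equal(resolve_layer_key(h, "output_1_6")$dist_to_output, 0L)
  expect_equal(resolve_layer_key(h, "cos_1_2:1")$dist_from_input, 1L)
  # against the BFS oracle, for every entry of several fixtures
  for (nm in c("fig4a", "branching_div", "internal_rand", "nested_mod")) {
    hh <- traced_history(nm)
    ed <- history_edges(hh)
    inputs <- vapply(Filter(function(e) e$is_input, hh$entries), `[[`, "",
                     "layer_label_w_pass")
    for (e in hh$entries) {
      d <- bfs_distance(ed, inputs, e$layer_label_w_pass, forward = TRUE)
      expect_equal(e$dist_from_input,
                   if (is.finite(d)) as.integer(d) else NA_integer_,
                   info = paste(nm, e$layer_label_w_pass))
    }
    # shortest-path property along every edge
    for (e in hh$entries) {
      for (p in e$parents) {
        pd <- hh$entries[[p$id]]$dist_from_input
        if (!is.na(pd) && !is.na(e$dist_from_input)) {
          expect_lte(e$dist_from_input, pd + 1L)
        }
      }
    }
  }
})

test_that("if-branch inference marks the Boolean terminal and the branch start", {
  h <- traced_history("cond_branch")
  gt <- resolve_layer_key(h, "gt_1_4")
  expect_true(gt$is_bool_terminal)
  expect_length(gt$children, 0)
  sub <- resolve_layer_key(h, "sub_1_2")
  expect_true(sub$is_branch_start)
  # the branch start is an ancestor of the bool terminal but not of the output
  ed <- history_edges(h)
  anc_gt <- bfs_reachable(ed, "gt_1_4", forward = FALSE)
  anc_out <- bfs_reachable(ed, "output_1_6", forward = FALSE)
  expect_true("sub_1_2" %in% anc_gt)
  expect_false("sub_1_2" %in% anc_out)
  # and its parent is on the path to the output
  expect_true("input_1_1" %in% anc_out)

  # feedforward model: no flags anywhere
  h2 <- traced_history("feedforward")
  expect_false(any(vapply(h2$entries, `[[`, logical(1), "is_bool_terminal")))
  expect_false(any(vapply(h2$entries, `[[`, logical(1), "is_branch_start")))
})

test_that("internally generated entries inherit containment from their nearest input-descended descendant", {
  # noise created inside a submodule and added to the main path
  model <- nn_module("NoiseNet",
    function(self, x) self$modules$blk(x),
    modules = list(blk = nn_module("Block", function(self, x) {
      noise <- nn_mul(nn_rand(c(1, 4)), 0.1)
      nn_add(x, noise)
    })))
  h <- log_forward_pass(model, array(1, c(1, 4)), seed = 1)
  rand_e <- resolve_layer_key(h, "rand_1")
  mul_e <- resolve_layer_key(h, "mul_1")
  expect_equal(rand_e$module_stack, "blk")
  expect_equal(mul_e$module_stack, "blk")
  # brute-force forward-search oracle: nearest descendant with input descent
  ed <- history_edges(h)
  desc <- bfs_reachable(ed, rand_e$layer_label_w_pass, forward = TRUE)
  in_desc <- Filter(function(e) e$descends_from_input &&
                      e$layer_label_w_pass %in% desc, h$entries)
  expect_true("blk" %in% unlist(lapply(in_desc, `[[`, "module_stack")))

  # model without internal tensors: stacks untouched
  h2 <- traced_history("feedforward")
  expect_true(all(vapply(h2$entries, function(e)
    length(e$module_stack) == 0, logical(1))))
})

test_that("shared-parameter layers and their adjacent repeats are grouped", {
  h <- traced_history("fig4a")
  groups <- h$groups
  passes <- stats::setNames(vapply(groups, `[[`, integer(1), "n_pass"),
                            vapply(groups, `[[`, "", "label"))
  expect_equal(passes[["linear_1_3"]], 2L)
  expect_equal(passes[["cos_1_2"]], 2L)
  expect_equal(passes[["add_1_4"]], 2L)
  expect_equal(passes[["sin_1_5"]], 1L)
})

test_that("back-to-back repetition groups but separated repetition does not", {
  h <- traced_history("fig4b")
  passes <- stats::setNames(vapply(h$groups, `[[`, integer(1), "n_pass"),
                            vapply(h$groups, `[[`, "", "label"))
  expect_equal(passes[["cos_1_2"]], 2L)
  expect_equal(passes[["cos_2_6"]], 1L)   # post-tangent occurrence is separate

  h3 <- traced_history("xyz3")
  p3 <- vapply(h3$groups, `[[`, integer(1), "n_pass")
  expect_equal(sort(unname(p3)), c(1L, 1L, 3L, 3L, 3L))  # input, output, 3 loops

  h4 <- traced_history("xyzab")
  expect_true(all(vapply(h4$groups, `[[`, integer(1), "n_pass") == 1L))
})

test_that("models with all-distinct ops have single-pass groups everywhere", {
  h <- traced_history("feedforward")
  expect_true(all(vapply(h$groups, `[[`, integer(1), "n_pass") == 1L))
})

test_that("grouping conserves entries and numbering is topological", {
  for (nm in small_fixtures()) {
    h <- traced_history(nm)
    expect_equal(sum(vapply(h$groups, `[[`, integer(1), "n_pass")),
                 length(h$entries), info = nm)
    # execution order increases along every edge of the unrolled graph
    pos <- stats::setNames(seq_along(h$entries), names(h$entries))
    for (e in h$entries) {
      for (p in e$parents) expect_lt(pos[p$id], pos[e$id])
    }
    # the unrolled graph is acyclic (execution order is a topological order)
    # and layer_total_num increases along first-pass edges
    for (e in h$entries) {
      if (e$pass_num != 1) next
      for (p in e$parents) {
        pe <- h$entries[[p$id]]
        if (pe$pass_num == 1) {
          expect_true(pe$layer_total_num <= e$layer_total_num, info = nm)
        }
      }
    }
  }
})

test_that("rolled edges carry per-pass structure that reproduces the unrolled graph", {
  for (nm in c("fig4a", "fig4b", "xyz3", "feedforward")) {
    h <- traced_history(nm)
    ed <- h$rolled$edges
    # expansion oracle: (group, pass) pairs map back to entries
    entry_of <- list()
    for (e in h$entries) entry_of[[paste(e$same_layer_id, e$pass_num)]] <- e$id
    expanded <- sort(vapply(seq_len(nrow(ed)), function(i) paste(
      entry_of[[paste(ed$src_group[i], ed$src_pass[i])]],
      entry_of[[paste(ed$dst_group[i], ed$dst_pass[i])]],
      ed$arg[i]), ""))
    unrolled <- sort(unname(unlist(lapply(h$entries, function(e)
      vapply(e$parents, function(p) paste(p$id, e$id, p$arg), "")))))
    expect_equal(expanded, unrolled, info = nm)
  }
  # fig4a: the cosine layer's incoming edges differ across passes
  h <- traced_history("fig4a")
  cosg <- resolve_layer_key(h, "cos_1_2")$same_layer_id
  ed <- h$rolled$edges
  incoming <- ed[ed$dst_group == cosg, ]
  src_labels <- vapply(incoming$src_group, function(g)
    h$groups[[g]]$label, "")
  expect_setequal(paste(src_labels, incoming$dst_pass),
                  c("input_1_1 1", "sin_1_5 2"))
  # feedforward: rolled graph isomorphic to unrolled graph
  h2 <- traced_history("feedforward")
  expect_equal(nrow(h2$rolled$edges),
               sum(vapply(h2$entries, function(e) length(e$parents), integer(1))))
})
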