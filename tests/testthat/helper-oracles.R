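# Independent oracles and shared helpers.  The graph-search oracles here are
# hand-rolled (plain BFS over edge lists) so they stay independent of the
# igraph-backed implementation they check.

# -- plain BFS reachability over an edge data.frame (from, to) ---------------
bfs_reachable <- function(edges, starts, forward = TRUE) {
  adj <- if (forward) split(edges$to, edges$from) else split(edges$from, edges$to)
  seen <- unique(starts)
  frontier <- seen
  while (length(frontier) > 0) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

# -- BFS shortest path length (edge count) -----------------------------------
bfs_distance <- function(edges, starts, target, forward = TRUE) {
  adj <- if (forward) split(edges$to, edges$from) else split(edges$from, edges$to)
  dist <- stats::setNames(rep(Inf, 0), character(0))
  frontier <- unique(starts)
  d <- 0
  seen <- character(0)
  while (length(frontier) > 0) {
    if (target %in% frontier) return(d)
    seen <- c(seen, frontier)
    frontier <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    d <- d + 1
  }
  Inf
}

# -- label-level summary of a finalized history, for ground-truth checks -----
history_edges <- function(h) {
  rows <- list()
  for (e in h$entries) {
    for (p in e$parents) {
      pe <- h$entries[[p$id]]
      rows[[length(rows) + 1L]] <- data.frame(
        from = pe$layer_label_w_pass, to = e$layer_label_w_pass,
        arg = as.character(p$arg), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame(from = character(0), to = character(0),
                                       arg = character(0)))
  do.call(rbind, rows)
}

history_nodes <- function(h) {
  flags_of <- function(e) {
    f <- c("is_input", "is_output", "is_buffer", "is_internally_generated",
           "is_bool_terminal", "is_branch_start")
    f[vapply(f, function(k) isTRUE(e[[k]]), logical(1))]
  }
  lapply(unname(h$groups), function(g) {
    firsts <- h$entries[[g$members[1]]]
    addrs <- unlist(lapply(g$members, function(m) h$entries[[m]]$module_addresses))
    list(label = g$label, type = firsts$layer_type, passes = g$n_pass,
         flags = sort(unique(unlist(lapply(g$members, function(m)
           flags_of(h$entries[[m]]))))),
         module_addresses = sort(unique(addrs %||% character(0))))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_matches_ground_truth <- function(h, gt) {
  got_nodes <- history_nodes(h)
  want_nodes <- lapply(gt$nodes, function(n) list(
    label = n$label, type = n$type, passes = as.integer(n$passes),
    flags = sort(unlist(n$flags) %||% character(0)),
    module_addresses = sort(unlist(n$module_addresses) %||% character(0))))
  key <- function(x) x$label
  got_nodes <- got_nodes[order(vapply(got_nodes, key, ""))]
  want_nodes <- want_nodes[order(vapply(want_nodes, key, ""))]
  expect_equal(vapply(got_nodes, key, ""), vapply(want_nodes, key, ""),
               info = gt$name)
  for (i in seq_along(want_nodes)) {
    expect_equal(got_nodes[[i]]$type, want_nodes[[i]]$type, info = gt$name)
    expect_equal(got_nodes[[i]]$passes, want_nodes[[i]]$passes,
                 info = paste(gt$name, want_nodes[[i]]$label))
    expect_equal(got_nodes[[i]]$flags %||% character(0), want_nodes[[i]]$flags,
                 info = paste(gt$name, want_nodes[[i]]$label))
    expect_equal(got_nodes[[i]]$module_addresses, want_nodes[[i]]$module_addresses,
                 info = paste(gt$name, want_nodes[[i]]$label))
  }
  got_e <- history_edges(h)
  got_keys <- sort(paste(got_e$from, got_e$to, got_e$arg))
  want_keys <- sort(vapply(gt$edges, function(e)
    paste(e$from, e$to, e$arg), ""))
  expect_equal(got_keys, want_keys, info = gt$name)
}

# -- memoized traced histories (all layers saved) ----------------------------
.trace_cache <- new.env(parent = emptyenv())
traced_history <- function(name, seed = 1L) {
  key <- paste(name, seed)
  if (is.null(.trace_cache[[key]])) {
    fx <- make_fixture(name, seed = seed)
    .trace_cache[[key]] <- log_forward_pass(fx$model, fx$input, seed = seed)
  }
  .trace_cache[[key]]
}

small_fixtures <- function() setdiff(fixture_names(), "alexnet")

# -- a minimal DOT syntax checker (independent of the emitter) ---------------
# Validates: single digraph block, balanced braces/brackets, properly closed
# quoted strings, and that every statement is a node, edge, subgraph or
# attribute statement.
expect_valid_dot <- function(lines) {
  text <- paste(lines, collapse = "\n")
  chars <- strsplit(text, "")[[1]]
  depth <- 0; brack <- 0; inq <- FALSE; prev <- ""
  for (ch in chars) {
    if (inq) {
      if (ch == "\"" && prev != "\\") inq <- FALSE
    } else {
      if (ch == "\"") inq <- TRUE
      else if (ch == "{") depth <- depth + 1
      else if (ch == "}") { depth <- depth - 1; expect_gte(depth, 0) }
      else if (ch == "[") brack <- brack + 1
      else if (ch == "]") { brack <- brack - 1; expect_gte(brack, 0) }
    }
    prev <- ch
  }
  expect_false(inq)
  expect_equal(depth, 0)
  expect_equal(brack, 0)
  expect_match(lines[1], "^digraph\\s+\\S+\\s*\\{")
  body <- lines[-c(1, length(lines))]
  body <- trimws(body)
  body <- body[nzchar(body)]
  stmt_ok <- grepl(
    "^(subgraph\\s+\\S+\\s*\\{|\\}|(\"[^\"]*\"|[A-Za-z0-9_:.]+)\\s*(->\\s*(\"[^\"]*\"|[A-Za-z0-9_:.]+))?\\s*(\\[[^]]*\\])?;?$|node\\s*\\[[^]]*\\];?$|rankdir=|label(loc|just)?=)",
    body)
  expect_true(all(stmt_ok), info = paste("bad DOT statements:",
                                         paste(body[!stmt_ok], collapse = " | ")))
}
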