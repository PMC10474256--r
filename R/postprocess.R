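# graph_post: transform the raw operation log into the final annotated
# computational graph.

entry_ids <- function(history) names(history$entries)

edge_frame <- function(history) {
  rows <- list()
  for (e in history$entries) {
    for (p in e$parents) {
      rows[[length(rows) + 1L]] <- data.frame(
        from = p$id, to = e$id, arg = as.character(p$arg),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(from = character(0), to = character(0), arg = character(0)))
  }
  do.call(rbind, rows)
}

fill_children <- function(history) {
  for (id in entry_ids(history)) history$entries[[id]]$children <- list()
  for (e in history$entries) {
    for (p in e$parents) {
      history$entries[[p$id]]$children <-
        c(history$entries[[p$id]]$children, list(list(id = e$id, arg = p$arg)))
    }
  }
  history
}

history_igraph <- function(history) {
  ed <- edge_frame(history)
  igraph::graph_from_data_frame(ed, directed = TRUE,
                                vertices = data.frame(name = entry_ids(history)))
}

reachable_from <- function(g, ids, mode) {
  if (length(ids) == 0) return(character(0))
  unique(unlist(lapply(ids, function(i)
    names(igraph::subcomponent(g, i, mode = mode)))))
}

#' Trim orphan operations
#'
#' Removes entries that neither descend from any model input nor contribute to
#' any model output.  Dead-end entries that do descend from the input are
#' kept: they may be the tests of conditional branches.
#'
#' @param history a history object.
#' @return the history without orphan entries.
#' @export
trim_orphans <- function(history) {
  g <- history_igraph(history)
  from_input <- reachable_from(g, history$input_ids, "out")
  to_output <- reachable_from(g, history$output_ids, "in")
  keep <- union(from_input, to_output)
  drop <- setdiff(entry_ids(history), keep)
  if (length(drop)) {
    history$trimmed <- c(history$trimmed, drop)
    history$entries <- history$entries[setdiff(entry_ids(history), drop)]
    for (id in entry_ids(history)) {
      e <- history$entries[[id]]
      e$parents <- Filter(function(p) p$id %in% names(history$entries), e$parents)
      history$entries[[id]] <- e
    }
  }
  fill_children(history)
}

#' Compute graph distances from input and to output
#'
#' Shortest directed path lengths (edge counts) from any input entry
#' (`dist_from_input`) and to any output entry (`dist_to_output`).  Entries
#' not connected in the respective direction get `NA`.
#'
#' @param history a history object (orphans trimmed).
#' @return the history with distances filled in.
#' @export
compute_graph_distances <- function(history) {
  g <- history_igraph(history)
  ids <- entry_ids(history)
  d_in <- if (length(history$input_ids)) {
    suppressWarnings(igraph::distances(g, v = history$input_ids, to = ids, mode = "out"))
  } else matrix(Inf, 0, length(ids), dimnames = list(NULL, ids))
  d_out <- if (length(history$output_ids)) {
    suppressWarnings(igraph::distances(g, v = history$output_ids, to = ids, mode = "in"))
  } else matrix(Inf, 0, length(ids), dimnames = list(NULL, ids))
  for (id in ids) {
    di <- if (nrow(d_in)) min(d_in[, id]) else Inf
    do <- if (nrow(d_out)) min(d_out[, id]) else Inf
    history$entries[[id]]$dist_from_input <- if (is.finite(di)) as.integer(di) else NA_integer_
    history$entries[[id]]$dist_to_output <- if (is.finite(do)) as.integer(do) else NA_integer_
  }
  history
}

#' Infer conditional if-branches
#'
#' Marks entries whose output is a single-element Boolean tensor with no
#' children (`is_bool_terminal`) -- the plausible tests of if-statements --
#' and, walking each terminal's ancestry backwards, flags the first operation
#' of the branch (`is_branch_start`): the entry that is not itself an ancestor
#' of the model output but has a parent that is.
#'
#' @param history a history object with finalized edges.
#' @return the annotated history.
#' @export
infer_conditional_branches <- function(history) {
  g <- history_igraph(history)
  anc_of_output <- reachable_from(g, history$output_ids, "in")
  for (id in entry_ids(history)) {
    e <- history$entries[[id]]
    e$is_bool_terminal <- FALSE
    e$is_branch_start <- FALSE
    history$entries[[id]] <- e
  }
  for (id in entry_ids(history)) {
    e <- history$entries[[id]]
    if (length(e$children) > 0 || e$dtype != "logical" || prod(e$shape) != 1 ||
        e$is_output) next
    history$entries[[id]]$is_bool_terminal <- TRUE
    # backward walk over the terminal's ancestry
    anc <- reachable_from(g, id, "in")
    for (a in anc) {
      if (a %in% anc_of_output) next
      pids <- vapply(history$entries[[a]]$parents, `[[`, "", "id")
      if (any(pids %in% anc_of_output)) {
        history$entries[[a]]$is_branch_start <- TRUE
      }
    }
  }
  history
}

#' Repair module containment of internally generated tensors
#'
#' Operations on tensors created inside the model (and buffers) carry no
#' module containment at logging time, because no ancestor tensor entered a
#' module.  For each such entry this walks its descendants until reaching one
#' that descends from the model input -- whose containment is accurate -- and
#' propagates that module stack backwards.
#'
#' @param history a history object.
#' @return the history with repaired module stacks.
#' @export
fix_internal_module_containment <- function(history) {
  for (id in entry_ids(history)) {
    e <- history$entries[[id]]
    if (isTRUE(e$module_stack_known)) next
    # breadth-first search forward for the nearest input-descended descendant
    frontier <- vapply(e$children, `[[`, "", "id")
    seen <- character(0)
    found <- NULL
    while (length(frontier) > 0 && is.null(found)) {
      nxt <- character(0)
      for (c_id in frontier) {
        ce <- history$entries[[c_id]]
        if (isTRUE(ce$descends_from_input) && isTRUE(ce$module_stack_known)) {
          found <- ce
          break
        }
        nxt <- c(nxt, vapply(ce$children, `[[`, "", "id"))
      }
      seen <- c(seen, frontier)
      frontier <- setdiff(unique(nxt), seen)
    }
    if (!is.null(found)) {
      history$entries[[id]]$module_stack <- found$module_stack
      history$entries[[id]]$module_stack_known <- TRUE
    }
  }
  history
}

## recurrence ----------------------------------------------------------------

op_signature <- function(e) {
  pk <- paste(sort(vapply(e$param_refs, `[[`, "", "id")), collapse = ",")
  lit <- if (length(e$literal_args)) {
    o <- order(names(e$literal_args))
    paste(names(e$literal_args)[o], unlist(e$literal_args)[o],
          sep = "=", collapse = ";")
  } else ""
  paste(e$op_name, e$output_index, pk, lit, sep = "|")
}

new_uf <- function(n) seq_len(n)

uf_find <- function(uf, i) {
  while (uf[i] != i) i <- uf[i]
  i
}

uf_union <- function(uf, i, j) {
  ri <- uf_find(uf, i); rj <- uf_find(uf, j)
  if (ri != rj) uf[max(ri, rj)] <- min(ri, rj)
  uf
}

#' Identify repeated (recurrent) layers
#'
#' Groups operation entries into layers with multiple passes according to
#' three rules: (1) operations applying the same trainable parameters more
#' than once are always passes of one layer; (2) identical operations adjacent
#' to different passes of an already-grouped layer are grouped, applied
#' recursively until fixpoint; (3) parameter-free sequences that repeat
#' back-to-back (a computational loop such as XYZXYZXYZ) are grouped
#' position-wise, while separated repetitions (XYZAXYZBXYZ) are not.
#'
#' @param history a history object.
#' @return the history with `same_layer_id` and `pass_num` assigned.
#' @export
identify_repeated_layers <- function(history) {
  ids <- entry_ids(history)
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  sig <- vapply(history$entries, op_signature, "")
  bookkeeping <- vapply(history$entries, function(e)
    e$is_input || e$is_output || e$is_buffer, logical(1))
  has_param <- vapply(history$entries, function(e) length(e$param_refs) > 0, logical(1))
  uf <- new_uf(n)

  # condition 1: shared trainable parameters
  p_keys <- ifelse(has_param & !bookkeeping, sig, NA_character_)
  for (key in unique(stats::na.omit(p_keys))) {
    members <- which(p_keys == key)
    if (length(members) >= 2) {
      for (m in members[-1]) uf <- uf_union(uf, members[1], m)
    }
  }

  classes <- function(uf) {
    roots <- vapply(seq_len(n), function(i) uf_find(uf, i), integer(1))
    split(seq_len(n), roots)
  }
  adjacency <- function(i, rel) {
    e <- history$entries[[ids[i]]]
    refs <- if (rel == "parents") e$parents else e$children
    unname(idx[vapply(refs, `[[`, "", "id")])
  }

  # condition 2: identical ops adjacent to different passes, to fixpoint
  repeat {
    changed <- FALSE
    for (cls in classes(uf)) {
      if (length(cls) < 2) next
      for (rel in c("parents", "children")) {
        adj_entry <- integer(0); adj_pass <- integer(0)
        for (p in seq_along(cls)) {
          for (a in adjacency(cls[p], rel)) {
            if (a %in% cls || bookkeeping[a]) next
            adj_entry <- c(adj_entry, a); adj_pass <- c(adj_pass, p)
          }
        }
        if (!length(adj_entry)) next
        for (s in unique(sig[adj_entry])) {
          sel <- sig[adj_entry] == s
          cand <- unique(adj_entry[sel])
          if (length(unique(adj_pass[sel])) >= 2 && length(cand) >= 2) {
            roots_before <- unique(vapply(cand, function(i) uf_find(uf, i), integer(1)))
            if (length(roots_before) > 1) {
              for (m in cand[-1]) uf <- uf_union(uf, cand[1], m)
              changed <- TRUE
            }
          }
        }
      }
    }
    if (!changed) break
  }

  # condition 3: parameter-free back-to-back repeating sequences
  roots <- vapply(seq_len(n), function(i) uf_find(uf, i), integer(1))
  in_multi <- roots %in% roots[duplicated(roots)]
  eligible <- !bookkeeping & !has_param & !in_multi
  single_parent <- function(i) {
    ps <- adjacency(i, "parents")
    if (length(ps) == 1) ps else NA_integer_
  }
  single_child <- function(i) {
    cs <- adjacency(i, "children")
    if (length(cs) == 1) cs else NA_integer_
  }
  chain_prev <- rep(NA_integer_, n)
  for (i in which(eligible)) {
    p <- single_parent(i)
    if (!is.na(p) && eligible[p] && identical(single_child(p), i)) chain_prev[i] <- p
  }
  starts <- which(eligible & is.na(chain_prev))
  for (s in starts) {
    chain <- s
    repeat {
      nxt <- single_child(chain[length(chain)])
      if (is.na(nxt) || !eligible[nxt] || !identical(chain_prev[nxt], chain[length(chain)])) break
      chain <- c(chain, nxt)
    }
    uf <- group_tandem_repeats(uf, chain, sig[chain])
  }

  # finalize groups in execution order of their first member
  roots <- vapply(seq_len(n), function(i) uf_find(uf, i), integer(1))
  firsts <- vapply(split(seq_len(n), roots), min, integer(1))
  ord <- order(firsts)
  group_of_root <- stats::setNames(seq_along(ord), names(firsts)[ord])
  history$groups <- vector("list", length(ord))
  for (k in seq_along(ord)) {
    members <- sort(split(seq_len(n), roots)[[ord[k]]])
    gid <- sprintf("g%03d", k)
    history$groups[[k]] <- list(id = gid, members = ids[members],
                                n_pass = length(members))
    for (p in seq_along(members)) {
      history$entries[[ids[members[p]]]]$same_layer_id <- gid
      history$entries[[ids[members[p]]]]$pass_num <- p
    }
  }
  names(history$groups) <- vapply(history$groups, `[[`, "", "id")
  history
}

# earliest start wins; at a start, maximize total repeated span, breaking
# span ties toward the smallest (primitive) period
group_tandem_repeats <- function(uf, chain, sigs) {
  n <- length(chain)
  i <- 1L
  while (i <= n) {
    best <- NULL
    for (p in seq_len((n - i + 1L) %/% 2L)) {
      r <- 1L
      while (i + (r + 1L) * p - 1L <= n &&
             all(sigs[i + r * p + 0:(p - 1L)] == sigs[i + 0:(p - 1L)])) {
        r <- r + 1L
      }
      if (r >= 2L) {
        span <- p * r
        if (is.null(best) || span > best$span) best <- list(p = p, r = r, span = span)
      }
    }
    if (is.null(best)) { i <- i + 1L; next }
    for (off in 0:(best$p - 1L)) {
      for (rep_k in seq_len(best$r - 1L)) {
        uf <- uf_union(uf, chain[i + off], chain[i + rep_k * best$p + off])
      }
    }
    i <- i + best$span
  }
  uf
}

#' Roll the graph across passes
#'
#' Collapses all passes of each layer group into a single rolled node, keeping
#' the full per-pass edge structure: each rolled edge records the source and
#' destination group, their pass numbers and the argument position, so the
#' unrolled adjacency can be reconstructed exactly.
#'
#' @param history a history object with `same_layer_id` assigned.
#' @return the history with a `rolled` element (`nodes`, `edges`).
#' @export
roll_graph <- function(history) {
  rows <- list()
  for (e in history$entries) {
    for (p in e$parents) {
      pe <- history$entries[[p$id]]
      rows[[length(rows) + 1L]] <- data.frame(
        src_group = pe$same_layer_id, dst_group = e$same_layer_id,
        src_pass = pe$pass_num, dst_pass = e$pass_num,
        arg = as.character(p$arg), stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(src_group = character(0), dst_group = character(0),
               src_pass = integer(0), dst_pass = integer(0), arg = character(0))
  nodes <- lapply(history$groups, function(g)
    list(id = g$id, members = g$members, pass_count = g$n_pass))
  history$rolled <- list(nodes = nodes, edges = edges)
  history
}
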