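# viz: render the annotated computational graph to Graphviz DOT source
# (and optionally an image when the `dot` binary is available), rolled or
# unrolled, at a chosen module-nesting depth.

STYLE <- list(
  input_fill = "#98FB98", output_fill = "#FF9999", param_fill = "#D3D3D3",
  buffer_fill = "#F5F5F5", bool_fill = "#FFFF99", default_fill = "white",
  fontname = "Helvetica", rankdir = "TB"
)

#' Visualization options
#'
#' @param nesting_depth positive integer number of module-nesting levels to
#'   expand, or `Inf` for unlimited.
#' @param rolled collapse all passes of a layer into one node?
#' @param orientation rank direction, `"TB"` (input at top) or `"LR"`.
#' @param format output format: `"dot"`, or `"png"`/`"pdf"`/`"svg"` when the
#'   Graphviz `dot` binary is available.
#' @param out optional output file path.
#' @return a list of class `vis_options`.
#' @export
vis_options <- function(nesting_depth = Inf, rolled = FALSE,
                        orientation = "TB", format = "dot", out = NULL) {
  stopifnot(is.infinite(nesting_depth) || nesting_depth >= 1)
  structure(list(nesting_depth = nesting_depth, rolled = rolled,
                 orientation = orientation, format = format, out = out),
            class = "vis_options")
}

dq <- function(x) sprintf("\"%s\"", gsub("\"", "\\\\\"", x))

fmt_pass_set <- function(p) {
  p <- sort(unique(p))
  runs <- split(p, cumsum(c(1, diff(p) != 1)))
  paste(vapply(runs, function(r)
    if (length(r) == 1) as.character(r) else sprintf("%d-%d", r[1], r[length(r)]),
    ""), collapse = ",")
}

# counts of entries per module address
module_entry_counts <- function(history) {
  tab <- table(unlist(lapply(history$entries, `[[`, "module_stack")))
  if (length(tab) == 0) return(integer(0))
  stats::setNames(as.integer(tab), names(tab))
}

#' Collapse modules beyond a nesting depth
#'
#' Computes the view used by [render_graph()]: modules nested deeper than
#' `depth` collapse into single nodes; modules within the depth that contain
#' several operations become boxes labelled with their address and class.
#'
#' @param history a `model_history`.
#' @param depth positive integer or `Inf`.
#' @return list with `nodes` (visible node ids, each mapping to the atom ids
#'   it contains), `node_kind`, and `boxes` (addresses of modules drawn as
#'   enclosing boxes).
#' @export
collapse_modules_at_depth <- function(history, depth = Inf) {
  atoms <- lapply(history$entries, function(e)
    list(id = e$id, stack = e$module_stack))
  collapse_atoms(history, atoms, depth)
}

collapse_atoms <- function(history, atoms, depth) {
  cnt <- module_entry_counts(history)
  multi <- function(addr) !is.na(cnt[addr]) && cnt[addr] > 1
  nodes <- list()       # vis id -> atom ids
  node_kind <- list()   # vis id -> "entry" | "module"
  node_stack <- list()  # vis id -> enclosing box addresses
  for (a in atoms) {
    if (is.finite(depth) && length(a$stack) >= depth) {
      vid <- paste0("module:", a$stack[depth])
      kind <- "module"
      stack <- a$stack[seq_len(depth - 1)]
    } else {
      vid <- a$id
      kind <- "entry"
      stack <- a$stack
    }
    # single-operation modules are drawn as rectangular nodes, not boxes
    stack <- Filter(multi, stack)
    nodes[[vid]] <- c(nodes[[vid]], list(a$id))
    node_kind[[vid]] <- kind
    node_stack[[vid]] <- stack
  }
  boxes <- unique(unlist(node_stack))
  list(nodes = nodes, node_kind = node_kind, node_stack = node_stack,
       boxes = boxes %||% character(0))
}

node_body <- function(history, e, pass_count = 1, rolled = FALSE) {
  lines <- e$layer_label
  if (rolled && pass_count > 1) lines <- sprintf("%s (×%d)", lines, pass_count)
  if (!rolled && pass_count > 1) lines <- e$layer_label_w_pass
  if (e$is_branch_start) lines <- paste0("IF\n", lines)
  lines <- c(lines, sprintf("%s  %s", paste(e$shape, collapse = "×"),
                            fmt_bytes(e$bytes)))
  if (length(e$param_refs)) {
    lines <- c(lines, sprintf("params: %s", paste(vapply(e$param_refs, function(p)
      paste(p$shape, collapse = "×"), ""), collapse = ", ")))
  }
  if (length(e$module_addresses)) {
    lines <- c(lines, paste(e$module_addresses, collapse = ", "))
  }
  paste(lines, collapse = "\\n")
}

node_attrs <- function(history, e, bottom_mod) {
  fill <- STYLE$default_fill
  if (length(e$param_refs)) fill <- STYLE$param_fill
  if (e$is_buffer) fill <- STYLE$buffer_fill
  if (e$is_bool_terminal) fill <- STYLE$bool_fill
  if (e$is_input) fill <- STYLE$input_fill
  if (e$is_output) fill <- STYLE$output_fill
  shape <- if (bottom_mod) "box" else "ellipse"
  style <- c("filled", if (e$is_internally_generated || e$is_buffer) "dashed")
  sprintf("shape=%s, style=%s, fillcolor=%s, fontname=%s",
          shape, dq(paste(style, collapse = ",")), dq(fill), dq(STYLE$fontname))
}

graph_header <- function(history) {
  t <- history$totals
  sprintf("%s\\n%d tensors (%s)\\n%s params (%s)",
          history$model_name, t$n_tensors, fmt_bytes(t$tensor_bytes),
          format(t$n_params, big.mark = ","), fmt_bytes(t$param_bytes))
}

#' Render the computational graph as Graphviz DOT
#'
#' Applies the full visual code: green input and red output nodes, gray for
#' layers with trainable parameters, light-gray buffers, dashed outlines for
#' internally generated tensors, yellow Boolean-terminal nodes with a bold
#' `IF` at the branch start, rectangles for single-operation modules and
#' ellipses otherwise, boxes around multi-operation modules (to the chosen
#' nesting depth), argument-position labels on edges of non-commutative
#' multi-parent operations, per-pass `In`/`Out` labels on rolled edges that
#' differ across passes, and a header with the model totals.
#'
#' @param history a `model_history`.
#' @param options a [vis_options()] list.
#' @return the DOT source, invisibly; written/rendered to `options$out` if
#'   set (falls back to DOT source with a warning when no rendering backend
#'   is available).
#' @export
render_graph <- function(history, options = vis_options()) {
  dot <- if (options$rolled) dot_rolled(history, options) else dot_unrolled(history, options)
  if (!is.null(options$out)) {
    if (identical(options$format, "dot")) {
      writeLines(dot, options$out)
    } else {
      dot_bin <- Sys.which("dot")
      if (nzchar(dot_bin)) {
        src <- tempfile(fileext = ".dot")
        writeLines(dot, src)
        system2(dot_bin, c(paste0("-T", options$format), src, "-o", options$out))
      } else {
        warning("no Graphviz 'dot' binary found; writing DOT source instead")
        writeLines(dot, options$out)
      }
    }
  }
  invisible(dot)
}

dot_preamble <- function(history, options) {
  c("digraph model {",
    sprintf("  rankdir=%s;", options$orientation),
    sprintf("  labelloc=\"t\"; labeljust=\"l\"; label=%s;", dq(graph_header(history))),
    sprintf("  node [fontname=%s];", dq(STYLE$fontname)))
}

# emit cluster boxes recursively; node_lines is named by vis id
emit_clusters <- function(history, view, node_lines, prefix, indent) {
  out <- character(0)
  boxes_here <- Filter(function(b) {
    parts <- strsplit(b, ".", fixed = TRUE)[[1]]
    parent <- if (length(parts) == 1) "" else paste(parts[-length(parts)], collapse = ".")
    identical(parent, prefix)
  }, view$boxes)
  nodes_here <- names(view$nodes)[vapply(names(view$nodes), function(v) {
    st <- view$node_stack[[v]]
    identical(if (length(st)) st[length(st)] else "", prefix)
  }, logical(1))]
  pad <- strrep("  ", indent)
  for (v in nodes_here) out <- c(out, paste0(pad, node_lines[[v]]))
  for (b in boxes_here) {
    cls <- history$module_info[[b]] %||% "Module"
    out <- c(out,
             sprintf("%ssubgraph %s {", pad, dq(paste0("cluster_", b))),
             sprintf("%s  label=%s; style=rounded;", pad, dq(sprintf("%s (%s)", b, cls))),
             emit_clusters(history, view, node_lines, b, indent + 1),
             paste0(pad, "}"))
  }
  out
}

bottom_level_module <- function(history, e) {
  if (length(e$module_stack) == 0) return(FALSE)
  module_entry_counts(history)[e$module_stack[length(e$module_stack)]] == 1
}

dot_unrolled <- function(history, options) {
  depth <- options$nesting_depth
  view <- collapse_modules_at_depth(history, depth)
  node_lines <- list()
  for (vid in names(view$nodes)) {
    if (view$node_kind[[vid]] == "module") {
      addr <- sub("^module:", "", vid)
      cls <- history$module_info[[addr]] %||% "Module"
      node_lines[[vid]] <- sprintf("%s [shape=box3d, style=filled, fillcolor=%s, label=%s];",
                                   dq(vid), dq(STYLE$param_fill),
                                   dq(sprintf("%s\\n(%s)", addr, cls)))
    } else {
      e <- history$entries[[vid]]
      g <- history$groups[[e$same_layer_id]]
      node_lines[[vid]] <- sprintf("%s [%s, label=%s];", dq(vid),
                                   node_attrs(history, e, bottom_level_module(history, e)),
                                   dq(node_body(history, e, g$n_pass, rolled = FALSE)))
    }
  }
  atom_to_vis <- list()
  for (vid in names(view$nodes)) for (a in view$nodes[[vid]]) atom_to_vis[[a]] <- vid
  edges <- character(0)
  seen_e <- character(0)
  for (e in history$entries) {
    n_tensor_parents <- length(e$parents)
    for (p in e$parents) {
      u <- atom_to_vis[[p$id]]; v <- atom_to_vis[[e$id]]
      if (is.null(u) || is.null(v) || identical(u, v)) next
      lab <- NULL
      info <- the$op_info[[e$op_name]]
      if (!is.null(info) && !info$commutative && n_tensor_parents > 1 &&
          view$node_kind[[v]] == "entry") {
        lab <- if (is.character(p$arg)) p$arg else sprintf("arg %s", p$arg)
      }
      key <- paste(u, v, lab %||% "")
      if (key %in% seen_e) next
      seen_e <- c(seen_e, key)
      edges <- c(edges, sprintf("  %s -> %s%s;", dq(u), dq(v),
                                if (is.null(lab)) "" else sprintf(" [label=%s]", dq(lab))))
    }
  }
  c(dot_preamble(history, options),
    emit_clusters(history, view, node_lines, "", 1),
    edges, "}")
}

dot_rolled <- function(history, options) {
  # one node per layer group; edges annotated with active pass numbers when
  # a layer's connectivity differs across passes
  rolled <- history$rolled
  node_lines <- character(0)
  for (g in history$groups) {
    e <- history$entries[[g$members[1]]]
    node_lines <- c(node_lines,
      sprintf("  %s [%s, label=%s];", dq(g$id),
              node_attrs(history, e, bottom_level_module(history, e)),
              dq(node_body(history, e, g$n_pass, rolled = TRUE))))
  }
  ed <- rolled$edges
  edges <- character(0)
  if (nrow(ed)) {
    keys <- paste(ed$src_group, ed$dst_group, ed$arg)
    for (k in unique(keys)) {
      sub <- ed[keys == k, ]
      src <- sub$src_group[1]; dst <- sub$dst_group[1]
      labs <- character(0)
      dst_total <- history$groups[[dst]]$n_pass
      src_total <- history$groups[[src]]$n_pass
      # annotate only when the layer's edges differ across its passes
      dst_other <- ed[ed$dst_group == dst & ed$src_group != src, ]
      if (dst_total > 1 && (length(unique(sub$dst_pass)) < dst_total || nrow(dst_other) > 0)) {
        labs <- c(labs, sprintf("In %s", fmt_pass_set(sub$dst_pass)))
      }
      src_other <- ed[ed$src_group == src & ed$dst_group != dst, ]
      if (src_total > 1 && (length(unique(sub$src_pass)) < src_total || nrow(src_other) > 0)) {
        labs <- c(labs, sprintf("Out %s", fmt_pass_set(sub$src_pass)))
      }
      e_dst <- history$entries[[history$groups[[dst]]$members[1]]]
      info <- the$op_info[[e_dst$op_name]]
      if (!is.null(info) && !info$commutative && length(e_dst$parents) > 1) {
        labs <- c(labs, if (suppressWarnings(is.na(as.integer(sub$arg[1]))))
          sub$arg[1] else sprintf("arg %s", sub$arg[1]))
      }
      edges <- c(edges, sprintf("  %s -> %s%s;", dq(src), dq(dst),
                                if (length(labs)) sprintf(" [label=%s]", dq(paste(labs, collapse = "; "))) else ""))
    }
  }
  c(dot_preamble(history, options), node_lines, edges, "}")
}
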