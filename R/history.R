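# naming_index: layer nomenclature, module addresses, and the ModelHistory
# lookup / summary surface.

#' Assign default layer labels
#'
#' Every layer gets a label `{layer_type}_{layer_type_num}_{layer_total_num}`:
#' the type token, the ordinal among layers of that type, and the ordinal
#' among all layers.  Numbering follows the execution order of each layer's
#' first pass (topologically consistent), with the model input counted as
#' layer 1.  Entries belonging to a multi-pass layer additionally carry a
#' `:{pass}` suffix, e.g. `linear_1_3:2` for the second pass.
#'
#' @param history a history object with layer groups assigned.
#' @return the history with labels filled in.
#' @export
assign_layer_labels <- function(history) {
  type_counts <- integer(0)
  for (k in seq_along(history$groups)) {
    g <- history$groups[[k]]
    first <- history$entries[[g$members[1]]]
    token <- first$type_token
    type_counts[token] <- (if (is.na(type_counts[token])) 0L else type_counts[token]) + 1L
    label <- sprintf("%s_%d_%d", token, type_counts[token], k)
    history$groups[[k]]$label <- label
    history$groups[[k]]$layer_type <- token
    history$groups[[k]]$layer_type_num <- unname(type_counts[token])
    history$groups[[k]]$layer_total_num <- k
    for (m in g$members) {
      e <- history$entries[[m]]
      e$layer_type <- token
      e$layer_type_num <- unname(type_counts[token])
      e$layer_total_num <- k
      e$layer_label <- label
      e$layer_label_w_pass <- if (g$n_pass > 1) sprintf("%s:%d", label, e$pass_num) else label
      history$entries[[m]] <- e
    }
  }
  history
}

#' Assign module addresses to module-output layers
#'
#' An entry that produced the tensor returned by a module receives that
#' module's dotted address, at every nesting level for which this holds (the
#' last operation of `features.12` can simultaneously be the output of
#' `features`).  Modules executed more than once get pass-qualified addresses
#' (`address:pass`).
#'
#' @param history a history object.
#' @return the history with `module_addresses` per entry and an
#'   address-to-entry lookup.
#' @export
assign_module_addresses <- function(history) {
  multi_pass_mod <- table(unlist(lapply(history$entries, function(e)
    vapply(e$module_output_addresses, `[[`, "", "address"))))
  for (id in entry_ids(history)) {
    e <- history$entries[[id]]
    addrs <- character(0)
    for (mo in e$module_output_addresses) {
      qualified <- if (!is.na(multi_pass_mod[mo$address]) &&
                       multi_pass_mod[mo$address] > 1) {
        sprintf("%s:%d", mo$address, mo$pass)
      } else mo$address
      addrs <- c(addrs, qualified)
    }
    history$entries[[id]]$module_addresses <- addrs
    history$entries[[id]]$module_addresses_raw <-
      vapply(e$module_output_addresses, `[[`, "", "address")
  }
  history
}

build_lookup <- function(history) {
  lk <- list()
  for (id in entry_ids(history)) {
    e <- history$entries[[id]]
    lk[[e$layer_label_w_pass]] <- id
    if (!e$layer_label %in% names(lk) || e$pass_num == 1) lk[[e$layer_label]] <- id
    trunc <- sprintf("%s_%d", e$layer_type, e$layer_type_num)
    if (!trunc %in% names(lk) || e$pass_num == 1) lk[[trunc]] <- id
    for (a in e$module_addresses) lk[[a]] <- id
    for (a in e$module_addresses_raw) if (!a %in% names(lk)) lk[[a]] <- id
    lk[[id]] <- id
  }
  history$lookup <- lk
  history
}

compute_totals <- function(history) {
  ops <- Filter(function(e) !e$is_input && !e$is_output, history$entries)
  params <- list()
  for (e in history$entries) for (p in e$param_refs) params[[p$id]] <- p
  history$totals <- list(
    n_entries = length(history$entries),
    n_tensors = length(ops),
    tensor_bytes = sum(vapply(ops, `[[`, numeric(1), "bytes")),
    n_params = sum(vapply(params, `[[`, numeric(1), "n")),
    param_bytes = 8 * sum(vapply(params, `[[`, numeric(1), "n")),
    n_layers = length(history$groups)
  )
  history
}

#' Finalize a raw trace into a ModelHistory
#'
#' Runs the full post-processing pipeline on a raw trace: orphan trimming,
#' graph distances, conditional-branch inference, module-containment repair,
#' recurrent-layer grouping, graph rolling, layer labelling, module addresses,
#' lookup maps and totals.
#'
#' @param raw the raw history from [run_traced_forward()].
#' @return a `model_history` object.
#' @export
finalize_history <- function(raw) {
  history <- raw
  history$trimmed <- character(0)
  history <- fill_children(history)
  history <- trim_orphans(history)
  history <- compute_graph_distances(history)
  history <- infer_conditional_branches(history)
  history <- fix_internal_module_containment(history)
  history <- identify_repeated_layers(history)
  history <- roll_graph(history)
  history <- assign_layer_labels(history)
  history <- assign_module_addresses(history)
  history <- build_lookup(history)
  history <- compute_totals(history)
  history$saved_ids <- entry_ids(history)
  class(history) <- "model_history"
  history
}

#' Resolve a layer key to an entry
#'
#' Accepts any of: the full label (`relu_3_6`), the truncated label
#' (`relu_3`), a pass-qualified label (`conv2d_3_7:2`), a module address
#' (`features.12`), or an integer ordinal in execution order (negative counts
#' from the end; when only a subset of layers is saved, integer indexing is
#' over the saved layers only).
#'
#' @param history a `model_history`.
#' @param key layer key.
#' @return the layer entry (a list).
#' @export
resolve_layer_key <- function(history, key) {
  if (is.numeric(key)) {
    pool <- history$saved_ids
    n <- length(pool)
    i <- as.integer(key)
    if (i < 0) i <- n + i + 1L
    if (is.na(i) || i < 1L || i > n) {
      stop(sprintf("layer index %s out of range (1..%d)", key, n))
    }
    return(history$entries[[pool[i]]])
  }
  key <- as.character(key)
  id <- history$lookup[[key]]
  if (is.null(id)) {
    cand <- utils::head(names(history$lookup)[
      startsWith(names(history$lookup), substr(key, 1, max(3, nchar(key) - 2)))], 5)
    if (length(cand) == 0) {
      cand <- utils::head(agrep(key, names(history$lookup), value = TRUE,
                                max.distance = 0.3), 5)
    }
    stop(sprintf("unknown layer key '%s'%s", key,
                 if (length(cand)) paste0("; did you mean: ",
                                          paste(cand, collapse = ", "), "?") else ""))
  }
  history$entries[[id]]
}

#' @export
`[[.model_history` <- function(x, i) resolve_layer_key(x, i)

#' @export
length.model_history <- function(x) length(x$saved_ids)

#' Select layers by predicate
#'
#' Returns, in execution order, every entry for which `predicate(entry)` is
#' true.  The entry passed to the predicate carries `parent_types` and
#' `child_types` fields for convenient structural queries (e.g. all pooling
#' layers with a ReLU parent).
#'
#' @param history a `model_history`.
#' @param predicate function of one entry returning a logical.
#' @return list of layer entries.
#' @export
select_layers <- function(history, predicate) {
  out <- list()
  for (id in entry_ids(history)) {
    e <- history$entries[[id]]
    e$parent_types <- vapply(e$parents, function(p)
      history$entries[[p$id]]$layer_type, "")
    e$child_types <- vapply(e$children, function(p)
      history$entries[[p$id]]$layer_type, "")
    if (isTRUE(predicate(e))) out[[length(out) + 1L]] <- e
  }
  out
}

fmt_bytes <- function(b) {
  if (b >= 1024^2) sprintf("%.1f MB", b / 1024^2)
  else if (b >= 1024) sprintf("%.1f KB", b / 1024)
  else sprintf("%d B", as.integer(b))
}

#' Summarize a model history
#'
#' @param history a `model_history`.
#' @return character vector of summary lines.
#' @export
summarize_model <- function(history) {
  t <- history$totals
  c(sprintf("ModelHistory for %s", history$model_name),
    sprintf("  layers: %d (%d entries incl. passes)", t$n_layers, t$n_entries),
    sprintf("  tensors computed: %d, total size %s", t$n_tensors, fmt_bytes(t$tensor_bytes)),
    sprintf("  trainable parameters: %s in %s",
            format(t$n_params, big.mark = ","), fmt_bytes(t$param_bytes)),
    sprintf("  forward pass time: %.4f s", history$elapsed))
}

#' @export
print.model_history <- function(x, ...) {
  cat(summarize_model(x), sep = "\n")
  invisible(x)
}

#' One row per layer entry
#'
#' @param x a `model_history`.
#' @param ... unused.
#' @return a tibble with one row per (layer, pass) entry in execution order.
#' @method tidy model_history
#' @export
tidy.model_history <- function(x, ...) {
  rows <- lapply(x$entries, function(e) tibble::tibble(
    label = e$layer_label_w_pass,
    layer = e$layer_label,
    type = e$layer_type,
    pass = e$pass_num,
    shape = paste(e$shape, collapse = "x"),
    bytes = e$bytes,
    n_params = sum(vapply(e$param_refs, `[[`, numeric(1), "n")),
    duration = e$duration,
    dist_from_input = e$dist_from_input,
    dist_to_output = e$dist_to_output,
    module_address = paste(e$module_addresses, collapse = ";"),
    is_input = e$is_input, is_output = e$is_output,
    is_buffer = e$is_buffer,
    is_internally_generated = e$is_internally_generated,
    is_bool_terminal = e$is_bool_terminal,
    is_branch_start = e$is_branch_start,
    saved = !is.null(e$saved)))
  do.call(rbind, rows)
}

#' One-row model summary
#'
#' @param x a `model_history`.
#' @param ... unused.
#' @return a one-row tibble of model totals.
#' @method glance model_history
#' @export
glance.model_history <- function(x, ...) {
  t <- x$totals
  tibble::tibble(model = x$model_name, n_layers = t$n_layers,
                 n_entries = t$n_entries, n_tensors = t$n_tensors,
                 tensor_bytes = t$tensor_bytes, n_params = t$n_params,
                 param_bytes = t$param_bytes, elapsed = x$elapsed)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Export a history to the JSON interchange schema
#'
#' Serializes entries (labels, flags, shapes, parameter metadata, module
#' addresses), edges with argument positions, and layer groups, so the
#' post-processed graph can be consumed without the tensor framework.
#'
#' @param history a `model_history`.
#' @param path output file; if `NULL` the JSON string is returned.
#' @return the path, or the JSON string when `path` is `NULL`.
#' @export
export_history_json <- function(history, path = NULL) {
  entries <- lapply(unname(history$entries), function(e) list(
    id = e$id, label = e$layer_label_w_pass, layer = e$layer_label,
    type = e$layer_type, pass = e$pass_num,
    layer_type_num = e$layer_type_num, layer_total_num = e$layer_total_num,
    shape = e$shape, dtype = e$dtype, bytes = e$bytes,
    params = lapply(e$param_refs, function(p) list(shape = p$shape, n = p$n)),
    duration = e$duration,
    dist_from_input = e$dist_from_input, dist_to_output = e$dist_to_output,
    module_stack = e$module_stack, module_addresses = e$module_addresses,
    flags = list(is_input = e$is_input, is_output = e$is_output,
                 is_buffer = e$is_buffer,
                 is_internally_generated = e$is_internally_generated,
                 is_bool_terminal = e$is_bool_terminal,
                 is_branch_start = e$is_branch_start)))
  doc <- list(
    model = history$model_name,
    totals = history$totals,
    elapsed = history$elapsed,
    entries = entries,
    edges = edge_frame(history),
    groups = lapply(unname(history$groups), function(g)
      list(id = g$id, label = g$label, members = g$members, passes = g$n_pass))
  )
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  path
}
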