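# validation: algorithmically verify saved activations by re-executing each
# layer's function on the saved values of its parents, from the model outputs
# back to the origin layers, with random-substitution counter-checks.

TOL_REL <- 1e-5
TOL_ABS <- 1e-8

tensors_close <- function(a, b) {
  if (is.null(a) || is.null(b)) return(FALSE)
  if (!identical(dim(a) %||% length(a), dim(b) %||% length(b))) return(FALSE)
  if (is.logical(a) || is.logical(b)) return(identical(as.vector(a), as.vector(b)))
  all(abs(a - b) <= TOL_ABS + TOL_REL * abs(b))
}

max_deviation <- function(a, b) {
  if (is.null(a) || is.null(b) || length(a) != length(b)) return(Inf)
  if (is.logical(a) || is.logical(b)) return(sum(as.vector(a) != as.vector(b)))
  max(abs(as.vector(a) - as.vector(b)))
}

# rebuild the argument list of an entry's call, substituting parent values
rebuild_args <- function(history, e, parent_values) {
  args <- list()
  nms <- character(0)
  for (ca in e$call_args) {
    val <- switch(ca$kind,
      parent = parent_values[[ca$ref]],
      param = get(ca$ref, envir = history$param_store),
      literal = ca$value)
    args <- c(args, list(val))
    nms <- c(nms, if (is.character(ca$key)) ca$key else "")
  }
  names(args) <- nms
  args
}

reexecute_entry <- function(history, e, parent_values) {
  if (e$is_input || e$is_buffer) return(e$saved)
  if (e$is_output) return(parent_values[[e$parents[[1]]$id]])
  fn <- the$originals[[e$op_name]]
  args <- rebuild_args(history, e, parent_values)
  old_rng <- get_rng_state()
  on.exit(set_rng_state(old_rng))
  set_rng_state(e$rng_state)
  out <- do.call(fn, args)
  if (is.list(out)) out[[e$output_index + 1L]] else out
}

input_insensitive_structural <- function(e) {
  if (prod(e$shape) == 0) return(TRUE)
  lits <- Filter(function(ca) ca$kind == "literal", e$call_args)
  if (e$op_name == "mul" &&
      any(vapply(lits, function(ca)
        is.numeric(ca$value) && all(ca$value == 0), logical(1)))) return(TRUE)
  if (e$op_name == "clamp") {
    v <- lapply(e$call_args, `[[`, "value")
    names(v) <- vapply(e$call_args, function(ca) as.character(ca$key), "")
    if (!is.null(v$min) && !is.null(v$max) && isTRUE(v$min == v$max)) return(TRUE)
  }
  FALSE
}

substitute_values <- function(history, e, seed, draw) {
  vals <- list()
  for (p in e$parents) {
    pe <- history$entries[[p$id]]
    set.seed((abs(seed) * 7919L + sum(utf8ToInt(pe$layer_label)) * 131L + draw) %%
               2147483647L)
    s <- stats::sd(as.vector(pe$saved))
    if (!is.finite(s) || s == 0) s <- 1
    v <- array(stats::rnorm(prod(pe$shape), sd = s), pe$shape)
    if (is.logical(pe$saved)) v <- v > 0
    vals[[p$id]] <- v
  }
  vals
}

#' Validate one layer's saved activation
#'
#' Re-executes the layer's function on the saved values of its parent layers
#' and checks that the result reproduces the saved activation (relative
#' tolerance `1e-5`, absolute `1e-8`); then re-executes on random substitute
#' parent values (standard normal, scaled to each parent's standard
#' deviation) and checks that the result differs -- skipped for
#' input-insensitive operations such as multiplication by zero, detected
#' structurally and by an empirical two-draw fallback.  Stochastic operations
#' are replayed under the RNG state captured at logging time.
#'
#' @param history a `model_history` with all activations saved.
#' @param target_label any valid key of the target layer.
#' @param seed integer seed for the substitute generator.
#' @return `TRUE`/`FALSE`, with attributes `check` and `max_dev` on failure.
#' @export
validate_layer <- function(history, target_label, seed = 0L) {
  e <- resolve_layer_key(history, target_label)
  if (is.null(e$saved)) {
    stop(sprintf("no saved activation for layer '%s'; validation requires all intermediate tensors", e$layer_label_w_pass))
  }
  parent_vals <- list()
  for (p in e$parents) {
    pe <- history$entries[[p$id]]
    if (is.null(pe$saved)) {
      stop(sprintf("no saved activation for parent layer '%s'", pe$layer_label_w_pass))
    }
    parent_vals[[p$id]] <- pe$saved
  }
  re <- reexecute_entry(history, e, parent_vals)
  if (!tensors_close(re, e$saved)) {
    return(structure(FALSE, check = "recompute", max_dev = max_deviation(re, e$saved)))
  }
  if (length(parent_vals) == 0 || e$is_output || e$is_input || e$is_buffer) {
    return(TRUE)
  }
  if (!input_insensitive_structural(e)) {
    out1 <- reexecute_entry(history, e, substitute_values(history, e, seed, 1L))
    out2 <- reexecute_entry(history, e, substitute_values(history, e, seed, 2L))
    if (!isTRUE(all.equal(out1, out2, tolerance = 1e-12))) {
      # op is input-sensitive: a substitute must change the output
      if (tensors_close(out1, e$saved) && tensors_close(out2, e$saved)) {
        return(structure(FALSE, check = "perturbation",
                         max_dev = max_deviation(out1, e$saved)))
      }
    }
  }
  TRUE
}

#' Validate every saved activation of a history
#'
#' Walks the graph from the model outputs back to the parentless origin
#' layers, applying [validate_layer()] to each entry.  Returns `TRUE` iff
#' every layer passes; the per-layer results are attached as a report.
#'
#' @param history a `model_history` with all activations saved.
#' @param seed integer seed.
#' @return logical; attribute `report` holds a tibble (layer, pass, check,
#'   max deviation).
#' @export
validate_history <- function(history, seed = 0L) {
  rows <- list()
  ok <- TRUE
  frontier <- history$output_ids
  seen <- character(0)
  while (length(frontier) > 0) {
    nxt <- character(0)
    for (id in frontier) {
      if (id %in% seen) next
      seen <- c(seen, id)
      e <- history$entries[[id]]
      res <- validate_layer(history, id, seed)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        label = e$layer_label_w_pass,
        passed = isTRUE(res),
        check = if (isTRUE(res)) NA_character_ else attr(res, "check"),
        max_dev = if (isTRUE(res)) 0 else attr(res, "max_dev"))
      ok <- ok && isTRUE(res)
      nxt <- c(nxt, vapply(e$parents, `[[`, "", "id"))
    }
    frontier <- setdiff(unique(nxt), seen)
  }
  structure(ok, report = do.call(rbind, rows))
}

#' Trace a model and validate all saved activations
#'
#' Runs its own traced forward pass with every intermediate activation saved,
#' then validates each layer by re-execution, beginning at the model outputs
#' and recursing to the parentless origin layers.
#'
#' @param model an [nn_module()] or plain function.
#' @param input a tensor or list of tensors.
#' @param seed integer seed used for the forward pass and the substitute
#'   generator.
#' @return logical; attribute `report` as in [validate_history()].
#' @export
validate_saved_activations <- function(model, input, seed = 0L) {
  history <- log_forward_pass(model, input, which_layers = "all", seed = seed)
  validate_history(history, seed = seed)
}

#' Write a validation report as JSON
#'
#' @param result return value of [validate_history()] or
#'   [validate_saved_activations()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
export_validation_json <- function(result, path) {
  rep <- attr(result, "report")
  doc <- list(passed = isTRUE(as.logical(result)), layers = rep)
  writeLines(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                           null = "null")), path)
  invisible(path)
}
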