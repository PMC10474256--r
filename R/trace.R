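# trace_core: transiently wrap every tensor-returning routine of the
# framework, log each operation executed during one forward pass, and restore
# the framework untouched afterwards (including on error).

new_trace_session <- function(config = list()) {
  s <- new.env(parent = emptyenv())
  s$active <- FALSE
  s$depth <- 0L
  s$records <- list()
  s$entry_by_barcode <- new.env(parent = emptyenv())
  s$buffer_entries <- new.env(parent = emptyenv())
  s$param_store <- new.env(parent = emptyenv())
  s$wrapped <- list()
  s$module_stack <- character(0)
  s$module_pass <- new.env(parent = emptyenv())
  s$module_info <- list()
  s$hook_handles <- character(0)
  s$barcode_counter <- 0L
  s$stats <- list(skipped = 0L)
  s$config <- config
  s
}

fresh_barcode <- function(session) {
  session$barcode_counter <- session$barcode_counter + 1L
  sprintf("bc%06d", session$barcode_counter)
}

get_rng_state <- function() {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    return(NULL)   # never consume RNG: tracing must be observationally silent
  }
  get(".Random.seed", envir = globalenv(), inherits = FALSE)
}

set_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

canonical_literal <- function(v) {
  if (is.null(v)) return("NULL")
  if (tensor_like(v) && length(v) > 16) {
    return(sprintf("array[%s]#%.8g", paste(dim(v), collapse = "x"), sum(v)))
  }
  paste(deparse(unclass(v), control = "exact"), collapse = "")
}

#' Wrap the framework's tensor-returning routines for logging
#'
#' Replaces every routine in the framework registry by a logging wrapper that
#' records the call (inputs, outputs, timing, module stack, RNG state) before
#' delegating to the original.  Originals are retained so that
#' [restore_framework_functions()] can return the framework to its exact
#' pre-trace state.  Nested calls between wrapped routines are merged into the
#' outermost user-visible operation.
#'
#' @param session a trace session (internal).
#' @return invisibly, the number of wrapped routines.
#' @keywords internal
wrap_framework_functions <- function(session) {
  if (length(session$wrapped) > 0) stop("trace session already active")
  ok <- TRUE
  for (nm in names(the$op_info)) {
    orig <- tryCatch(get(nm, envir = the$ops, inherits = FALSE),
                     error = function(e) NULL)
    if (is.null(orig)) { ok <- FALSE; break }
    session$wrapped[[nm]] <- orig
    assign(nm, make_wrapper(nm, orig, the$op_info[[nm]], session), envir = the$ops)
  }
  if (!ok) {
    restore_framework_functions(session)
    stop("failed to resolve routine for wrapping; framework restored")
  }
  invisible(length(session$wrapped))
}

#' Remove the logging wrappers
#'
#' Returns every wrapped routine to its original definition.  Calling it twice
#' is a no-op; after restoration, forward passes produce no further records.
#'
#' @param session a trace session (internal).
#' @return invisibly `NULL`.
#' @keywords internal
restore_framework_functions <- function(session) {
  for (nm in names(session$wrapped)) {
    assign(nm, session$wrapped[[nm]], envir = the$ops)
  }
  session$wrapped <- list()
  session$active <- FALSE
  invisible(NULL)
}

#' Routines still carrying a logging wrapper
#'
#' Sweeps the framework registry and reports any routine whose current binding
#' differs from its original definition.  After any tracing session (even one
#' that raised an error) this must be empty.
#'
#' @return character vector of routine names (empty when fully restored).
#' @export
residual_wrappers <- function() {
  names(the$originals)[!vapply(names(the$originals), function(nm)
    identical(get(nm, envir = the$ops), the$originals[[nm]]), logical(1))]
}

make_wrapper <- function(name, orig, info, session) {
  force(name); force(orig); force(info); force(session)
  function(...) {
    if (!isTRUE(session$active)) return(orig(...))
    args <- list(...)   # force promises first: ops evaluated in argument
                        # position are their own user-visible calls
    session$depth <- session$depth + 1L
    on.exit(session$depth <- session$depth - 1L)
    if (session$depth > 1L) return(do.call(orig, args))   # merge nested calls
    rng <- get_rng_state()
    t0 <- proc.time()[["elapsed"]]
    out <- do.call(orig, args)
    dur <- proc.time()[["elapsed"]] - t0
    log_operation(session, name, info, args, out, dur, rng)
  }
}

ensure_buffer_entry <- function(session, x) {
  bid <- attr(x, "nl_buffer_id")
  id <- session$buffer_entries[[bid]]
  if (!is.null(id)) return(id)
  rec <- origin_record(session, "buffer", x)
  rec$is_buffer <- TRUE
  rec$module_stack_known <- FALSE
  rec$saved <- detach_tensor(x)
  id <- append_record(session, rec)
  session$buffer_entries[[bid]] <- id
  id
}

origin_record <- function(session, op_name, x) {
  list(op_name = op_name, type_token = op_name, output_index = 0L,
       n_outputs = 1L, barcode = fresh_barcode(session), duration = 0,
       parents = list(), call_args = list(), literal_args = list(),
       param_refs = list(), module_stack = character(0),
       module_stack_known = TRUE, module_output_addresses = list(),
       rng_state = NULL, in_place = FALSE,
       is_input = FALSE, is_output = FALSE, is_buffer = FALSE,
       is_internally_generated = FALSE,
       shape = dim(x) %||% length(x), dtype = tensor_dtype(x),
       bytes = tensor_bytes(x), saved = NULL,
       descends_from_input = FALSE)
}

append_record <- function(session, rec) {
  i <- length(session$records) + 1L
  rec$id <- sprintf("e%d", i)
  session$records[[i]] <- rec
  session$entry_by_barcode[[rec$barcode]] <- i
  rec$id
}

#' Log one executed tensor operation
#'
#' Called from inside a routine wrapper during an active session.  Classifies
#' every argument as a tensor parent (by barcode), trainable parameter, buffer
#' or literal, appends one record per returned tensor (tagged with a fresh
#' barcode), and returns the -- now tagged -- outputs.  Calls returning no
#' tensor are skipped and counted in the session statistics.
#'
#' @return the op's output, with tensors tagged.
#' @keywords internal
log_operation <- function(session, op_name, info, args, out, duration, rng_state) {
  nms <- names(args) %||% rep("", length(args))
  call_args <- vector("list", length(args))
  parents <- list()
  param_refs <- list()
  literal_args <- list()
  descends <- FALSE
  pos <- -1L
  for (i in seq_along(args)) {
    a <- args[[i]]
    key <- if (nzchar(nms[i])) nms[i] else { pos <- pos + 1L; pos }
    if (tensor_like(a) && !is.null(attr(a, "nl_barcode"))) {
      pi <- session$entry_by_barcode[[attr(a, "nl_barcode")]]
      prec <- session$records[[pi]]
      parents <- c(parents, list(list(id = prec$id, arg = key)))
      descends <- descends || isTRUE(prec$descends_from_input)
      call_args[[i]] <- list(kind = "parent", key = key, ref = prec$id)
    } else if (tensor_like(a) && is_param(a)) {
      pid <- attr(a, "nl_param_id")
      assign(pid, detach_tensor(a), envir = session$param_store)
      param_refs <- c(param_refs, list(list(id = pid, shape = dim(a), n = length(a))))
      call_args[[i]] <- list(kind = "param", key = key, ref = pid)
    } else if (tensor_like(a) && is_buffer_tensor(a)) {
      bid <- ensure_buffer_entry(session, a)
      parents <- c(parents, list(list(id = bid, arg = key)))
      call_args[[i]] <- list(kind = "parent", key = key, ref = bid)
    } else {
      literal_args[[as.character(key)]] <- canonical_literal(a)
      call_args[[i]] <- list(kind = "literal", key = key, value = a)
    }
  }
  outs <- if (info$multi_output && is.list(out)) out else list(out)
  is_tensor_out <- vapply(outs, tensor_like, logical(1))
  if (!any(is_tensor_out)) {
    session$stats$skipped <- session$stats$skipped + 1L
    return(out)
  }
  internally_generated <- info$creates ||
    (length(parents) == 0 && !any(vapply(call_args, function(ca)
      identical(ca$kind, "parent"), logical(1))))
  if (info$creates) descends <- FALSE
  for (k in seq_along(outs)) {
    if (!is_tensor_out[k]) next
    o <- outs[[k]]
    rec <- origin_record(session, op_name, o)
    rec$type_token <- info$type_token
    rec$output_index <- k - 1L
    rec$n_outputs <- length(outs)
    rec$duration <- duration
    rec$parents <- parents
    rec$call_args <- call_args
    rec$literal_args <- literal_args
    rec$param_refs <- param_refs
    rec$rng_state <- if (info$stochastic) rng_state else NULL
    rec$in_place <- info$in_place
    rec$is_internally_generated <- internally_generated
    rec$descends_from_input <- descends
    rec$module_stack <- if (descends) session$module_stack else character(0)
    rec$module_stack_known <- descends
    rec$saved <- detach_tensor(o)
    append_record(session, rec)
    attr(o, "nl_barcode") <- rec$barcode
    outs[[k]] <- o
  }
  if (info$multi_output && is.list(out)) outs else outs[[1L]]
}

#' Attach forward hooks to a model's module tree
#'
#' Walks the (possibly nested) module tree, assigns each submodule its dotted
#' address (e.g. `features.3`), and enables entry/exit tracking so that every
#' subsequently logged operation records the modules it executed inside.
#' Models without submodules yield empty module stacks.
#'
#' @param model an [nn_module()] (plain-function models are accepted and
#'   yield no hooks).
#' @return invisibly, a character vector of hooked module addresses
#'   (the hook handles).
#' @export
attach_module_hooks <- function(model) {
  if (!inherits(model, "nn_module")) return(invisible(character(0)))
  sess <- the$session
  mods <- walk_modules(model)
  for (addr in names(mods)) {
    mods[[addr]]$address <- addr
    mods[[addr]]$hooked <- TRUE
    if (!is.null(sess)) sess$module_info[[addr]] <- mods[[addr]]$class_name
  }
  if (!is.null(sess)) sess$hook_handles <- names(mods)
  invisible(names(mods))
}

detach_module_hooks <- function(model) {
  if (!inherits(model, "nn_module")) return(invisible(NULL))
  for (self in walk_modules(model)) {
    self$hooked <- FALSE
  }
  invisible(NULL)
}

#' Run one traced forward pass
#'
#' Wraps the framework, runs the model on the input with every tensor
#' operation logged, and restores the framework afterwards -- also when the
#' model raises an error.  The model's own code is executed unchanged, and the
#' returned model output is identical to an untraced run under the same RNG
#' state.
#'
#' @param model an [nn_module()] or a plain function of its input tensor(s).
#' @param input a tensor or list of tensors.
#' @param config list of options (`seed`, ...).
#' @return list with elements `output` (the model output) and `history`
#'   (a raw, un-postprocessed trace; see [finalize_history()]).
#' @export
run_traced_forward <- function(model, input, config = list()) {
  if (!is.null(the$session) && isTRUE(the$session$active)) {
    stop("a trace session is already active")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  session <- new_trace_session(config)
  the$session <- session
  wrap_framework_functions(session)
  attach_module_hooks(model)
  on.exit({
    restore_framework_functions(session)
    detach_module_hooks(model)
    the$session <- NULL
  })
  inputs <- if (is.list(input)) input else list(input)
  tagged <- lapply(inputs, function(x) {
    if (is.null(dim(x))) dim(x) <- length(x)
    rec <- origin_record(session, "input", x)
    rec$is_input <- TRUE
    rec$descends_from_input <- TRUE
    rec$saved <- detach_tensor(x)
    append_record(session, rec)
    attr(x, "nl_barcode") <- rec$barcode
    x
  })
  session$active <- TRUE
  t0 <- proc.time()[["elapsed"]]
  out <- do.call(model, tagged)
  elapsed <- proc.time()[["elapsed"]] - t0
  session$active <- FALSE
  outs <- if (is.list(out)) out else list(out)
  for (o in outs) {
    bc <- attr(o, "nl_barcode")
    if (is.null(bc)) next
    prec <- session$records[[session$entry_by_barcode[[bc]]]]
    rec <- origin_record(session, "output", o)
    rec$is_output <- TRUE
    rec$parents <- list(list(id = prec$id, arg = 0L))
    rec$descends_from_input <- prec$descends_from_input
    rec$saved <- detach_tensor(o)   # returned outside all modules: empty stack
    append_record(session, rec)
  }
  model_name <- if (inherits(model, "nn_module")) module_self(model)$class_name else "model"
  entries <- session$records
  names(entries) <- vapply(entries, `[[`, "", "id")
  raw <- structure(list(
    model_name = model_name,
    entries = entries,
    input_ids = names(entries)[vapply(entries, `[[`, logical(1), "is_input")],
    output_ids = names(entries)[vapply(entries, `[[`, logical(1), "is_output")],
    elapsed = elapsed,
    param_store = session$param_store,
    module_info = session$module_info,
    stats = session$stats,
    seed = config$seed %||% NA
  ), class = "model_history_raw")
  list(output = if (is.list(out)) lapply(out, detach_tensor) else detach_tensor(out),
       history = raw)
}
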