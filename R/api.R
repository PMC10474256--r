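# api_cli: user-facing facade mirroring the trace -> post-process ->
# name/index -> (optionally) visualize pipeline, plus a command-line front
# end.

resolve_which_layers <- function(history, which_layers) {
  ids <- entry_ids(history)
  if (is.function(which_layers)) {
    sel <- select_layers(history, which_layers)
    return(vapply(sel, `[[`, "", "id"))
  }
  if (is.null(which_layers) || length(which_layers) == 0) return(character(0))
  if (identical(which_layers, "all")) return(ids)
  out <- character(0)
  types <- unique(vapply(history$entries, `[[`, "", "layer_type"))
  for (token in which_layers) {
    if (token %in% types) {
      out <- c(out, ids[vapply(history$entries, function(e)
        identical(e$layer_type, token), logical(1))])
    } else {
      e <- resolve_layer_key(history, token)   # errors on unknown selector
      grp <- history$groups[[e$same_layer_id]]
      out <- c(out, unlist(grp$members))
    }
  }
  ids[ids %in% out]
}

#' Log one forward pass of a model
#'
#' The core entry point: runs a traced forward pass, post-processes the
#' computational graph, assigns the layer nomenclature, and returns a
#' [`model_history`][finalize_history()] with saved activations for the
#' selected layers (metadata is always recorded for all layers).  Optionally
#' writes a visualization of the graph.
#'
#' @param model an [nn_module()] or a plain function of its input tensor(s),
#'   written in the package's tensor operations.
#' @param input a tensor (array) or list of tensors.
#' @param which_layers `"all"` (default), a character vector of layer
#'   selectors (full/truncated labels, module addresses, or type tokens such
#'   as `"relu"`), a predicate function over entries, or `NULL`/empty to save
#'   no activations.
#' @param seed optional integer seed applied before the forward pass.
#' @param visualize `"none"`, `"unrolled"` or `"rolled"`.
#' @param vis_path,nesting_depth visualization output path and module depth.
#' @return a `model_history`.
#' @export
log_forward_pass <- function(model, input, which_layers = "all", seed = NULL,
                             visualize = "none", vis_path = NULL,
                             nesting_depth = Inf) {
  res <- run_traced_forward(model, input, config = list(seed = seed))
  history <- finalize_history(res$history)
  history$model_output <- res$output
  keep <- resolve_which_layers(history, which_layers)
  for (id in setdiff(entry_ids(history), keep)) {
    history$entries[[id]]$saved <- NULL
  }
  history$saved_ids <- if (length(keep) > 0 && length(keep) < length(entry_ids(history))) {
    keep
  } else {
    entry_ids(history)
  }
  if (!identical(visualize, "none")) {
    render_graph(history, vis_options(nesting_depth = nesting_depth,
                                      rolled = identical(visualize, "rolled"),
                                      out = vis_path))
  }
  history
}

#' Extract model metadata without saving activations
#'
#' Identical to [log_forward_pass()] with saving disabled: the returned
#' history carries the full graph, labels and per-layer metadata but no
#' activation payloads.  Useful to programmatically select layers before a
#' saving run.
#'
#' @inheritParams log_forward_pass
#' @return a `model_history` with no saved activations.
#' @export
get_model_metadata <- function(model, input, seed = NULL) {
  log_forward_pass(model, input, which_layers = character(0), seed = seed)
}

#' Visualize a model's computational graph
#'
#' Traces the model, discards activations, and renders the graph.
#'
#' @inheritParams log_forward_pass
#' @param rolled collapse passes of recurrent layers into single nodes?
#' @param out output file (DOT source, or an image format when available).
#' @param format `"dot"`, `"png"`, `"pdf"` or `"svg"`.
#' @return the DOT source, invisibly.
#' @export
show_model_graph <- function(model, input, nesting_depth = Inf, rolled = FALSE,
                             out = NULL, format = "dot", seed = NULL) {
  history <- get_model_metadata(model, input, seed = seed)
  render_graph(history, vis_options(nesting_depth = nesting_depth,
                                    rolled = rolled, format = format, out = out))
}

#' Write saved activations to an archive directory
#'
#' One array file per saved layer, keyed by the full layer label, plus a JSON
#' manifest mapping each label to shape, dtype and byte size.
#'
#' @param history a `model_history`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_activations <- function(history, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (id in entry_ids(history)) {
    e <- history$entries[[id]]
    if (is.null(e$saved)) next
    key <- gsub(":", "-", e$layer_label_w_pass)
    saveRDS(e$saved, file.path(dir, paste0(key, ".rds")))
    manifest[[e$layer_label_w_pass]] <- list(
      shape = e$shape, dtype = e$dtype, bytes = e$bytes,
      file = paste0(key, ".rds"))
  }
  writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE)),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

## command line --------------------------------------------------------------

cli_usage <- function() {
  paste(
    "usage: netlens <graph|log|validate|meta> <model-spec> [options]",
    "  model-spec  fixture:<name>   (see fixture_names())",
    "              <file.R>:<fun>   fun(seed) must return list(model, input)",
    "  options     --seed N  --out PATH  --format dot|json  --depth D",
    "              --rolled | --unrolled  --layers a,b,c  --activations DIR",
    "              --config FILE.yaml", sep = "\n")
}

parse_cli_args <- function(argv) {
  opts <- list(seed = 1L, out = NULL, format = NULL, depth = Inf,
               rolled = FALSE, layers = "all", activations = NULL)
  pos <- character(0)
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    take <- function() { i <<- i + 1L; if (i > length(argv)) stop("missing value for ", a); argv[i] }
    if (a == "--seed") opts$seed <- as.integer(take())
    else if (a == "--out") opts$out <- take()
    else if (a == "--format") opts$format <- take()
    else if (a == "--depth") opts$depth <- as.numeric(take())
    else if (a == "--rolled") opts$rolled <- TRUE
    else if (a == "--unrolled") opts$rolled <- FALSE
    else if (a == "--layers") opts$layers <- strsplit(take(), ",")[[1]]
    else if (a == "--activations") opts$activations <- take()
    else if (a == "--config") {
      cfg <- yaml::read_yaml(take())
      for (k in intersect(names(cfg), names(opts))) opts[[k]] <- cfg[[k]]
    }
    else if (startsWith(a, "--")) stop("unknown option ", a)
    else pos <- c(pos, a)
    i <- i + 1L
  }
  list(opts = opts, pos = pos)
}

cli_load_model <- function(spec, seed) {
  if (startsWith(spec, "fixture:")) {
    fx <- make_fixture(sub("^fixture:", "", spec), seed = seed)
    return(list(model = fx$model, input = fx$input))
  }
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !file.exists(parts[1])) {
    stop("model spec must be fixture:<name> or <file.R>:<fun>")
  }
  env <- new.env()
  sys.source(parts[1], envir = env)
  fn <- get(parts[2], envir = env)
  fn(seed)
}

#' Command-line entry point
#'
#' Subcommands: `graph` (render the computational graph), `log` (trace and
#' export metadata, optionally an activation archive), `validate` (trace and
#' validate saved activations), `meta` (metadata-only export).  Exit status 0
#' on success, 1 on validation failure, 2 on usage errors.
#'
#' @param argv character vector of arguments (as from
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit code, invisibly.
#' @export
cli_main <- function(argv) {
  code <- tryCatch({
    parsed <- parse_cli_args(argv)
    pos <- parsed$pos; opts <- parsed$opts
    if (length(pos) < 1 || !pos[1] %in% c("graph", "log", "validate", "meta")) {
      message(cli_usage()); return(invisible(2L))
    }
    if (length(pos) < 2) { message(cli_usage()); return(invisible(2L)) }
    loaded <- cli_load_model(pos[2], opts$seed)
    switch(pos[1],
      graph = {
        out <- opts$out %||% "model.dot"
        show_model_graph(loaded$model, loaded$input, nesting_depth = opts$depth,
                         rolled = opts$rolled, out = out,
                         format = opts$format %||% "dot", seed = opts$seed)
        0L
      },
      log = {
        h <- log_forward_pass(loaded$model, loaded$input,
                              which_layers = opts$layers, seed = opts$seed)
        export_history_json(h, opts$out %||% "model_history.json")
        if (!is.null(opts$activations)) write_activations(h, opts$activations)
        0L
      },
      meta = {
        h <- get_model_metadata(loaded$model, loaded$input, seed = opts$seed)
        export_history_json(h, opts$out %||% "model_metadata.json")
        0L
      },
      validate = {
        ok <- validate_saved_activations(loaded$model, loaded$input,
                                         seed = opts$seed)
        if (!is.null(opts$out)) export_validation_json(ok, opts$out)
        if (isTRUE(as.logical(ok))) 0L else 1L
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(code)
}
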