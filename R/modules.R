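# Lightweight module system: named, nestable units that own parameters,
# buffers and submodules.  A module is callable; during a tracing session a
# forward hook fires on entry/exit, maintaining the module stack and marking
# which entries are module outputs.

#' Define a module
#'
#' Modules organise model code into named, possibly nested units, own
#' trainable parameters and (non-trainable) buffers, and are callable like
#' functions.  During tracing, entering and leaving a module pushes and pops
#' its address on the module stack, and the tensor a module returns is marked
#' as that module's output.
#'
#' @param class_name class label of the module (shown in visualizations).
#' @param forward function `(self, ...)` implementing the computation; access
#'   parameters as `self$params$name`, buffers as `self$buffers$name` and
#'   submodules as `self$modules$name` (callable).
#' @param params named list of arrays; each is tagged via [nl_parameter()].
#' @param buffers named list of arrays stored with the module but not
#'   trainable.
#' @param modules named list of submodules.
#' @return a callable of class `nn_module`.
#' @export
nn_module <- function(class_name, forward, params = list(), buffers = list(),
                      modules = list()) {
  self <- new.env(parent = emptyenv())
  self$class_name <- class_name
  self$params <- lapply(params, function(p) if (is_param(p)) p else nl_parameter(p))
  self$buffers <- lapply(buffers, function(b) {
    if (is.null(dim(b))) dim(b) <- length(b)
    the$buffer_counter <- the$buffer_counter + 1L
    attr(b, "nl_buffer_id") <- sprintf("b%04d", the$buffer_counter)
    b
  })
  self$modules <- modules
  self$forward <- forward
  self$address <- NA_character_   # assigned by attach_module_hooks
  self$hooked <- FALSE
  f <- function(...) module_call(self, ...)
  class(f) <- c("nn_module", "function")
  attr(f, "self") <- self
  f
}

module_self <- function(m) attr(m, "self")

#' Sequential container
#'
#' Children are addressed by zero-based position (`"0"`, `"1"`, ...),
#' mirroring the indexing convention of sequential containers in deep-learning
#' frameworks, and applied in order.
#'
#' @param ... submodules, in application order.
#' @param class_name class label.
#' @return an `nn_module`.
#' @export
nn_sequential <- function(..., class_name = "Sequential") {
  mods <- list(...)
  names(mods) <- as.character(seq_along(mods) - 1L)
  nn_module(class_name, function(self, x) {
    for (m in self$modules) x <- m(x)
    x
  }, modules = mods)
}

## single-op module wrappers ------------------------------------------------

#' Single-operation modules
#'
#' Convenience constructors for modules that perform exactly one tensor
#' operation ("bottom-level" modules, drawn as rectangles in visualizations).
#' Weights are initialised from the current RNG state with a scaled-normal
#' scheme (sd `1/sqrt(fan_in)`).
#'
#' @param in_features,out_features,in_ch,out_ch,kernel,stride,padding,output_size,p
#'   layer configuration.
#' @return an `nn_module`.
#' @name op-modules
NULL

init_weight <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = 1 / sqrt(fan_in)), dims)
}

#' @rdname op-modules
#' @export
nn_linear_mod <- function(in_features, out_features) {
  nn_module("Linear", function(self, x)
    nn_linear(x, self$params$weight, self$params$bias),
    params = list(weight = init_weight(c(out_features, in_features), in_features),
                  bias = init_weight(out_features, in_features)))
}

#' @rdname op-modules
#' @export
nn_conv2d_mod <- function(in_ch, out_ch, kernel, stride = 1L, padding = 0L) {
  fan <- in_ch * kernel * kernel
  m <- nn_module("Conv2d", function(self, x)
    nn_conv2d(x, self$params$weight, self$params$bias,
              stride = self$stride, padding = self$padding),
    params = list(weight = init_weight(c(out_ch, in_ch, kernel, kernel), fan),
                  bias = init_weight(out_ch, fan)))
  s <- module_self(m); s$stride <- stride; s$padding <- padding
  m
}

#' @rdname op-modules
#' @export
nn_relu_mod <- function() nn_module("ReLU", function(self, x) nn_relu(x))

#' @rdname op-modules
#' @export
nn_maxpool2d_mod <- function(kernel, stride = kernel) {
  m <- nn_module("MaxPool2d", function(self, x)
    nn_maxpool2d(x, self$kernel, self$stride))
  s <- module_self(m); s$kernel <- kernel; s$stride <- stride
  m
}

#' @rdname op-modules
#' @export
nn_adaptive_avgpool2d_mod <- function(output_size) {
  m <- nn_module("AdaptiveAvgPool2d", function(self, x)
    nn_adaptive_avgpool2d(x, self$output_size))
  s <- module_self(m); s$output_size <- output_size
  m
}

#' @rdname op-modules
#' @export
nn_dropout_mod <- function(p = 0.5) {
  m <- nn_module("Dropout", function(self, x) nn_dropout(x, self$p))
  s <- module_self(m); s$p <- p
  m
}

## calling ------------------------------------------------------------------

module_call <- function(self, ...) {
  args <- list(...)   # force promises before entering the module, so ops in
                      # argument position are logged outside this module
  sess <- the$session
  tracked <- !is.null(sess) && isTRUE(sess$active) && isTRUE(self$hooked) &&
    !is.na(self$address) && nzchar(self$address)
  if (tracked) {
    pass_n <- (sess$module_pass[[self$address]] %||% 0L) + 1L
    sess$module_pass[[self$address]] <- pass_n
    sess$module_stack <- c(sess$module_stack, self$address)
    on.exit(sess$module_stack <- sess$module_stack[-length(sess$module_stack)])
  }
  out <- do.call(self$forward, c(list(self), args))
  if (tracked) note_module_output(sess, out, self$address, pass_n)
  out
}

note_module_output <- function(sess, out, address, pass_n) {
  outs <- if (is.list(out)) out else list(out)
  for (o in outs) {
    bc <- attr(o, "nl_barcode")
    if (is.null(bc)) next
    i <- sess$entry_by_barcode[[bc]]
    if (is.null(i)) next
    rec <- sess$records[[i]]
    rec$module_output_addresses <- c(rec$module_output_addresses,
                                     list(list(address = address, pass = pass_n)))
    sess$records[[i]] <- rec
  }
}

# depth-first walk assigning dotted addresses; returns named list of selves
walk_modules <- function(model, prefix = "") {
  self <- module_self(model)
  out <- list()
  if (nzchar(prefix)) out[[prefix]] <- self
  for (nm in names(self$modules)) {
    addr <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    out <- c(out, walk_modules(self$modules[[nm]], addr))
  }
  out
}
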