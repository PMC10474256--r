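# Tensor-operation framework: plain R arrays plus a registry of
# array-returning routines that models are written in.  Tracing works by
# transiently swapping the registry bindings for logging wrappers, so model
# code never changes.

# package-global state
the <- new.env(parent = emptyenv())

#' Create a tensor
#'
#' Tensors in netlens are ordinary R arrays (double or logical) carrying a
#' `dim` attribute.  This helper coerces numeric data to that shape.
#'
#' @param data numeric or logical vector/array.
#' @param dims integer vector of dimensions; defaults to `dim(data)` or length.
#' @return an array.
#' @export
nl_tensor <- function(data, dims = NULL) {
  if (is.null(dims)) dims <- if (is.null(dim(data))) length(data) else dim(data)
  array(data, dim = dims)
}

tensor_like <- function(x) (is.numeric(x) || is.logical(x)) && !is.null(dim(x))

# payload size in bytes (8 per double element, 4 per logical)
tensor_bytes <- function(x) length(x) * if (is.logical(x)) 4L else 8L

tensor_dtype <- function(x) if (is.logical(x)) "logical" else "double"

# strip tracing attributes, keep dim
detach_tensor <- function(x) {
  a <- attributes(x)
  attributes(x) <- list(dim = a$dim)
  x
}

#' Extract the single scalar value of a tensor
#'
#' Utility accessor (not a logged tensor operation); used e.g. to evaluate an
#' if-condition on a one-element Boolean tensor inside a model's forward code.
#'
#' @param x one-element tensor.
#' @return the scalar value.
#' @export
nl_item <- function(x) {
  stopifnot(length(x) == 1)
  as.vector(x)[1]
}

#' Mark an array as a trainable parameter
#'
#' Assigns a unique parameter identity so that operations applying the same
#' parameters more than once during a forward pass can be recognised as passes
#' of the same layer.
#'
#' @param x numeric array of weights.
#' @return the array tagged with a parameter identity.
#' @export
nl_parameter <- function(x) {
  if (is.null(dim(x))) dim(x) <- length(x)
  the$param_counter <- (the$param_counter %||% 0L) + 1L
  attr(x, "nl_param_id") <- sprintf("p%04d", the$param_counter)
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_param <- function(x) !is.null(attr(x, "nl_param_id"))
is_buffer_tensor <- function(x) !is.null(attr(x, "nl_buffer_id"))

## ---------------------------------------------------------------------------
## op implementations

op_elwise <- function(f) function(x) {
  out <- f(detach_tensor(x))
  dim(out) <- dim(x)
  out
}

impl_relu <- function(x) {
  out <- pmax(detach_tensor(x), 0)
  dim(out) <- dim(x)
  out
}

impl_clamp <- function(x, min = -Inf, max = Inf) {
  out <- pmin(pmax(detach_tensor(x), min), max)
  dim(out) <- dim(x)
  out
}

impl_binary <- function(f) function(x, y) {
  xv <- if (tensor_like(x)) detach_tensor(x) else x
  yv <- if (tensor_like(y)) detach_tensor(y) else y
  out <- f(as.vector(xv), as.vector(yv))
  dim(out) <- if (tensor_like(x)) dim(x) else dim(y)
  out
}

impl_matmul <- function(x, y) {
  out <- unclass(detach_tensor(x) %*% detach_tensor(y))
  out
}

impl_linear <- function(x, weight, bias = NULL) {
  xm <- detach_tensor(x)
  if (length(dim(xm)) == 1L) dim(xm) <- c(1L, dim(xm))
  out <- xm %*% t(detach_tensor(weight))
  if (!is.null(bias)) out <- sweep(out, 2L, as.vector(bias), `+`)
  unclass(out)
}

pad4 <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1], d[2], d[3] + 2 * p, d[4] + 2 * p))
  out[, , (p + 1):(p + d[3]), (p + 1):(p + d[4])] <- x
  out
}

impl_conv2d <- function(x, weight, bias = NULL, stride = 1L, padding = 0L) {
  x <- detach_tensor(x); weight <- detach_tensor(weight)
  d <- dim(x)                       # N,C,H,W
  wd <- dim(weight)                 # O,C,kh,kw
  xp <- pad4(x, padding)
  Hp <- dim(xp)[3]; Wp <- dim(xp)[4]
  kh <- wd[3]; kw <- wd[4]; O <- wd[1]; C <- wd[2]
  Ho <- (Hp - kh) %/% stride + 1L
  Wo <- (Wp - kw) %/% stride + 1L
  # rows of the patch matrix ordered (c fastest, then i, then j)
  base <- expand.grid(c = seq_len(C), i = seq_len(kh), j = seq_len(kw))
  # weight rearranged to match: Wm[o, (c,i,j)]
  Wm <- matrix(aperm(weight, c(1L, 2L, 3L, 4L)), nrow = O)  # flatten (c,i,j) with c fastest
  out <- array(0, c(d[1], O, Ho, Wo))
  offs <- expand.grid(oh = seq_len(Ho), ow = seq_len(Wo))
  for (n in seq_len(d[1])) {
    xn <- xp[n, , , , drop = TRUE]
    if (C == 1L) dim(xn) <- c(1L, Hp, Wp)
    # linear index into xn (C,Hp,Wp): c + C*(h-1) + C*Hp*(w-1)
    h_idx <- outer(base$i, (offs$oh - 1L) * stride, `+`)     # (CKK, HoWo)
    w_idx <- outer(base$j, (offs$ow - 1L) * stride, `+`)
    lin <- base$c + C * (h_idx - 1L) + C * Hp * (w_idx - 1L)
    P <- matrix(xn[lin], nrow = C * kh * kw)
    res <- Wm %*% P                                          # (O, HoWo)
    if (!is.null(bias)) res <- res + as.vector(bias)
    out[n, , , ] <- array(t(res), c(Ho, Wo, O)) |> aperm(c(3L, 1L, 2L))
  }
  out
}

pool_slabs <- function(x, kernel, stride, f) {
  d <- dim(x)
  Ho <- (d[3] - kernel) %/% stride + 1L
  Wo <- (d[4] - kernel) %/% stride + 1L
  out <- NULL
  for (i in seq_len(kernel)) for (j in seq_len(kernel)) {
    slab <- x[, , seq(i, by = stride, length.out = Ho),
              seq(j, by = stride, length.out = Wo), drop = FALSE]
    out <- if (is.null(out)) slab else f(out, slab)
  }
  out
}

impl_maxpool2d <- function(x, kernel, stride = kernel) {
  pool_slabs(detach_tensor(x), kernel, stride, pmax)
}

impl_avgpool2d <- function(x, kernel, stride = kernel) {
  pool_slabs(detach_tensor(x), kernel, stride, `+`) / (kernel * kernel)
}

impl_adaptive_avgpool2d <- function(x, output_size) {
  x <- detach_tensor(x)
  d <- dim(x)
  oh <- output_size[1]; ow <- output_size[if (length(output_size) > 1) 2 else 1]
  out <- array(0, c(d[1], d[2], oh, ow))
  for (i in seq_len(oh)) for (j in seq_len(ow)) {
    hs <- floor((i - 1) * d[3] / oh) + 1L; he <- ceiling(i * d[3] / oh)
    ws <- floor((j - 1) * d[4] / ow) + 1L; we <- ceiling(j * d[4] / ow)
    out[, , i, j] <- apply(x[, , hs:he, ws:we, drop = FALSE], c(1, 2), mean)
  }
  out
}

impl_flatten <- function(x, start_dim = 2L) {
  x <- detach_tensor(x)
  d <- dim(x)
  keep <- d[seq_len(start_dim - 1L)]
  array(x, c(keep, prod(d[start_dim:length(d)])))
}

impl_dropout <- function(x, p = 0.5, training = TRUE) {
  x <- detach_tensor(x)
  if (!training || p <= 0) return(x)
  mask <- (stats::runif(length(x)) >= p) / (1 - p)
  out <- x * mask
  dim(out) <- dim(x)
  out
}

impl_chunk <- function(x, chunks, dim = 2L) {
  x <- detach_tensor(x)
  d <- dim(x)
  step <- d[dim] %/% chunks
  lapply(seq_len(chunks), function(k) {
    idx <- rep(list(quote(expr = )), length(d))
    idx[[dim]] <- seq((k - 1L) * step + 1L, k * step)
    do.call(`[`, c(list(x), idx, list(drop = FALSE)))
  })
}

impl_reduce <- function(f) function(x) array(f(detach_tensor(x)), 1L)

impl_compare <- function(f) function(x, y) {
  xv <- if (tensor_like(x)) detach_tensor(x) else x
  yv <- if (tensor_like(y)) detach_tensor(y) else y
  out <- f(as.vector(xv), as.vector(yv))
  dim(out) <- if (tensor_like(x)) dim(x) else dim(y)
  out
}

impl_rand  <- function(shape) array(stats::runif(prod(shape)), shape)
impl_randn <- function(shape) array(stats::rnorm(prod(shape)), shape)
impl_ones  <- function(shape) array(1, shape)
impl_zeros <- function(shape) array(0, shape)

## ---------------------------------------------------------------------------
## registry

def_op <- function(name, fn, type_token = name, commutative = FALSE,
                   creates = FALSE, stochastic = FALSE, in_place = FALSE,
                   multi_output = FALSE) {
  list(name = name, fn = fn, type_token = type_token, commutative = commutative,
       creates = creates, stochastic = stochastic, in_place = in_place,
       multi_output = multi_output)
}

build_op_table <- function() {
  ops <- list(
    def_op("cos",  op_elwise(cos)),  def_op("sin", op_elwise(sin)),
    def_op("tan",  op_elwise(tan)),  def_op("tanh", op_elwise(tanh)),
    def_op("exp",  op_elwise(exp)),  def_op("log", op_elwise(log)),
    def_op("sqrt", op_elwise(sqrt)), def_op("abs", op_elwise(abs)),
    def_op("sigmoid", op_elwise(function(x) 1 / (1 + exp(-x)))),
    def_op("identity", op_elwise(identity)),
    def_op("relu", impl_relu),
    def_op("relu_", impl_relu, type_token = "relu", in_place = TRUE),
    def_op("clamp", impl_clamp),
    def_op("add", impl_binary(`+`), commutative = TRUE),
    def_op("sub", impl_binary(`-`)),
    def_op("mul", impl_binary(`*`), commutative = TRUE),
    def_op("div", impl_binary(`/`)),
    def_op("pow", impl_binary(`^`)),
    def_op("matmul", impl_matmul),
    def_op("linear", impl_linear),
    def_op("conv2d", impl_conv2d),
    def_op("maxpool2d", impl_maxpool2d),
    def_op("avgpool2d", impl_avgpool2d),
    def_op("adaptiveavgpool2d", impl_adaptive_avgpool2d, type_token = "avgpool2d"),
    def_op("flatten", impl_flatten),
    def_op("dropout", impl_dropout, stochastic = TRUE),
    def_op("chunk", impl_chunk, multi_output = TRUE),
    def_op("mean", impl_reduce(mean)),
    def_op("sum", impl_reduce(sum)),
    def_op("gt", impl_compare(`>`)), def_op("lt", impl_compare(`<`)),
    def_op("ge", impl_compare(`>=`)), def_op("le", impl_compare(`<=`)),
    def_op("eq", impl_compare(`==`)),
    def_op("rand",  impl_rand,  creates = TRUE, stochastic = TRUE),
    def_op("randn", impl_randn, creates = TRUE, stochastic = TRUE),
    def_op("ones",  impl_ones,  creates = TRUE),
    def_op("zeros", impl_zeros, creates = TRUE)
  )
  names(ops) <- vapply(ops, `[[`, "", "name")
  ops
}

init_registry <- function() {
  the$op_info <- build_op_table()
  the$originals <- lapply(the$op_info, `[[`, "fn")
  the$ops <- new.env(parent = emptyenv())
  for (nm in names(the$originals)) assign(nm, the$originals[[nm]], envir = the$ops)
}

.onLoad <- function(libname, pkgname) {
  the$param_counter <- 0L
  the$buffer_counter <- 0L
  init_registry()
}

#' Names of the framework's tensor-returning routines
#'
#' The curated set of array-returning routines that a tracing session wraps.
#' Utility accessors that do not return tensors (e.g. [nl_item()]) are outside
#' this set by design.
#'
#' @return character vector of routine names.
#' @export
framework_ops <- function() names(the$op_info)

op_invoke <- function(name, ...) get(name, envir = the$ops)(...)

#' Tensor operations of the framework
#'
#' Elementwise math, arithmetic, matrix product, neural-network layers
#' (linear, 2-d convolution and pooling, dropout, flatten), comparisons,
#' reductions and tensor-creation routines.  Models are ordinary R functions
#' (or [nn_module()] objects) composed of these calls; every call is logged
#' during a tracing session.  Shapes follow the `(N, C, H, W)` convention for
#' image-like tensors.
#'
#' @param x,y input tensors (arrays); second operands of arithmetic may be
#'   scalar literals.
#' @param weight,bias parameter tensors created with [nl_parameter()].
#' @param stride,padding,kernel,output_size,start_dim,chunks,dim,p,training,min,max
#'   non-tensor configuration arguments.
#' @param shape integer vector for tensor-creation ops.
#' @return an array (or, for `nn_chunk`, a list of arrays).
#' @name tensor-ops
NULL

#' @rdname tensor-ops
#' @export
nn_cos <- function(x) op_invoke("cos", x)
#' @rdname tensor-ops
#' @export
nn_sin <- function(x) op_invoke("sin", x)
#' @rdname tensor-ops
#' @export
nn_tan <- function(x) op_invoke("tan", x)
#' @rdname tensor-ops
#' @export
nn_tanh <- function(x) op_invoke("tanh", x)
#' @rdname tensor-ops
#' @export
nn_exp <- function(x) op_invoke("exp", x)
#' @rdname tensor-ops
#' @export
nn_log <- function(x) op_invoke("log", x)
#' @rdname tensor-ops
#' @export
nn_sqrt <- function(x) op_invoke("sqrt", x)
#' @rdname tensor-ops
#' @export
nn_abs <- function(x) op_invoke("abs", x)
#' @rdname tensor-ops
#' @export
nn_sigmoid <- function(x) op_invoke("sigmoid", x)
#' @rdname tensor-ops
#' @export
nn_identity <- function(x) op_invoke("identity", x)
#' @rdname tensor-ops
#' @export
nn_relu <- function(x) op_invoke("relu", x)
#' @rdname tensor-ops
#' @export
nn_relu_ <- function(x) op_invoke("relu_", x)
#' @rdname tensor-ops
#' @export
nn_clamp <- function(x, min = -Inf, max = Inf) op_invoke("clamp", x, min = min, max = max)
#' @rdname tensor-ops
#' @export
nn_add <- function(x, y) op_invoke("add", x, y)
#' @rdname tensor-ops
#' @export
nn_sub <- function(x, y) op_invoke("sub", x, y)
#' @rdname tensor-ops
#' @export
nn_mul <- function(x, y) op_invoke("mul", x, y)
#' @rdname tensor-ops
#' @export
nn_div <- function(x, y) op_invoke("div", x, y)
#' @rdname tensor-ops
#' @export
nn_pow <- function(x, y) op_invoke("pow", x, y)
#' @rdname tensor-ops
#' @export
nn_matmul <- function(x, y) op_invoke("matmul", x, y)
#' @rdname tensor-ops
#' @export
nn_linear <- function(x, weight, bias = NULL) op_invoke("linear", x, weight, bias)
#' @rdname tensor-ops
#' @export
nn_conv2d <- function(x, weight, bias = NULL, stride = 1L, padding = 0L)
  op_invoke("conv2d", x, weight, bias, stride = stride, padding = padding)
#' @rdname tensor-ops
#' @export
nn_maxpool2d <- function(x, kernel, stride = kernel) op_invoke("maxpool2d", x, kernel = kernel, stride = stride)
#' @rdname tensor-ops
#' @export
nn_avgpool2d <- function(x, kernel, stride = kernel) op_invoke("avgpool2d", x, kernel = kernel, stride = stride)
#' @rdname tensor-ops
#' @export
nn_adaptive_avgpool2d <- function(x, output_size) op_invoke("adaptiveavgpool2d", x, output_size = output_size)
#' @rdname tensor-ops
#' @export
nn_flatten <- function(x, start_dim = 2L) op_invoke("flatten", x, start_dim = start_dim)
#' @rdname tensor-ops
#' @export
nn_dropout <- function(x, p = 0.5, training = TRUE) op_invoke("dropout", x, p = p, training = training)
#' @rdname tensor-ops
#' @export
nn_chunk <- function(x, chunks, dim = 2L) op_invoke("chunk", x, chunks = chunks, dim = dim)
#' @rdname tensor-ops
#' @export
nn_mean <- function(x) op_invoke("mean", x)
#' @rdname tensor-ops
#' @export
nn_sum <- function(x) op_invoke("sum", x)
#' @rdname tensor-ops
#' @export
nn_gt <- function(x, y) op_invoke("gt", x, y)
#' @rdname tensor-ops
#' @export
nn_lt <- function(x, y) op_invoke("lt", x, y)
#' @rdname tensor-ops
#' @export
nn_ge <- function(x, y) op_invoke("ge", x, y)
#' @rdname tensor-ops
#' @export
nn_le <- function(x, y) op_invoke("le", x, y)
#' @rdname tensor-ops
#' @export
nn_eq <- function(x, y) op_invoke("eq", x, y)
#' @rdname tensor-ops
#' @export
nn_rand <- function(shape) op_invoke("rand", shape = shape)
#' @rdname tensor-ops
#' @export
nn_randn <- function(shape) op_invoke("randn", shape = shape)
#' @rdname tensor-ops
#' @export
nn_ones <- function(shape) op_invoke("ones", shape = shape)
#' @rdname tensor-ops
#' @export
nn_zeros <- function(shape) op_invoke("zeros", shape = shape)
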