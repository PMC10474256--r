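# fixtures: programmatically built toy architectures, each paired with a
# hand-written ground-truth graph (JSON under inst/extdata/fixtures), so the
# tracer, post-processor, namer, validator and renderer are all testable
# without any downloads.

fixture_builders <- function() list(

  single_op = function() {
    list(model = function(x) nn_tanh(x), input = rand_input(c(2, 3)))
  },

  identity = function() {
    list(model = function(x) x, input = rand_input(c(2, 2)))
  },

  feedforward = function() {
    w1 <- nl_parameter(init_weight(c(4, 4), 4))
    b1 <- nl_parameter(init_weight(4, 4))
    w2 <- nl_parameter(init_weight(c(2, 4), 4))
    b2 <- nl_parameter(init_weight(2, 4))
    list(model = function(x) nn_linear(nn_relu(nn_linear(x, w1, b1)), w2, b2),
         input = rand_input(c(1, 4)))
  },

  branching_div = function() {
    list(model = function(x) {
      a <- nn_cos(x)
      b <- nn_add(nn_sin(x), 2)
      nn_div(a, b)
    }, input = rand_input(c(1, 4)))
  },

  internal_rand = function() {
    list(model = function(x) {
      t <- nn_tanh(x)
      noise <- nn_rand(c(1, 4))
      nn_add(t, nn_mul(noise, 0.1))
    }, input = rand_input(c(1, 4)))
  },

  orphan_ops = function() {
    list(model = function(x) {
      y <- nn_relu(x)
      junk <- nn_rand(c(2, 2))
      nn_cos(junk)               # transformed and discarded
      y
    }, input = rand_input(c(1, 4)))
  },

  buffer_model = function() {
    model <- nn_module("BufferNet",
      function(self, x) nn_mul(x, self$buffers$scale),
      buffers = list(scale = array(c(0.5, 1, 1.5, 2), c(1, 4))))
    list(model = model, input = rand_input(c(1, 4)))
  },

  cond_branch = function() {
    list(model = function(x) {
      test <- nn_gt(nn_mean(nn_sub(x, 5)), 3)
      if (nl_item(test)) nn_relu(x) else nn_tanh(x)
    }, input = rand_input(c(1, 4), offset = 9))   # mean(x - 5) > 3 holds
  },

  fig4a = function() {
    w <- nl_parameter(init_weight(c(3, 3), 3))
    b <- nl_parameter(init_weight(3, 3))
    list(model = function(x) {
      h <- nn_add(nn_linear(nn_cos(x), w, b), 1)
      h <- nn_sin(h)
      nn_add(nn_linear(nn_cos(h), w, b), 1)
    }, input = rand_input(c(1, 3)))
  },

  fig4b = function() {
    list(model = function(x) {
      h <- nn_mul(nn_relu(nn_cos(x)), 0.5)
      h <- nn_mul(nn_relu(nn_cos(h)), 0.5)
      h <- nn_tan(h)
      nn_mul(nn_relu(nn_cos(h)), 0.5)
    }, input = rand_input(c(1, 4)))
  },

  xyz3 = function() {
    list(model = function(x) {
      for (k in 1:3) x <- nn_tanh(nn_add(nn_mul(x, 2), 1))
      x
    }, input = rand_input(c(1, 4)))
  },

  xyzab = function() {
    list(model = function(x) {
      x <- nn_tanh(nn_add(nn_mul(x, 2), 1))
      x <- nn_cos(x)
      x <- nn_tanh(nn_add(nn_mul(x, 2), 1))
      x <- nn_sin(x)
      nn_tanh(nn_add(nn_mul(x, 2), 1))
    }, input = rand_input(c(1, 4)))
  },

  inplace_op = function() {
    list(model = function(x) nn_cos(nn_relu_(nn_add(x, 1))),
         input = rand_input(c(1, 4)))
  },

  tuple_out = function() {
    list(model = function(x) {
      pieces <- nn_chunk(x, 2, dim = 2)
      nn_add(pieces[[1]], pieces[[2]])
    }, input = rand_input(c(2, 4)))
  },

  mul_zero = function() {
    list(model = function(x) nn_add(nn_mul(x, 0), 1),
         input = rand_input(c(1, 4)))
  },

  module_reuse = function() {
    model <- nn_module("ReuseNet",
      function(self, x) {
        h <- self$modules$act(self$modules$fc1(x))
        self$modules$act(self$modules$fc2(h))
      },
      modules = list(fc1 = nn_linear_mod(4, 4), fc2 = nn_linear_mod(4, 4),
                     act = nn_relu_mod()))
    list(model = model, input = rand_input(c(1, 4)))
  },

  nested_mod = function() {
    model <- nn_module("NestedNet",
      function(self, x) {
        h <- self$modules$stem(x)
        h <- self$modules$block(h)
        self$modules$head(h)
      },
      modules = list(
        stem = nn_sequential(nn_linear_mod(4, 4), nn_relu_mod()),
        block = nn_module("Block",
          function(self, x) nn_add(self$modules$b1(x), self$modules$b2(x)),
          modules = list(
            b1 = nn_sequential(nn_linear_mod(4, 4), nn_relu_mod()),
            b2 = nn_sequential(nn_linear_mod(4, 4), nn_relu_mod()))),
        head = nn_linear_mod(4, 2)))
    list(model = model, input = rand_input(c(1, 4)))
  },

  alexnet = function() {
    model <- nn_module("AlexNet",
      function(self, x) {
        h <- self$modules$features(x)
        h <- self$modules$avgpool(h)
        h <- nn_flatten(h)
        self$modules$classifier(h)
      },
      modules = list(
        features = nn_sequential(
          nn_conv2d_mod(3, 64, 11, stride = 4, padding = 2),
          nn_relu_mod(),
          nn_maxpool2d_mod(3, 2),
          nn_conv2d_mod(64, 192, 5, padding = 2),
          nn_relu_mod(),
          nn_maxpool2d_mod(3, 2),
          nn_conv2d_mod(192, 384, 3, padding = 1),
          nn_relu_mod(),
          nn_conv2d_mod(384, 256, 3, padding = 1),
          nn_relu_mod(),
          nn_conv2d_mod(256, 256, 3, padding = 1),
          nn_relu_mod(),
          nn_maxpool2d_mod(3, 2)),
        avgpool = nn_adaptive_avgpool2d_mod(c(6, 6)),
        classifier = nn_sequential(
          nn_dropout_mod(0.5),
          nn_linear_mod(9216, 4096),
          nn_relu_mod(),
          nn_dropout_mod(0.5),
          nn_linear_mod(4096, 4096),
          nn_relu_mod(),
          nn_linear_mod(4096, 1000))))
    list(model = model, input = rand_input(c(1, 3, 224, 224)))
  }
)

rand_input <- function(shape, offset = 0) {
  array(stats::runif(prod(shape)) + offset, shape)
}

#' Names of the fixture catalog
#' @return character vector of fixture names.
#' @export
fixture_names <- function() names(fixture_builders())

#' Build a fixture model
#'
#' Constructs one of the catalog's toy architectures with seeded random
#' weights and a seeded example input, together with its hand-written
#' ground-truth graph (node multiset, adjacency with argument positions,
#' labels, pass counts, flags, module addresses).
#'
#' @param name a name from [fixture_names()].
#' @param seed integer seed for weights and input.
#' @return list with `model`, `input`, and `spec` (name plus `ground_truth`).
#' @export
make_fixture <- function(name, seed = 1L) {
  builders <- fixture_builders()
  if (!name %in% names(builders)) {
    stop(sprintf("unknown fixture '%s'; available: %s", name,
                 paste(names(builders), collapse = ", ")))
  }
  set.seed(seed)
  built <- builders[[name]]()
  gt_path <- system.file("extdata", "fixtures", paste0(name, ".json"),
                         package = "netlens")
  gt <- if (nzchar(gt_path)) {
    jsonlite::read_json(gt_path, simplifyVector = FALSE)
  } else NULL
  list(model = built$model, input = built$input,
       spec = list(name = name, ground_truth = gt))
}
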