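# netlens

Exhaustive tracing, naming, validation and visualization of neural-network
forward passes.

Researchers who study the internal representations of deep networks — to
understand what a model computes, to profile it, or to compare its
intermediate activations with brain measurements — need the result of *every*
tensor operation in a forward pass, not just the outputs of the modules a
model's author happened to name.  netlens produces that record for models
written in its array-operation framework: it transiently wraps every
tensor-returning routine of the framework with a logging decorator, runs one
forward pass with the model's code unchanged, restores the framework exactly,
and assembles the log into the model's full computational graph — including
branching, conditional (if–then) control flow, internally generated tensors
(e.g. noise), buffers, and recurrence.

The core ideas:

* **Operation-level tracing.** Output tensors are tagged with a *barcode*
  linking them to the entry that produced them, so parent–child edges (with
  argument positions) are recovered no matter how the model's code is
  organised.  Only operations that actually executed are logged, which is
  what makes dynamic control flow unproblematic.
* **Graph post-processing.** Orphan operations are trimmed; distances from
  input and to output are computed; childless one-element Boolean tensors are
  flagged as if-tests and the start of each conditional branch is inferred;
  module containment of internally generated tensors is repaired.
* **Recurrent-layer grouping.** Operations applying the same trainable
  parameters more than once are passes of one layer; identical operations
  adjacent to different passes of a grouped layer join it recursively; and
  parameter-free sequences repeating back-to-back (`XYZXYZXYZ`) form loops,
  while separated repetitions (`XYZAXYZBXYZ`) do not.
* **Uniform nomenclature.** Layers are named
  `{type}_{type_ordinal}_{global_ordinal}` (e.g. `relu_3_6`, pass 2 of a
  recurrent layer being `relu_3_6:2`), and module-output layers also resolve
  by module address at every applicable nesting level (`features.12`,
  `features`).
* **Validation by re-execution.** Every layer's function is re-run on the
  saved values of its parents (with captured RNG state for stochastic
  operations) and must reproduce the saved activation; random-substitute
  counter-checks guard against silent errors, with special-case handling for
  input-insensitive operations such as multiplication by zero.
* **Visualization.** Graphviz DOT rendering, rolled or unrolled, with the
  full visual code (colors for inputs/outputs/parameters/buffers, dashed
  internal tensors, `IF` branch marks, per-pass edge labels, module boxes at
  a chosen nesting depth).

## Worked example

The two-pass recurrent toy model — input → cosine → shared linear → add →
sine → the same cosine → the same linear → the same add → output — is in the
fixture catalog as `fig4a`:

```r
library(netlens)

fx <- make_fixture("fig4a", seed = 1)
h  <- log_forward_pass(fx$model, fx$input, seed = 1)
h
#> ModelHistory for model
#>   layers: 6 (9 entries incl. passes)
#>   tensors computed: 7, total size 168 B
#>   trainable parameters: 12 in 96 B
#>   forward pass time: 0.0030 s

tidy(h)[, c("label", "type", "pass", "shape", "dist_from_input")]
#>          label   type pass shape dist_from_input
#> 1    input_1_1  input    1   1x3               0
#> 2    cos_1_2:1    cos    1   1x3               1
#> 3 linear_1_3:1 linear    1   1x3               2
#> 4    add_1_4:1    add    1   1x3               3
#> 5      sin_1_5    sin    1   1x3               4
#> 6    cos_1_2:2    cos    2   1x3               5
#> 7 linear_1_3:2 linear    2   1x3               6
#> 8    add_1_4:2    add    2   1x3               7
#> 9   output_1_6 output    1   1x3               8
```

Nine operations were executed but only six distinct layers exist: the shared
fully-connected layer is `linear_1_3` (first linear layer, third layer
overall) with 2 passes, and the cosine and addition around it are grouped
with it.  In the rolled graph the cosine's incoming edge is annotated per
pass — from the input on pass 1, from `sin_1_5` on pass 2:

```r
dot <- render_graph(h, vis_options(rolled = TRUE))
# ... "g001" -> "g002" [label="In 1"];   (input -> cos, pass 1)
# ... "g005" -> "g002" [label="In 2"];   (sin   -> cos, pass 2)
# ... label="linear_1_3 (×2)\n..."
```

Layers resolve by any alias — `h[["linear_1"]]`, `h[["cos_1_2:2"]]`,
`h[[-5]]` — and on the AlexNet fixture by module address:
`h[["features.3"]]` is the second convolution, `h[["features.12"]]` (equally
`h[["features"]]`) the third max-pool.  Validation is one call:

```r
validate_saved_activations(fx$model, fx$input, seed = 1)
#> [1] TRUE
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/netlens.R graph fixture:fig4a --rolled --seed 1 --out g.dot
Rscript inst/cli/netlens.R validate fixture:fig4b --seed 1
```

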