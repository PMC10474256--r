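---
title: "Tracing, naming and validating neural-network forward passes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing, naming and validating neural-network forward passes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netlens)
```

## What the package does

netlens produces a complete, queryable record of one forward pass of a
neural-network model: every tensor operation that was executed, in order, with
its inputs, outputs, timing, module containment, parameter metadata and
(optionally) its saved activation.  From that record it assembles the model's
computational graph, identifies recurrent layers, assigns a uniform layer
nomenclature, verifies the saved activations algorithmically, and renders the
graph as Graphviz DOT.

The motivating problem comes from computational neuroscience and model
introspection: researchers comparing internal representations of deep networks
(to each other, or to brain measurements) need *all* intermediate tensors, not
just the outputs of named modules; they need to know where each operation sits
in the graph of a possibly branching, recurrent or stochastically controlled
model; and they need confidence that what was saved is actually what the model
computed.

## The host tensor framework

Models are written in the package's own compact tensor-operation framework:
tensors are plain R arrays, operations are a curated registry of
array-returning routines (`nn_cos()`, `nn_linear()`, `nn_conv2d()`, ...; see
`framework_ops()`), and `nn_module()` provides named, nestable units owning
parameters and buffers, mirroring the module systems of mainstream
deep-learning frameworks.  Keeping the framework inside the package has one
decisive property for tracing: every tensor-returning routine dispatches
through a single registry environment, so a tracing session can transiently
replace each binding with a logging wrapper and afterwards restore the exact
original function objects.  `residual_wrappers()` sweeps the registry and must
return an empty set after any session, including sessions that ended in an
error (restoration runs in an exit handler).

Three design points are worth recording:

* **Lazy evaluation.** In R, arguments are promises: in `nn_add(nn_cos(x), 1)`
  the inner cosine is evaluated *inside* the outer wrapper's frame.  Wrappers
  therefore force their arguments before incrementing the nesting depth, so an
  operation evaluated in argument position is logged as its own user-visible
  call.  Genuinely nested calls -- a wrapped routine whose implementation
  invokes other wrapped routines -- are merged into the outermost call, giving
  one node per user-visible operation and self-times that do not double count.
* **Barcodes.** Each logged output tensor is tagged with an opaque identifier
  linking it to the entry that produced it; when a later call consumes the
  tensor, its parents are looked up from these tags, which is what makes the
  approach insensitive to branching and dynamic control flow: only operations
  that actually executed are recorded.  In-place operations re-tag the mutated
  tensor with a fresh barcode and log a new entry whose parent is the tensor's
  previous entry.
* **Module containment.** Entering a hooked module pushes its dotted address
  (`features.3`) on a stack that every logged operation copies.  Operations
  whose output does not descend from the model input -- tensors created inside
  the model via `nn_rand()` and friends, and buffers -- record *no* containment
  at logging time, because no ancestor tensor ever entered a module on their
  behalf; their containment is repaired during post-processing by walking to
  the nearest input-descended descendant and propagating its stack backwards.

## Post-processing the graph

After the forward pass, `finalize_history()` applies, in order: orphan
trimming (entries that neither descend from an input nor reach an output are
removed; dead ends that *do* descend from the input are kept, since they may
be conditional tests), shortest-path distances from input and to output (edge
counts; unreachable distances are `NA` rather than infinite),
conditional-branch inference, module-containment repair, recurrent-layer
identification, graph rolling, labelling and indexing.

**Branch inference.** A childless one-element Boolean tensor is almost always
the test of an `if` statement, so such entries are flagged as Boolean
terminals.  Walking each terminal's ancestry backwards, the first operation
that is *not* an ancestor of the model output but whose parent is marks the
start of the branch; for a test like `mean(x - 5) > 3` that is the
subtraction, and the visualization prints a bold `IF` there.

**Recurrence.** A layer is recurrent when it executes its operation several
times in one forward pass.  Grouping follows three rules: (1) operations
applying the same trainable parameters more than once are always passes of one
layer; (2) operations with identical signatures (same routine, same parameter
identity, same canonicalized non-tensor arguments) that are adjacent --
direct parent or child in the unrolled graph -- to *different* passes of an
already-grouped layer are grouped, recursively to fixpoint, which grows blocks
of repeated layers around the shared-parameter cores; (3) parameter-free
sequences that repeat back-to-back (XYZXYZXYZ) are grouped position-wise as a
computational loop, while separated repetitions (XYZAXYZBXYZ) are not.  For
rule 3 the scan starts from parentless layers and walks forward along chains;
when candidate repeats overlap, the earliest start wins and, at a given start,
the largest total repeated span; span ties prefer the smallest (primitive)
period, so four adjacent identical operations become one layer with four
passes rather than two layers with two.  Pass numbers follow execution order.
Two deliberately permissive choices: adjacency for rule 2 ignores module
boundaries, and passes of one group may produce different tensor shapes
(per-pass shapes are kept).

**Rolling.** The rolled graph has one node per layer group; each rolled edge
retains the full set of (source pass, destination pass, argument position)
triples, so expanding it reproduces the unrolled adjacency exactly.  Edge
annotations (`In 1`, `Out 2-3`) are printed only where a layer's connectivity
differs across passes.

## Nomenclature

Every layer gets `{layer_type}_{layer_type_num}_{layer_total_num}` --
`relu_3_6` is the third ReLU and sixth layer overall -- with `:pass` appended
for multi-pass layers, and the truncated form (`relu_3`) accepted everywhere.
Numbering follows first-execution order, which for branching models is a
topological order.  The model input counts as layer 1 and buffer and
internally generated origin entries are numbered too; this keeps the global
index aligned with the rolled node sequence of recurrent models.  Layers that
produce a module's return value also carry that module's address at every
nesting level for which this holds (AlexNet's third max-pool is both
`features.12` and `features`), with `address:pass` qualification when a module
runs more than once.  `ModelHistory` objects resolve full labels, truncated
labels, pass-qualified labels, module addresses and (negative) integer
ordinals; when only a subset of layers is saved, integer indexing runs over
the saved layers only.

## Validation by re-execution

`validate_saved_activations()` re-runs each layer's function on the saved
values of its parents and requires the result to reproduce the saved target,
walking from the model outputs back to the parentless origin layers.  Since
floating-point re-execution is not bit-stable across operation orderings, the
comparison uses an elementwise tolerance of `1e-5` relative plus `1e-8`
absolute; Boolean tensors must match exactly.  A second check substitutes
random parent values -- standard normal, scaled to each parent's standard
deviation so values stay in a plausible range, seeded from the session seed
and the layer label -- and requires the output to change.  That check is
skipped for input-insensitive operations, detected structurally
(multiplication by a zero literal, clamping with equal bounds, zero-size
tensors) or empirically (two distinct substitutes yielding identical outputs).
Stochastic operations are re-executed under the RNG state captured when they
were logged, so dropout masks and noise replay exactly.  Corrupting any single
saved non-origin activation makes the walk fail at that layer or one of its
descendants; the per-layer report records which check failed and the maximum
deviation.

## Visualization

`render_graph()` emits DOT with a fixed style table: green inputs, red
outputs, gray parameterized layers, light-gray buffers, dashed outlines for
internally generated tensors, yellow Boolean terminals, rectangles for
single-operation modules and ellipses otherwise, boxes (DOT clusters) around
multi-operation modules labelled with address and class, argument-position
labels only on non-commutative multi-parent operations, and a header with the
model's totals.  The concrete hexes and fonts are the package's own choices;
rank direction is top-to-bottom with the input at the top.  `nesting_depth`
collapses modules nested at or beyond the given level into single nodes, so
node counts are non-decreasing in depth.  When no `dot` binary is available
the DOT source is still written, with a warning.

## Fixtures: what they emulate and what they do not

The test catalog (`fixture_names()`) rebuilds the canonical demonstration
architectures as seeded toy models -- a feedforward chain, branching with
non-commutative division, internally generated and buffer tensors, an
if-branch computing a single Boolean, the two-pass shared-linear loop
(`fig4a`), the double loop with a separated third repetition (`fig4b`), the
XYZXYZXYZ and XYZAXYZBXYZ patterns, in-place and tuple-returning operations,
reused and nested modules, and an AlexNet with the canonical
3-64-192-384-256-256 convolutional stack, 9216-4096-4096-1000 classifier and
conventional 1×3×224×224 input (61,100,840 parameters).  Weights are randomly
initialized from the seed (scaled normal, sd `1/sqrt(fan_in)`): only the
architecture matters for graph structure, nomenclature and validation.  Each
fixture ships a hand-written ground-truth graph (JSON under
`inst/extdata/fixtures/`) giving the expected node multiset, adjacency with
argument positions, labels, pass counts, flags and module addresses.

What passing these tests shows: that tracing is exhaustive and observationally
transparent, that the post-processing rules reproduce the intended graphs on
architectures exhibiting each structural feature, and that validation detects
injected corruptions.  What they do not show: behaviour on pretrained weights
(fixtures are random), very deep or very wide production models, models
written outside the package's operation registry, or parallel execution,
which is out of scope.

## Problem sizes and runtime choices

All tests run on one CPU.  The toy fixtures use inputs of at most a few dozen
elements and trace in milliseconds; the AlexNet fixture takes a few seconds
per forward pass (the convolutions are im2col matrix products) and is traced
once per seed, with traced histories memoized across tests.  The transparency
and validation property suites run every fixture at three and one-to-two
seeds respectively.  All randomness -- weights, inputs, dropout, substitute
values -- flows from a single user seed.

## Known limitations

* Models must be composed from the registry's operations; arbitrary base-R
  array code inside a model is invisible to the tracer.
* The branch-start heuristic can mark a node that merely feeds a dead-end
  Boolean computation outside an `if`; as with any heuristic over executed
  traces, untaken branches are never enumerated.
* Rule-3 recurrence detection walks single-parent/single-child chains;
  repeated parameter-free *subgraphs* with internal branching are not grouped.
* Validation logically requires saving all intermediate tensors, which can be
  memory-hungry for large models.
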