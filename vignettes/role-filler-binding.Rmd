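---
title: "Role-filler binding in recurrent networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Role-filler binding in recurrent networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`schemabind` is a simulation toolkit for a question from computational
cognitive neuroscience: can recurrent neural networks learn *role-filler
binding* — recalling which concrete filler occupies an abstract role in a
structured event — purely from the statistics of schema-generated stories,
and does an external memory component make the difference? This vignette
documents the generative model, the four architectures, the training and
evaluation conventions, and the design choices behind them.

## The story world

A schema is a directed acyclic graph of story states. Each state carries a
frame keyword and an ordered list of role slots drawn from {Subject,
Friend, Emcee, Poet, Drink, Dessert}. A story is a uniformly random walk
from the start state to the terminal state: at each state every outgoing
edge is equally likely, so a path's probability is the product of
`1/out-degree` over its states. The bundled coffee-shop schema
(`coffee_shop_graph()`) has 11 states and exactly 24 start-to-terminal
paths; counting, for each path, the roles that occur on it gives 112
answerable (path, query) pairs. Both counts are enforced by tests against
an independent brute-force enumeration, because they pin down the graph
topology (the published figure is graphical, and these counts plus the
example story are the three constraints that identify the edge list).

A story instance emits, per state, the keyword followed by that state's
fillers in slot order. One padding word is inserted at a uniformly random
position inside the body — ends included, since the source describes only
"a randomly chosen location" — to force representations that tolerate
small position shifts. The body is right-padded so all instances share the
fixed length `L`, and the query token (`qsubject` … `qdessert`, ordinary
vocabulary items with their own embeddings) comes last. `L` defaults to
the smallest value that fits the longest path body plus the inserted pad
and the query (25 for the coffee-shop schema): the source fixes a common
length without stating it, and any larger value only adds padding steps.

The correlation experiments use a fixed 13-slot linear frame
(`linear_frame()`: `begin [Subject] sit [Subject] [Friend] announce
[Emcee] perform [Poet] consume [Dessert] [Drink] goodbye`) and its fixed
stage shuffle (`shuffle_stages()`), which moves the final stage to the
front while preserving the token multiset.

## Word embeddings

Every token maps to a 50-dimensional vector drawn with independent
standard-normal coordinates and normalized to unit Euclidean norm; there
is no pretrained semantic structure. Filler distributions X and Y
additionally shift all even coordinates (0-based; the base is a
convention, since only the even/odd contrast matters) by +0.5 or −0.5
before normalization. The sign is one coin per vector — +0.5 with
probability 0.9 under X and 0.1 under Y — read from the definition "with
90% probability we add 0.5 to each even index" as a single event per
draw. Distribution Z applies no shift.

Retrieval is nearest-neighbor by cosine similarity against a corpus. For
fixed-lexicon experiments the corpus is the whole experiment vocabulary;
for unlimited-filler experiments it is the base vocabulary plus the six
fresh fillers of every story in the evaluation batch, so a base vocabulary
of 30 and a validation batch of 16 give 126 candidates and a chance rate
of 0.8%. The base vocabulary comprises the 11 state keywords, 6 query
tokens, and the padding word, padded with reserved tokens to the
conventional size of 30 used by that accounting. Six fresh fillers are
drawn per story for all six roles even when a role is absent from the
sampled path; this is what makes the 30 + 16 × 6 arithmetic hold for
mixed paths.

The decoding analyses score predictions with the ranking score
`1 − rank/|corpus|`, where rank is the 0-based position of the true word
when the corpus is sorted by descending cosine similarity to the
prediction. This is the only reading of the printed formula whose maximum
is exactly 1 and whose expectation under a random prediction is 0.5 (plus
a `1/(2|corpus|)` finite-size term). Ties in retrieval break toward the
lowest corpus index.

## Architectures

All four models consume one 50-d embedding per timestep and emit a 50-d
prediction from a linear readout of the state after the final (query)
token. Hidden size is 50 and the learning rate 1e-4 throughout.

* **RNN** — `h ← tanh(LN(W h + U x))`, with layer normalization (learnable
  gain/bias, ε = 1e-5) stabilizing the recurrence.
* **LSTM** — standard gates with per-gate layer normalization and a
  normalized cell before the output nonlinearity; forget-gate bias starts
  at 1.
* **Fast Weights** — a recurrent controller augmented with an
  auto-associative matrix updated every step from the incoming hidden
  state, `A ← λA + η h hᵀ`, applied through one inner "settling"
  iteration `h_s ← f(LN(W h + U x + A h_{s−1}))` with `h_0 = f(W h + U x)`.
  The hyperparameters λ = 0.95, η = 0.5, S = 1, and the ReLU
  nonlinearity are the canonical values of the cited fast-weights
  architecture, which the source adopts without restating them. A tanh
  variant is available via `fw_nonlin = "tanh"`; its bounded states give
  the fast-weight norm bound `‖A‖ ≤ η·max‖h‖²/(1−λ)`, which the tests
  verify. Since `A` is a λ-discounted sum of outer products of past
  hidden states, the implementation never materializes it during
  training: products `A·v` are computed in attention form over the
  stored state history, which is both exact and an order of magnitude
  cheaper than maintaining the 50 × 50 matrix.
* **DNC** — an LSTM controller reading and writing a 128 × 20 external
  buffer with one write head and one read head. Writing mixes content
  addressing (cosine keys, softplus-one strengths, softmax sharpening)
  with usage-based dynamic allocation under a write gate; reading mixes
  content addressing with temporal-linkage forward/backward reads. The
  temporal-link matrix is implemented in full (the cited architecture
  includes it and the source gives no reason to drop it). The readout
  projects `[h; read vector]` to 50-d, resolving an unstated detail in
  favor of the cited architecture's output layer.

Backpropagation through time for all four models — including the DNC's
allocation sort, linkage recursion, and cosine addressing — is derived by
hand in the compiled backend. Two independent checks guard it: a pure-R
single-step reference implementation must reproduce the compiled forward
pass to machine precision, and finite-difference tests must match every
parameter's analytic gradient on small configurations.

## Training

The source never states a training loss; only the prediction method
(retrieve the corpus word most cosine-similar to the 50-d output) is
given. The package therefore trains, by default, a softmax cross-entropy
over inner-product logits between the prediction and every lexicon word —
on unit-norm embeddings the argmax of those logits *is* the cosine
retrieval answer, so the objective optimizes exactly the reported metric.
Plain squared error to the target embedding is available
(`loss = "mse"`), but on the binding tasks its conditioning is poor: in
our calibration runs the Fast Weights network needs roughly twice the
optimizer steps under MSE to reach a weaker result than cross-entropy
(92% vs 96%+ on the reduced correlation-violation test), because the MSE
gradient vanishes as predictions approach the corpus-mean vector while
cross-entropy keeps explicit competition between candidate words alive.

Optimization is Adam at the stated learning rate of 1e-4 with minibatches
of 16. An optional global gradient-norm clip is available but off by
default — every converging calibration run used unclipped gradients.
Minibatch order is drawn from R's RNG, so runs are exactly reproducible
under `set.seed()`.

Limited-filler experiments draw stories per path with fillers from small
fixed pools (six per role), deduplicate on the exact body sequence
(states plus fillers; the padding position and query are not part of a
story's identity), and either split 80/20 or pair the training set with a
disjoint-pool test set. Unlimited-filler experiments iterate over the 112
(path, query) frames per epoch, drawing fresh filler vectors for every
story in every epoch. The correlation-violation experiment keeps a fixed
lexicon of 1,000 fillers (100 in reduced form), with each filler excluded
from exactly one of the four varied roles — exclusion is assigned
round-robin by filler index, the simplest scheme satisfying "each filler
is excluded from one of these four roles" — and resamples fresh role-
filler combinations from the allowed pools each epoch; the test set binds
each varied role only to its excluded quarter. Queries in the violation
experiments cover the four varied roles; the constant Dessert/Drink words
carry no binding information.

## Decoding analyses

For a decoding set, 100 sequences share one frame — identical frame text,
padding position, and query — and differ only in fillers. The default
frame is the path BEGIN → ORDER_DRINK → SIT → INTRO → POETRY → PERFORM →
ORDER_DESSERT → END, the unique kind of path on which all six roles occur,
so one set supports decoders for every role. Per (role, timestep,
component) a ridge regression (regularization strength 1.0, intercept via
centering) maps the activation — the 50-d hidden state, the flattened
2,500-d fast-weight matrix, or the flattened 2,560-d DNC buffer — to the
50-d filler embedding, fitted on 80 sequences and scored on 20 by the
mean ranking score. Decoders are fitted per timestep because the reported
curves move over time within a fixed mapping dimension; a
timestep-shared decoder could not produce them. High-dimensional
components use the kernel (dual) form of ridge, so every solve is 80 × 80
regardless of component width.

The DNC read/write analysis histograms, per role, the argmax of the write
weighting at the timesteps where the role's filler is input, and per
query the argmax of the read weighting at the query timestep, breaking
ties toward the lowest slot; Pearson correlations between write and read
histograms quantify location-based storage.

## Correlation probes

In retention experiments, training fillers for Dessert/Emcee/Poet come
from X and Subject/Friend/Drink from Y, while frame words always come
from Z. Test suites redraw all fillers from X, Y, an equal per-filler X/Y
mixture, or Z. The ambiguous probe zeroes the queried filler's input
vector (the zero vector is outside the corpus and has no even/odd
asymmetry) and summarizes predictions per role by a Welch two-sample
t-statistic between all pooled even-coordinate and odd-coordinate values
of a trial — the source does not define the pooling, and pooling across
test examples within a trial is the most powerful symmetric choice.
Positive statistics mean X-like (elevated even coordinates) predictions.
The residual probe applies the same statistic to `prediction − target` on
all-Z test sets, where any asymmetry must come from the model, and
reports retrieval accuracy alongside.

## Problem sizes and what the simulations show

The packaged experiments run at reduced scale, chosen once as the
smallest sizes at which each qualitative phenomenon is stable: 2 paths ×
200 stories for the limited-filler failure mode, a 100-filler universe
with 75/25 pools and 512-story generative epochs for the violation
design, 768-story epochs for the retention trials, and 100-sequence
decoding sets. Under these conditions the Fast Weights network crosses
from the mean-prediction plateau to near-perfect correlation-violating
binding after roughly 250–350 thousand optimizer steps at the stated
learning rate, and role-conditional retention biases stabilize by about
100 thousand steps; the packaged runs train to an accuracy-based early
stop with generous caps around those points.

The synthetic world reproduces the structural properties the claims rest
on — schema-governed ordering, arbitrary role-filler pairings, controlled
train/test divergence — but not properties of natural text (meaningful
embeddings, variable story length, lexical ambiguity), so passing tests
support the architectural comparisons, not claims about language
processing.

Known limitations. Learning in the unlimited-filler graph regime is
strongly query-frequency dependent: the rarest query (QDessert, 12 of the
112 frames) needs on the order of 200 thousand steps before it exceeds
chance, several times longer than the common queries, so short
demonstrations show the full six-query pattern only partially; the same
holds for the query-time advantage of external-memory decoding over
hidden-state decoding, which emerges together with task success. At this
reduced vocabulary a plain RNN also creeps a few percent above chance on
non-Subject queries — unlike at full scale, where it sits at chance —
while remaining far below the external-memory architectures. The DNC is
trained only in small demonstrations (its step mechanics, gradients, and
analyses are fully tested; the packaged experiments train the lighter
architectures). And the exact composition of the historical base corpora
(the 50-word and 30-word vocabularies) is a convention documented above
rather than a derivable fact.
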