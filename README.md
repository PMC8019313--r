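# schemabind

Role-filler binding in recurrent networks with external memory.

Event schemata — structured templates like "visiting a coffee shop" — are
made of abstract *roles* (Poet, Drink, Customer) that each episode fills
with concrete *fillers* (chris, latte, alice). Understanding a new episode
requires **role-filler binding**: recalling which filler occupies a queried
role, even for fillers never seen before and pairings that contradict past
experience. `schemabind` implements a complete simulation pipeline for
studying whether recurrent neural networks learn this ability from
schema-generated stories:

* a stochastic story generator over an 11-state "coffee shop world" schema
  graph (24 paths, 112 answerable queries), plus the fixed linear story
  frame used by correlation experiments;
* random unit-norm 50-d word embeddings, with optional distributions X/Y/Z
  that shift even vector coordinates by ±0.5 to give fillers
  role-correlated statistics;
* four recurrent architectures with one contract — layer-normalized RNN and
  LSTM, Fast Weights (`A ← λA + η h hᵀ`, retrieval by one layer-normalized
  settling iteration), and a Differentiable Neural Computer (LSTM
  controller, 128×20 memory, content addressing + dynamic allocation +
  temporal links, 1 read/1 write head) — trained by hand-derived
  backpropagation through time (RcppArmadillo backend) with Adam at
  learning rate 1e-4, against softmax cross-entropy over corpus logits
  (default; its argmax equals cosine retrieval) or squared error to the
  target embedding;
* cosine nearest-neighbor retrieval evaluation with corpus-derived chance
  rates (e.g. 30 base words + 16×6 fresh fillers = 126 candidates, 0.8%
  chance);
* ridge-regression decoding (α = 1.0, 80/20 split, ranking score with
  chance 0.5) of fillers from hidden states and flattened external memory,
  and DNC read/write-location analyses;
* correlation-violation, correlation-retention, ambiguous-query (zero
  vector), and shuffled-story probes with per-role even/odd Welch
  t-statistics.

## A worked example

Train an LSTM on a reduced limited-filler experiment and test it on
stories whose fillers come from a disjoint pool:

```r
library(schemabind)
set.seed(1001)

graph <- coffee_shop_graph()
spec  <- experiment_spec("limited_unseen", graph = graph,
                         paths = enumerate_paths(graph)[1:2],
                         stories_per_path = 200, fillers_per_role = 6)
ds    <- build_limited_datasets(spec)

lstm  <- binding_model("lstm")
lstm  <- train_model(lstm, ds$train, epochs = 1200, eval_every = 50,
                     stop_train_acc = 0.9,
                     monitor_stories = length(ds$train$stories))
tail(lstm$curves, 1)
#>   epoch      loss train_acc val_acc
#> 7  8750 0.8225679 0.9494949      NA

evaluate_model(lstm, ds$test)
#> <eval_report> accuracy 0.000 (chance 0.0098, n = 497)
#>   per query: qdessert=0  qdrink=0  qemcee=0  qfriend=0  qpoet=0  qsubject=0
```

The network memorizes its training stories (95% train accuracy after 8,750
optimizer steps) yet scores **0%** on the disjoint-filler test set — below
the 1% chance rate — because it only ever predicts fillers from the
training pool:

```r
rep <- evaluate_model(lstm, ds$test)
mean(rep$predicted %in% ds$train_pool)
#> [1] 1
```

This is the characteristic failure mode of limited-filler training: the
network learns the schema but welds it to the filler vocabulary it saw.
Giving networks fresh random fillers in every training story
(`build_unlimited_datasets()`), or probing with the correlation designs
(`build_violation_datasets()`, `build_retention_datasets()`), tests
whether an architecture can bind *arbitrary* fillers instead.

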