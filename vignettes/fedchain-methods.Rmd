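---
title: "Methods: ledger-secured federated learning on synthetic EHR cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ledger-secured federated learning on synthetic EHR cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedchain)
```

# What the package simulates

`fedchain` is a desk-scale simulation of a healthcare consortium that trains
a diabetes risk classifier collaboratively without pooling patient records.
Five healthcare providers (by default) each hold a private shard of a
tabular cohort; only serialized model updates cross the trust boundary, and
every exchange — registration, consent, model submission, aggregation,
reward — is an Ed25519-signed transaction on an append-only, hash-chained
ledger with smart-contract semantics. Because real deployments of this
architecture are evaluated on an external proprietary-scale dataset, the
package instead ships a synthetic cohort generator with a *known* outcome
model, so that every claim the simulation makes (convergence, ceilings,
attack resistance, communication costs) is checkable against ground truth.

The components, bottom to top:

1. **Synthetic EHR generator** — cohorts with the schema of a public
   diabetes-prediction dataset (gender, age, hypertension, heart disease,
   smoking history, BMI, HbA1c, glucose, binary diabetes label) and a
   logistic ground-truth label model.
2. **Preprocessing** — imputation, categorical encoding, min-max scaling,
   class rebalancing by undersampling, and partitioning into client shards.
3. **Identity & ledger** — seedable Ed25519 key pairs, Ethereum-shaped
   addresses, signed transactions with per-sender nonces, hash-chained
   blocks, and a content-addressed off-chain blob store.
4. **Contracts** — deterministic state machines for role registration,
   consent, record writes, validated model-update submission, aggregation
   bookkeeping and flat per-contribution rewards, all with strict revert
   semantics.
5. **Federated learning** — gradient-boosted trees (xgboost), fine-tuned
   locally by continued boosting and aggregated by prediction distillation.
6. **Audit & attacks** — scripted adversarial scenarios and
   communication-overhead accounting.

# The synthetic cohort generator

The generator is first-class, tested code, not a fixture: its outcome model
defines the ground truth that the learning stack is judged against.

**Feature marginals.** The public dataset this schema emulates publishes no
per-feature distributions, so the marginals are the package's own choices,
picked once for clinical plausibility: age is truncated normal
$\mathcal{N}(42, 20^2)$ on $[0, 100]$ years; BMI is lognormal around
27 kg/m²; HbA1c is a two-component mixture (85% "healthy" around 5.5%,
15% "elevated" around 7%); glucose is $\mathcal{N}(140, 40^2)$ mg/dL
truncated at 40; hypertension and heart disease are Bernoulli(0.08) and
Bernoulli(0.04); gender and the six-level smoking history are categorical
noise features.

**Label model.** The diabetes label is Bernoulli with
$\Pr(y = 1 \mid x) = \sigma\!\big(\beta_0 + \beta^\top z\big)$, where $z$
holds the four continuous features standardized by frozen reference moments
(estimated once from a large Monte-Carlo draw of the marginals above) plus
the two raw 0/1 comorbidity indicators. Default per-SD log-odds: HbA1c 1.6,
glucose 1.4, age 0.8, BMI 0.6, hypertension 0.4, heart disease 0.3 — the
glycemic markers dominate, as they do clinically. The intercept $\beta_0$
is not a free parameter: it is calibrated by bisection on a $10^5$-sample
pilot draw so that the expected prevalence matches `target_prevalence`
(tolerance 0.002). The default prevalence is 0.10, reflecting the class
imbalance ("fewer positive cases") typical of diabetes screening cohorts;
the exact imbalance of the public dataset is not published, so this is a
default, not a reproduction.

**Bayes ceiling.** Because the label model is known, `bayes_accuracy()`
Monte-Carlo-estimates the accuracy of the rule "predict positive iff
$\sigma(\beta_0 + \beta^\top z) \ge 0.5$" — the ceiling no classifier
trained on these cohorts can beat beyond Monte-Carlo error. Under the
defaults it is ≈ 0.93. This is what makes "the federated model converged"
a falsifiable statement here.

**Missingness** is MCAR, injected per cell at a configurable rate over the
eight feature columns (never the label or the id); MAR mechanisms are out
of scope. What the generator does *not* emulate: longitudinal structure,
inter-feature correlation beyond the shared outcome, coded missingness
("No Info" smoking status is a category, not NA), and the real dataset's
marginals. Green tests therefore demonstrate correctness of the machinery
under a known model, not clinical performance on real data.

# Preprocessing choices

The published pipeline offers alternatives without choosing ("mean/median"
imputation, "one-hot or ordinal" encoding); the package defaults to
**median + mode** imputation and **one-hot** encoding (robustness, no
spurious category order), with the alternatives selectable. Columns more
than 50% missing are dropped (`drop_threshold = 0.5`). Min-max scaling maps
each fitted column to $[0,1]$; constant columns map to 0 and out-of-range
values at apply time are *not* clipped, so distribution shift stays visible.
A category unseen at fit time encodes as an all-zero indicator row with a
warning (ordinal: −1), not an error — a single odd record should not abort
a federated round.

Two ordering decisions matter for the privacy story:

* **Fit-on-init-subset.** All preprocessing statistics (medians, modes,
  category lists, min/max) are fitted on the orchestrator's public init
  subset and distributed with the global model. Clients never exchange
  statistics of their private rows.
* **Per-shard undersampling.** Class rebalancing (majority:minority 1:1 by
  default, majority rows subsampled without replacement) runs per client
  shard *after* partitioning; a central rebalancing pass would require
  pooling labels. Both orders are implemented; per-shard is the default.

Partitioning is `iid` (shuffle, near-equal split, sizes differing by at
most one) or `label_skew` (per-class shard proportions from a symmetric
Dirichlet($\alpha$), smaller $\alpha$ = stronger skew).

# Identity, ledger and contracts

**Keys and addresses.** Ed25519 throughout. The seeded path derives the
private scalar as SHA-256 of a tagged seed string — it exists so that
simulations are bit-reproducible and must never guard real assets; the
unseeded path uses OS entropy. An address is `0x` plus the last 20 bytes of
the SHA-256 digest of the raw public key, matching the Ethereum address
shape without claiming account compatibility (no Keccak).

**Canonical serialization.** Everything that is hashed or signed goes
through canonical JSON: keys sorted at every depth, no whitespace, UTF-8,
15 significant digits. Two structurally equal objects hash identically
across runs, which is what makes chain dumps byte-reproducible and state
digests comparable.

**The chain.** A single honest sequencer orders transactions by arrival —
consensus (PoS/PoW), forks and gas are infrastructure, not method, and are
out of scope. Block timestamps come from a monotone logical clock, so two
runs with one seed produce identical chains. A transaction is accepted only
if (1) its type is known, (2) its signature verifies against the sender's
*registered* key, (3) its nonce is exactly the sender's last accepted nonce
plus one (replay protection), and (4) the contract layer approves the
payload. Validation builds a complete candidate state first and the ledger
swaps it in only on acceptance, so a rejected transaction provably leaves
the digest of (contract state, chain, pending pool, nonces, off-chain
store) unchanged — the property the attack suite quantifies.

**Off-chain store.** Blobs (model updates, clinical records) live in a
local content-addressed store keyed by SHA-256; only hashes and metadata go
on-chain. Sidecar blobs ride with their transaction and are written only on
acceptance. An encryption hook for blobs exists (`model_cipher()`) and
ships as a pass-through, since the experiments specify signing + off-chain
storage rather than a cipher.

**Contract parameters.** The model-update performance floor defaults to
accuracy ≥ 0.5 on the public validation split (no threshold is published;
configurable). One update per client per round; duplicates and wrong-round
submissions reject. Consent is all-or-nothing per (owner, grantee);
purpose- and time-scoped consent is out of scope. Rewards are a flat
configurable amount per accepted contribution (default 10 units) — no
reward formula is published, so anything fancier would be invention.
Revoking a never-granted consent is recorded (auditability) but reports
`FALSE` and changes nothing.

# Federated learning by distillation

Tree ensembles have no averageable parameters, so classical federated
averaging does not apply. The published description — retraining the global
model on a compilation of the local models' predictions — is formalized as
**weighted soft-vote distillation**:

$$\bar p(x) = \sum_k w_k\, p_k(x), \qquad w_k = \frac{n_k}{\sum_j n_j}
\text{ (by size, default) or } w_k = \tfrac1K,$$

computed over the public init subset (never client data — using it would
break the privacy boundary). In `hard` mode (default) a fresh ensemble is
retrained on the labels $\mathbf{1}\{\bar p \ge 0.5\}$ (ties to positive);
in `soft` mode a squared-error regressor is fitted to $\bar p$ and
thresholded at predict time.

**Local fine-tuning** is continued boosting: `local_trees` (default 20) new
trees are appended to the received global ensemble, fitted to the client's
shard; full retraining is a selectable alternative. A single-class shard
makes the client skip the round. Model updates are full serialized
ensembles — trees have neither gradients nor averageable parameters — and
their byte size is what the communication report charges.

**Defaults and splits.** 5 clients, 10 rounds; init 10% (the "small
portion" used both for global initialization and as the distillation set),
validation 10% (the contract's public performance check), test 20% (one
shared held-out test set for all models — whether the published per-client
curves use a shared or per-client test set is unstated; shared is this
package's choice, stated as such). Hyperparameters default to 60 trees,
depth 3, learning rate 0.3, `base_score` pinned at 0.5 (keeps training
defined for single-class label vectors and boosters byte-reproducible);
`tune_hyperparams()` runs a seeded random search over a declared grid,
maximizing validation F1. All stage seeds derive from one master seed by
fixed offsets, so an adversary callback injecting extra transactions cannot
perturb the honest path's randomness — the paired clean/attacked runs in
the test suite are identical by construction unless an attack actually
lands.

**Problem sizes.** The shipped study conditions are $n = 10{,}000$ subjects
(convergence suite: five master seeds; demo: one), which puts ≈ 1,200 raw
rows per client and ≈ 240 balanced training rows after undersampling.
These sizes were chosen as the smallest at which the convergence behavior
is stable and binomial noise on the test metrics stays well inside the
tolerances below.

**What convergence means here.** With iid shards and a 10%-prevalence
logistic ground truth, the clients sit near their ceiling from round one
(the task is easy for 60 trees), so the honest expectation — mirrored in
the tests — is *flat* stability: mean client F1 non-decreasing through
round 4 within 0.02, all four metrics within 0.03 between rounds 4 and 10,
final global accuracy at least the round-1 client mean, at most the Bayes
ceiling plus Monte-Carlo error, and within 0.05 of a pooled-data comparator
trained on the union of the (undersampled) shards with identical
hyperparameters. Precision is structurally low (≈ 0.3) and recall high
(≈ 0.77): balanced local training at a 0.5 threshold trades false positives
for sensitivity on a 10%-prevalence test set. That trade-off is a property
of the rebalancing choice, not a defect.

# Communication accounting

Centralized cost: each client uploads its raw chunk once — the cohort-CSV
bytes of its partitioned rows, *before* any training-side rebalancing.
Federated cost per round: every client's serialized update up, plus the
global blob broadcast down to all $K$ clients:

$$B_{fed} = \sum_{r} \Big( \sum_k \lvert m_{r,k}\rvert \;+\; K\,\lvert g_{r-1}\rvert \Big).$$

No byte values are published for this comparison, so the formula above is
this package's explicit definition. Honest finding at desk scale: with
full-ensemble updates (~60–75 KB) and only ~2,000 rows per client
(~130 KB), ten federated rounds move ≈ 19× *more* bytes than the one-time
centralized upload. The federated advantage is real only when per-client
shard bytes exceed roughly $2 \times \text{rounds} \times \text{blob}$
bytes — a condition the test suite asserts as the conditional claim it is.
It holds for datasets tens of times larger per client, or for compact
update encodings; it does not hold at this simulation's scale, and the
package reports the measured inequality rather than the advertised one.

# Numerical and degenerate-input decisions

* Metric denominators of zero (no predicted or no true positives) yield 0.
* Distillation ties ($\bar p = 0.5$) label positive.
* Constant columns min-max-scale to 0; apply-time values outside the fitted
  range are not clipped.
* Mode imputation breaks frequency ties toward the lexicographically first
  level; `iid` partition gives the remainder rows to the lowest-numbered
  shards — both purely for determinism.
* A round with zero accepted updates carries the previous global forward
  (logged), rather than aborting the run.
* `n = 0` cohorts, empty blocks and zero-round runs are all legal and
  covered by tests.

# Known limitations

* One sequencer, no consensus, no networking: the ledger models integrity
  and auditability, not distributed agreement.
* The seeded key path is for reproducibility only.
* Synthetic cohorts make machinery verifiable but say nothing about
  clinical transportability; the published headline accuracy on the
  external dataset is deliberately not asserted here.
* Secure aggregation, differential privacy, homomorphic encryption and
  client dropout are out of scope; the encryption hook is an interface,
  not a cipher.
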