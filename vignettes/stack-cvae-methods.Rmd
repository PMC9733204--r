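---
title: "Methods: stack-augmented conditional VAE with reward-driven fine-tuning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stack-augmented conditional VAE with reward-driven fine-tuning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`stackcvae` generates molecules as SMILES strings with a conditional
variational autoencoder (CVAE) whose encoder is a *stack-augmented*
recurrent network, and then fine-tunes the decoder by policy-gradient
reinforcement learning toward molecules that are predicted to be
synthesizable, to bind a panel of on-target proteins, and to avoid a panel
of off-target proteins.

### Conditioning

Each molecule is described by the triple (molecular weight in Da, LogP,
TPSA in Å²), computed by the OpenBabel descriptor implementations via
ChemmineOB. During pretraining every molecule is conditioned on its **own**
descriptors; at generation and fine-tuning time the condition is the
**reference molecule's** descriptors (e.g. sorafenib for a Raf-kinase
campaign). Raw descriptor scales differ by orders of magnitude (hundreds
of Da vs. a few LogP units), so condition vectors are z-scored with
corpus statistics that are stored inside the model and its checkpoints.

### The stack-augmented cell

A recurrent cell with hidden state $h_t \in (0,1)^m$ is coupled to an
external differentiable stack $s_t \in [0,1]^{p \times k}$ (depth $p$,
element width $k$, top element in row 1):

$$h_t = \sigma(U x_t + R h_{t-1} + P\, s_{t-1}[1,\cdot])$$
$$a_t = \mathrm{softmax}(A h_t), \qquad v_t = \sigma(D h_t)$$
$$s_t[1,\cdot] = a_t[\mathrm{PUSH}]\, v_t + a_t[\mathrm{POP}]\, s_{t-1}[2,\cdot] + a_t[\mathrm{NOOP}]\, s_{t-1}[1,\cdot]$$
$$s_t[i,\cdot] = a_t[\mathrm{PUSH}]\, s_{t-1}[i-1,\cdot] + a_t[\mathrm{POP}]\, s_{t-1}[i+1,\cdot] + a_t[\mathrm{NOOP}]\, s_{t-1}[i,\cdot] \quad (i > 1)$$

With one-hot actions this reduces to a literal pushdown automaton, and the
package carries that automaton (`pushdown_oracle()`) as an executable
specification: the test suite checks bit-exact agreement over a thousand
random traces, and checks that the analytic gradients of a full cell step
match numerical differentiation.

Design choices where the architecture description was open:

* **Fixed stack depth.** The stack is a fixed $p \times k$ matrix
  (defaults 10 × 50): a PUSH discards the bottom row, a POP pulls in a
  zero row. A conceptually unbounded stack cannot be batched or
  differentiated as cleanly, and the configured depth of 10 is what the
  architecture actually uses.
* **$D$ is $k \times m$.** The pushed value must be a width-$k$ stack
  element; the stack-read matrix $P$ being $m \times k$ confirms stack
  elements are $k$-vectors.
* **One stack per layer.** In the 3-layer encoder each layer owns a
  private stack and layer $l$ consumes layer $l-1$'s hidden sequence; the
  multi-layer wiring is not otherwise determined.
* **Soft actions throughout.** Action probabilities are never hardened to
  argmax, including at generation time.

### CVAE objective

The encoder maps the embedded, condition-concatenated token sequence
(start token `<`, end token `>`) to a Gaussian posterior
$Q(z \mid X, c) = \mathcal N(\mu, \mathrm{diag}(e^{\lambda}))$; the prior is
taken as standard normal, independent of the condition, because generation
samples $z \sim \mathcal N(0, I)$ unconditionally. Training minimizes

$$\mathcal L = \underbrace{-\textstyle\sum_t \log p(x_{t+1} \mid x_{\le t}, z, c)}_{\text{token cross entropy}}
 + \tfrac12 \textstyle\sum_j \left(\mu_j^2 + e^{\lambda_j} - 1 - \lambda_j\right)$$

with teacher forcing, reparameterized sampling, and Adam (default learning
rate 1e-3, batch 64; both exposed in the config). The KL weight is 1 with
no annealing. The decoder is a GRU stack (3 × 512 by default) that
receives $[\mathrm{emb}(x_t); z; c]$ at **every** step — feeding $z$ and
$c$ per step rather than only initializing the hidden state keeps the
conditioning signal alive over long sequences. The latent and embedding
dimensions (128 each) are package defaults; nothing in the architecture
pins them.

All of this is implemented in base R matrix code with hand-derived
backpropagation through the stack cell, the GRU, the latent
reparameterization and the embeddings. The gradient of every component is
tested against numerical differentiation.

### Rewards

For a generated SMILES the environment computes three components from two
oracles (a binding-affinity predictor scored so that ≈5–6 marks useful
binding, and a retrosynthetic-accessibility score RAscore in [0, 1]):

$$\mathrm{reward}_1 = \begin{cases} 1 & \mathrm{RAscore} = 0 \\ 5\,\mathrm{RAscore} + 1 & \text{otherwise} \end{cases}
\qquad
\mathrm{reward}_2 = \begin{cases} (\mathrm{aff}_A - 4)^2 + 1 & \mathrm{aff}_A > 5 \\ 1 & \text{otherwise} \end{cases}$$

$$\mathrm{reward}_3 = \begin{cases} 6 & \mathrm{aff}_D < 5.5 \\ 1 & \text{otherwise} \end{cases}$$

with $\mathrm{aff}_A$, $\mathrm{aff}_D$ the panel-mean affinities for the
on- and off-target groups, and total reward the sum. RAscore is accepted
as a continuous value: the formula multiplies it by 5, which only makes
sense on a continuous scale, even though the score is sometimes described
as binary. Invalid SMILES receive the all-minimum total of 3 — rather
than 0 — so the policy-gradient terms stay finite while invalidity is
still dominated by any molecule that clears a threshold.

The real predictors are deliberately **not** bundled. Oracles are plain
callables behind a registry; the packaged `"mock"` oracles are
deterministic, structure-dependent stand-ins (affinity increases with
nitrogen fraction plus a seeded per-protein offset; RAscore is logistic in
heavy-atom count) so the whole loop runs and is testable offline with a
learnable signal. Conclusions from mock-oracle runs concern the learning
machinery, not chemistry.

### Reinforcement learning

The decoder is the policy; an episode samples $z \sim \mathcal N(0, I)$,
generates until `>` or the length cap, and receives the total reward at
the end (intermediate rewards are zero). The loss for one episode is

$$\mathrm{Loss} = -\sum_{t=0}^{T-1} \log(y_t)\, \cdot \mathrm{discounted\ reward}_t$$

where $y_t$ is the probability of the emitted token and the discounted
reward anchors the full terminal reward at the final step, attenuated by
$\gamma^{T-1-t}$ toward the start (default $\gamma = 0.1$). Reading
"reward multiplied by a discount rate" as a flat constant would merely
rescale the learning rate; the geometric return is the standard
interpretation that makes $\gamma$ a discount.

Two empirically forced choices, both measured on the toy corpus before
being adopted:

* **The end-token emission is part of the gradient.** With $\gamma = 0.1$
  the return is so myopic that effectively only the final action is
  reinforced. If that final action excludes the `>` emission, reinforcing
  the last interior token systematically steals probability mass from the
  end token, sequences lengthen, validity decays, and mean reward falls.
  Including the termination action (with the terminal weight) makes
  finishing a good molecule itself reinforceable. The exported episode
  trace still reports `step_probs`/`discounted` over the $T$ interior
  tokens, matching the loss formula above.
* **A moving-average reward baseline, on by default.** Every reward is
  ≥ 3, so baseline-free REINFORCE pushes up the probability of *every*
  sampled episode, good or bad; at toy scale this demonstrably erodes the
  pretrained policy (mean reward drifts down, or collapses outright).
  Subtracting a running mean restores a signed signal, and the reward
  curve then rises as expected. `baseline = FALSE` recovers the
  unmodified estimator.

Only the decoder (GRU layers and output head) is updated; the encoder is
unused at RL time because $z$ comes from the prior, and the shared token
embedding is kept frozen with it. The RL update uses plain SGD: with a
stochastic REINFORCE gradient, Adam's per-coordinate normalization mostly
amplifies sampling noise, which we observed as reward decline at equal
learning rates. The condition vector is fixed to the reference drug's
descriptors for all episodes.

## Corpus handling and the toy generator

Training corpora are filtered to valid SMILES with string length < 100
(strict) and molecular weight in [150, 500] Da (inclusive — "between" is
read inclusively). Tokenization is character-level except that the
two-character halogens `Cl`/`Br`, bracket atoms such as `[nH]`, and `%nn`
ring closures are single tokens; the vocabulary is the sorted token union
plus `<`, `>`, and a padding token, so it is independent of corpus order.

Validity is decided by a strict syntactic check (balanced branches and
bracket atoms, paired ring-closure digits) *and* an OpenBabel parse. The
syntactic pre-check matters because OpenBabel silently repairs some
malformed strings (an unclosed branch `C(` parses as methane), which would
otherwise inflate validity metrics.

`generate_toy_corpus()` assembles molecules from a fixed fragment grammar
— alkyl seeds, aromatic/aliphatic rings, amide/ester linkers, terminal
halogen and small polar caps — so every emitted string is valid by
construction, short (mean ≈ 24 characters), and diverse. This emulates
the *formal* properties a real corpus exercises (branches, rings,
aromaticity, heteroatoms, two-character tokens) but not its chemical
breadth: no stereochemistry, charges, isotopes, fused polycycles, or
macrocycles. Tests passing on the toy corpus therefore certify the
learning and evaluation machinery, not performance on pharmaceutical
chemistry at scale.

## Evaluation

* **Validity / uniqueness / novelty** are the three nested percentages of
  a generated batch: parseable; structurally distinct among the valid
  (canonical-SMILES identity, with a raw-string mode behind a flag);
  distinct and absent from the canonicalized training set. The nesting
  order is asserted as a property over random batches.
* **Property windows** count molecules whose descriptor or oracle value
  lies within a fractional tolerance (default 10%, inclusive) of the
  reference molecule's value.
* **The composite score** is
  $1 / (0.3\,\frac{mw + logP + TPSA}{3} + 0.7\,\frac{bind_A + 1 - bind_D + 1 - RA}{3} + \varepsilon)$
  over batch-min-max-scaled absolute descriptor differences and scaled
  affinities. The $bind_A$ term is implemented **as printed**, although as
  written a higher scaled on-target affinity *lowers* the score, which is
  at odds with the score's stated intent; a sign-corrected variant
  ($1 - bind_A$) is available via `corrected = TRUE` rather than silently
  "fixing" the formula. Min-max scaling is over the batch being scored
  (the scaling population is otherwise unspecified); constant batches
  scale to zero, and $\varepsilon = 10^{-9}$ guards the division. Top-k
  selection breaks score ties lexicographically on canonical SMILES so
  rankings are reproducible.

## Numerical and reproducibility choices

* Every stochastic entry point (corpus generation, pretraining,
  episode sampling, generation, fine-tuning) takes an integer seed and
  restores the caller's RNG state afterwards; identical seeds give
  bit-identical results, which the tests assert.
* Softmaxes subtract the row maximum; cross entropy floors probabilities
  at 1e-12; the padding token is masked out of generation distributions.
* Checkpoints store weights and condition statistics in an RDS payload
  (bit-exact round trip) beside a JSON manifest describing vocabulary,
  configuration and format version.
* Degenerate inputs: empty corpora, zero-epoch training, zero-length
  episodes (immediate `>`, scored as an invalid empty molecule at the
  minimum reward) and truncation at the length cap are all defined and
  tested behaviors.

## Problem sizes used by the test suite

The packaged studies run at desk scale, chosen once as the smallest sizes
at which each qualitative behavior is clearly expressed: a 500-molecule
toy corpus with a 1-layer, 32-unit model (stack 4 × 8, latent 8) for the
pretraining loss trend; 150 RL epochs of 32 episodes for the reward trend;
a 3-token bandit for the policy-gradient sanity check; 1000 random traces
for the stack/pushdown equivalence. The full-scale defaults (3 × 512
model, 500 RL epochs) remain the package defaults for real corpora.

## Known limitations

* OpenBabel's descriptor implementations differ numerically from other
  toolkits' (its LogP for sorafenib is ≈ 6.1 where Crippen-style
  implementations give ≈ 4–5); conditioning and property windows are
  consistent within the package but not interchangeable across toolkits.
* OpenBabel accepts some chemically dubious strings (hypervalent atoms)
  that stricter parsers reject, so validity percentages are upper bounds
  relative to such parsers.
* Pure-R training is practical at desk scale only; the full-scale
  defaults would require hours to days on a large corpus.
* The mock oracles are monotone in crude structural features by design;
  they cannot rank real binders.
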