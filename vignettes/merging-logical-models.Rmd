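---
title: "Merging Boolean gene-regulatory models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging Boolean gene-regulatory models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BoolMerge)
```

## The modelling setting

A Boolean logical model represents a gene-regulatory network as a set of
nodes holding values 0/1, each updated by a Boolean rule over its
regulators. Long-term behaviour is summarised by **attractors**: under the
synchronous scheme all nodes update simultaneously and the dynamics is a
deterministic map whose cycles (including fixed points) are the
attractors; under the asynchronous scheme one unstable node updates at a
time and the attractors are the terminal strongly connected components of
the resulting state-transition graph. Fixed points are the solutions of
f(x) = x and coincide between the two schemes.

BoolMerge addresses the situation where two or more published models
describe overlapping parts of one system. After node symbols are
harmonized to a common nomenclature, the node set of the merged model is
the union of the source node sets; nodes known to only one model keep
their rule; nodes regulated in several models get a composed rule.

## The three composition strategies

For a node with source rules $f^{M_1}, \dots, f^{M_n}$:

* **OR**: $f = \bigvee_j f^{M_j}$ — pointwise maximum.
* **AND**: $f = \bigwedge_j f^{M_j}$ — pointwise minimum.
* **Inhibitor Wins (IW)**: let $I$ be the union, over all source rules, of
  the regulators classified as inhibitors of this node. Then $f(x) = 0$ if
  some member of $I$ is active in $x$, and $f(x) = f^{OR}(x)$ otherwise;
  in closed form $f = \neg(\bigvee I) \wedge f^{OR}$.

Three readings of IW were genuinely open and we fixed them as follows.
First, "an active inhibitor" means a regulator that inhibits the target in
*some* source rule and is ON in the current state — this makes IW a
well-defined Boolean function and agrees with the interaction-graph
translation rule (`graphToRules()`), where inhibition dominates
activation edge-wise. Second, the inhibitor set is pooled across all
source models rather than applied per model, matching the existential
flavour of the definition ("any edge in the original models"). Third,
regulators with both activating and inhibiting witnesses (dual) count as
inhibitors under IW, with a warning — the conservative choice when
inhibition is meant to dominate.

### What the strategies do and do not guarantee

$f^{IW} \le f^{OR}$ and $f^{AND} \le f^{OR}$ hold pointwise by
construction. The stronger chain $f^{AND} \le f^{IW}$ is **not** a theorem
under the hard-dominance semantics: with $f_1 = A \lor B$ and
$f_2 = \neg A \lor B$, the regulator $A$ is a pure inhibitor of $f_2$, yet
at the state $A{=}1, B{=}1$ both source rules evaluate to 1, so
$f^{AND} = 1$ while $f^{IW} = 0$. The chain does hold whenever every rule
has the activator/inhibitor template form
$(\bigvee \text{act}) \wedge \neg(\bigvee \text{inh})$, because there an
active inhibitor forces its own rule (hence AND) to 0. The test suite
asserts exactly these guarantees: the universal $IW \le OR$, the full
chain on template-form rules, and the counterexample above as documented
semantics.

### Sign inference

Whether a regulator "inhibits" a target is decided semantically by
default: regulator $r$ is an inhibitor if some state exists where raising
$r$ lowers the rule output and no state where it raises it. This is an
exhaustive flip test over the rule's truth table, capped at 16 variables
(65,536 assignments — instantaneous at that size, and published Boolean
rules essentially never have larger in-degree). Past the cap a syntactic
fallback classifies a regulator as inhibitory when an occurrence sits
under an odd number of negations. Semantic inference is the default
because syntactic negation misreports signs on simplifiable rules (in
$A \lor (A \wedge \neg B)$, $B$ is inert).

## Rule grammar and canonical forms

Rules use identifiers, `0`/`1`, `!`, `&`, `|`, and parentheses, with
precedence `!` > `&` > `|` and left associativity — the convention of
common Boolean-rule file formats; the source material fixes the operator
symbols but not the precedence, so we adopt the file-format standard.
Constants are admitted so clamped genes are expressible. Expression trees
keep AND/OR children flattened, serialisation emits minimal parentheses,
and identifiers are case-sensitive: symbol matching across models happens
only after harmonization, never by case folding.

## Harmonization

Offline mapping tables (alias → approved symbol, with provenance
`alias`/`previous`/`ortholog`/`manual`) are the source of truth; live
nomenclature lookups are deliberately not a dependency. Renaming never
merges two nodes silently — a collision aborts with the offending nodes
listed, since resolving it (e.g. two paralogs mapped to one symbol) is a
curation decision. Unmappable symbols such as fusion proteins or
complexes pass through unchanged and are flagged in the report. Orthology
(e.g. mouse *Gata1* → human *GATA1*) is handled by ortholog rows in the
same table; nodes whose regulatory logic is suspected to diverge between
species can only be flagged in the report, because no automatic criterion
exists.

## Dynamics: choices that matter

* **State encoding.** States are packed into integers over the
  lexicographically sorted node order (first sorted node = bit 0), making
  attractor order and labels (`<modelId>1`, `<modelId>2`, … by smallest
  member state) deterministic.
* **External inputs** hold their value under both schemes. Because an
  input never changes, exhaustive enumeration automatically analyses every
  input combination, and each attractor reports its input context.
* **Exhaustive cap.** Exact mode enumerates all $2^n$ states and is capped
  at 22 nodes (≈4M states); the cap is where full asynchronous
  state-transition graphs stop being comfortable on a desktop. Beyond it,
  sampling mode must be requested explicitly: random starts with
  trajectory cycle detection (synchronous) or random walks plus a bounded
  forward-closure terminal-SCC test (asynchronous). Sampled attractors are
  always genuine (a forward-closed set's terminal SCC is an attractor),
  but completeness is flagged `unknown` and never silently upgraded.
* **Terminal SCCs** are computed with igraph's strong components; the test
  suite cross-checks them against an independently hand-written Kosaraju
  implementation on a state-transition graph built by a different code
  path.
* **Activation frequency** defaults to `uniform_attractor` weighting (mean
  within each attractor, then across attractors), with `uniform_state` as
  the alternative; the weighting used is part of the output, since the two
  differ whenever cyclic attractors have unequal sizes.

## Phenotype scoring

Phenotypes (proliferation, apoptosis, differentiation) are Boolean
read-out expressions over model nodes, not extra nodes: they leave the
dynamics untouched while providing the score
proliferation − apoptosis − differentiation ∈ [−2, 1] per state, averaged
within and then across attractors. Averaging over attractors is the
default (`mode = "mean"`); per-attractor scores are exposed because a
designated-attractor convention is equally defensible. Mutation profiles
clamp genes (GoF → constant 1, LoF → constant 0); the effect direction
must be supplied per gene, as no general rule derives it from mutation
data. Cohort scoring computes each distinct profile once, weights it by
patient count, and supports weighted Pearson/Spearman correlation against
an outcome (integer weights replicate observations).

## The synthetic generator

`randomModel()` draws OR-of-ANDs rules over at most `kRegulators`
regulators (default 2), with literals positive with probability
`activationBias` (default 0.5, a neutral mix so that all three strategies
and the sign classifier are exercised; bias 1 produces inhibitor-free
networks). `overlappingPair()` emulates the published-model-pair setting:
a shared core whose rules use only core genes (so both models carry
equivalent rules at `divergence = 0`), plus private genes per model; with
probability `divergence` a shared rule is regenerated in the second model
and recorded as ground truth. The RNG is pinned (Mersenne-Twister) and
the caller's RNG state is restored, so a seed fully determines a fixture.

What the generator does **not** emulate: scale-free topology, biologically
calibrated rule distributions, canalising functions, or the
curation noise of real published models (typos, implicit inputs,
multi-valued species). Green tests on synthetic pairs therefore establish
the algebraic and dynamical correctness of the pipeline, not that any
particular pair of real models merges into a biologically valid whole —
that judgement still needs the evaluation tools (retention report,
clustering, phenotype scores) applied case by case.

## Problem sizes used by the checks

The packaged checks run 500 random overlapping pairs (4–7 nodes per model,
overlap 2–4) against brute-force implementations of the three composition
formulas, 200 random models (3–8 nodes) against independent synchronous
and asynchronous attractor oracles, and 1,000 random expressions through
the parser round trip — sizes at which exhaustive truth tables and full
state-transition graphs are exact, which is the point: every comparison is
against an enumeration, not a heuristic. The acceptance script uses an
8 + 10 node pair with a 4-gene shared core, keeping the 14-node merged
model well inside exact asynchronous analysis.

## Degenerate inputs and edge cases

* A rule whose variables are all inert (e.g. $A \wedge \neg A$) has empty
  semantic support; such a node is treated as regulated by a constant, not
  as an input.
* A node that is an input in one model and regulated in another takes the
  regulated rule(s): a missing rule is missing knowledge, not a constant.
  The merge report flags every such resolution.
* The bnet format has no input keyword, so inputs are written as the
  self-identity line `A, A` and read back as inputs. An explicit
  self-identity rule is therefore indistinguishable from an input after a
  bnet round trip; the two have identical dynamics (both hold their
  value), and the round-trip guarantee is stated up to this equivalence.
* SBML-qual species with `maxLevel > 1` raise an error naming the species;
  nothing is silently binarised. Only Boolean models are in scope.
* Empty shared gene sets make Hamming distance undefined and raise; zero
  variance makes correlation undefined and raises.

## Known limitations

Multi-valued and probabilistic logics are out of scope, as is automatic
strategy selection; the IW inhibitor cap falls back to syntactic signs
rather than BDD techniques; sampling mode reports no basin statistics; and
the SBML-qual dialect is the minimal and/or/not-over-equality subset that
the major qualitative-modelling tools emit — documents using richer MathML
are rejected rather than approximated.
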