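---
title: "Methods: cost-reduction grammar induction for clinical sublanguage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cost-reduction grammar induction for clinical sublanguage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clingram)
```

## The model

`clingram` treats grammar induction as lossless compression of a corpus of
tagged sentences. A grammar and the derivations of all sentences under it
are a two-part code; the induced grammar is the one that (locally)
minimises the weighted code length

$$ C \;=\; f\,C_G \;+\; (1-f)\,C_D, \qquad f \in [0,1], $$

where the grammar cost charges $(1+|\beta|)\log_2|\Sigma|$ bits per
production $A \to \beta$ ($|\Sigma|$ counts terminals **and**
nonterminals), and the derivation cost charges $\log_2|P(s)|$ bits per
expansion of a nonterminal $s$ with $|P(s)|$ alternative productions,
summed over all corpus sentences *including duplicates*. Uniquely
expandable nonterminals are free: the receiver can reconstruct those
choices. $f=0.5$ is order-equivalent to the plain two-part sum; moving $f$
trades grammar size against derivation specificity and spans a family of
grammars from maximally specific ($f=0$: one production per unique
sentence) to maximally general ($f=1$).

Assumptions worth stating explicitly:

* **$|\Sigma|$ is dynamic.** Every cost is evaluated with the *current*
  inventory size, so adding a symbol re-prices every production. This is
  the only reading under which "the cost of the grammar" stays well
  defined while operators add and retire symbols; the alternative
  (freezing $|\Sigma|$ at its initial value) would make merge deltas
  systematically wrong after the first application.
* **Costs are measures, not codes.** No bit stream is ever produced;
  costs are real-valued and all comparisons happen in bits (base-2 logs
  throughout).
* **Duplicates matter twice.** The corpus keeps repeated sentences: each
  contributes a derivation to $C_D$ (clinical reports repeat sentences
  verbatim, and this repetition is what makes chunking profitable), while
  the initial grammar has one production per *unique* sentence.

## The search

The trivial initial grammar has `S -> W1..Wn` per unique sentence and one
shared pre-terminal `W -> w` per unique tag (pre-terminals exist because
the operators work on nonterminals only; sharing them keeps $|\Sigma|$
linear in the tag alphabet). The greedy loop enumerates, at every step:

* **combine** instances: every contiguous nonterminal n-gram
  ($2 \le n \le$ `max_n`, default 4) occurring on any right-hand side,
  counted left-to-right non-overlapping — the same tiling the rewrite
  uses, so the estimated saving is exactly what replacement realises;
* **merge** instances: every unordered pair of nonterminals except the
  start symbol.

Deltas are **exact**, not approximated: combine provably leaves $C_D$
unchanged (the new symbol has a single expansion, hence zero encoding
cost) and cannot collapse productions (the tiling rewrite is injective on
right-hand sides), so its delta has a closed form; merge deltas are
computed by simulating the relabel-and-deduplicate over the affected
productions, in compiled code, using maintained per-nonterminal expansion
counts. The test suite checks every candidate's delta against
apply-then-recompute-from-scratch at $10^{-9}$ bits.

The instance with the most negative delta is applied; the loop stops when
none improves the cost. Each applied step strictly decreases a quantity
bounded below by zero, so termination is guaranteed. Ties are broken
deterministically: combine before merge, longer n-grams first, then
lexicographic operand order — a convention (nothing in the method fixes
it) chosen so identical inputs give identical runs.

Two hard constraints, both on by default, are enforced by simulating the
post-application grammar:

* **No recursion**, direct or indirect ($A \Rightarrow^+ A$ through any
  chain). Recursion collapses grammar cost so effectively that the search
  otherwise jumps straight to tiny, overly general grammars; indirect
  cycles can be created by merges, so the check is a full cycle detection,
  not a self-loop test.
* **Tag blocklist**: `verb, det, prep, aux, conj` must not be derivable
  at right-hand-side position ≥ 2 of any production *other than
  expansions of the start symbol*. A nonterminal inherits "blocked" from
  any blocked terminal derivable from it. The start-symbol exemption is a
  deliberate design decision: the initial sentence templates necessarily
  carry verbs and prepositions in non-initial positions, and a literal
  reading (no production anywhere) would deadlock the search before its
  first step. The rule's purpose is to stop *learned constituents* from
  pairing, e.g., subject with verb or noun with a following preposition.

## Parsing and probabilities

Grammars are parsed **as induced** — right-hand sides of any length, no
binarisation. The parser is a span chart dynamic program generalised to
n-ary rules (a backward tiling DP matches each rule's right-hand side
against a span), with unit-production relaxation; for the acyclic grammars
the induction produces this is exact, and it is verified against an
exhaustive enumeration oracle on hundreds of random grammar/sentence
pairs. Equal-probability ties are broken by production creation order at
the topmost decision, then children left to right, earlier split points
first; "iteration zero" parsing (no probabilities at all) is the same
machinery with all rule weights equal, which returns the deterministic
first parse in that canonical order. Unknown tokens yield a distinct
`unknown_token` no-parse outcome; there is no smoothing.

Probabilities come from hard EM: uniform initialisation ($1/k$ over the
$k$ expansions of each nonterminal), then repeatedly parse the training
corpus (duplicates weighted), count production usages in each sentence's
single best parse, and set `prob = usage / lhs_total`. Numerical
conventions: unparsable sentences contribute nothing; a left-hand side
with zero total count keeps its previous distribution (rather than
becoming undefined); optional additive smoothing `alpha` is available but
off by default. The per-iteration Viterbi log-likelihood is monotone
non-decreasing (the classic hard-EM argument; asserted numerically at
$10^{-9}$), and in practice the probabilities stop changing within five
iterations. A fractional variant counts all parses of a sentence weighted
by their normalised probabilities; it enumerates parses explicitly
(finite under the recursion ban, capped by `max_parses`), which is
exponential in principle but cheap at clinical sentence lengths.

## Evaluation

Unlabeled bracketing only: induced labels (`C1`, `M3`, ...) are system
generated and cannot be scored against anything. Width-1 spans and the
full-sentence span are excluded at construction — they are correct for
every parse. Corpus scores are micro-averaged (summed intersections over
summed set sizes), the PARSEVAL-style default and the stable choice when
many short sentences have empty bracket sets; unparsed sentences
contribute empty predictions (a recall penalty, no precision penalty),
with `skip_unparsed` exposing the alternative. The novel-sentence parse
rate counts a test sentence as novel iff it is not string-identical to
any training sentence.

## The synthetic world

The corpus the original method was developed on is access-restricted, so
every experiment here runs on a synthetic stand-in designed to reproduce
the *statistical shape* of tagged clinical text:

* an acyclic reference PCFG (`clinical_like`) over 13 POS-like and 8
  semantic-class tags: determiner/adjective noun groups with
  semantic-class heads, prepositional attachment (noun- and
  verb-attached, a genuine ambiguity that probabilities must resolve),
  conjunction, measurements (`num unit`), auxiliary + participle verb
  groups;
* sentence length capped at 10 by rejection (truncation would corrupt
  gold trees); the resulting mean length is ≈ 6.4 tokens;
* Zipfian sentence-type reuse (exponent 1 over a pool of 1.25× the
  requested size), giving ≈ 70% test/train sentence overlap — the
  duplication level characteristic of discharge summaries. `zipf_s = 0`
  disables the pool and draws every occurrence independently;
* gold trees for all test sentences, giving gold bracket sets for free.

What a green test on this world does establish: the cost accounting,
operators, search, parser, EM and scoring interact correctly end to end,
and the method's qualitative behaviours (specific-to-general sweep with
$f$, training coverage always 100%, merges only growing the language)
hold. What it does **not** establish: bracketing accuracy on real
clinical text. Synthetic gold shares its generative process with the
corpus; human bracket conventions do not. Two concrete consequences,
both computed by the acceptance suite and `f_sweep()`: on this world the
bracketing F of the induced grammar keeps improving as $f$ approaches 1
(the recursion ban and the tag blocklist prevent the degenerate collapse
that punishes overly general grammars on real text, and in-distribution
gold flatters them), so the interior-$f$ optimum reported on real data
does not reproduce here; and the gain from probabilities over the
deterministic first parse is marginal on this world, because the induced
grammars are far less ambiguous than grammars induced from real reports.

For parameter recovery we compare EM output against the **gold-tree usage
frequencies of the sampled corpus**, not the nominal reference
probabilities: the length cap conditions the distribution (several
production frequencies shift by up to ≈ 0.09), so the nominal values are
not the estimand of any estimator that only sees capped data. Soft
(fractional) EM is the consistent estimator and is used for the recovery
check; hard EM — the production procedure — is what the five-iteration
convergence check runs on.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `f` | 0.5 | weight on grammar cost; higher = smaller, more general grammar |
| `max_n` | 4 | longest n-gram the combine operator considers |
| `forbid_recursion` | `TRUE` | reject operators creating derives-cycles |
| `blocked_tags` | verb, det, prep, aux, conj | tags banned from non-initial RHS positions of learned productions |
| `tol` | 1e-9 bits | deltas above `-tol` count as non-improving |
| `iterations` (EM) | 5 | hard-EM passes; probabilities stabilise within this |
| `smoothing_alpha` | 0 | additive count smoothing (0 = raw frequencies) |
| `max_len` (profile) | 10 | sentence-length cap, enforced by rejection |
| `zipf_s` (profile) | 1 | sentence-reuse exponent (0 = independent draws) |

## Known limitations

* The greedy search finds local minima only; no beam or restarts.
* Probabilities are estimated after induction, never used during it.
* Merge considers pairs only (wider merges are combinatorially
  expensive and expressible as sequences of pair merges).
* The parser's Viterbi extraction assumes no probability-1 derivation
  cycles; recursive grammars are supported for recognition but the
  language/enumeration oracles refuse or truncate them.
* The `f` axis follows the printed objective ($f$ multiplies $C_G$).
  Reports built on the opposite convention (where large $f$ means
  *restrictive*) must flip the axis: an optimum quoted at $f^\* = 0.15$
  there corresponds to $1 - f^\* = 0.85$ here.
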