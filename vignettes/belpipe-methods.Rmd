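---
title: "Methods: rule-based BEL statement extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based BEL statement extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(belpipe)
```

## The task and the model

A BEL statement is a triple `subject relation object` whose sides are
*abundances* — protein `p()`, chemical `a()`, biological process `bp()`,
pathology `path()` — optionally wrapped in a molecular *function*: `act`
(molecular activity), `tscript` (transcription), `complex`, `deg`
(degradation), `pmod` (protein modification, serialized BEL-1.0-style as
an argument inside the protein term), `tloc` (translocation). `belpipe`
models exactly the two causal predicates, `increases` and `decreases`;
the statement parser rejects any other relation explicitly rather than
guessing at semantics that are not modeled.

Extraction is a pipeline of four rule stages over a sentence and its
constituency parse. The underlying assumption is the *SVO hypothesis*: a
causal statement is expressed by a relation verb whose syntactic agent
contains the subject entity and whose patient contains the object entity.
Sentences that violate it (passive voice without an agent phrase after
the verb, causes buried in temporal or locative adjuncts, functions with
no lexical trigger) are by design not extracted; the packaged worked
examples include several such sentences so the scorer's false-negative
accounting is exercised honestly.

## Surface normalization and dictionary matching

`normalize_surface()` applies the basic rules in a fixed order: strip a
leading `"human "` (to a fixpoint) and a leading standalone `"h"` when
the remainder looks gene-like; lowercase; remove hyphens and periods;
collapse whitespace; strip one trailing plural `"s"`. Two details are
deliberate deviations forced by the idempotence requirement (the function
must be a fixpoint of itself, and is property-tested on 10,000 random
strings):

* the `"h"`-prefix rule fires only when the remainder starts with an
  uppercase letter followed by another uppercase letter or a digit
  (`hTERT`, `hIL6`), judged on the *original* casing, so `heat shock` is
  never rewritten;
* the plural rule never produces or consumes an `"ss"` ending and
  re-trims to a fixpoint, so `glass` survives and `mekk1s` → `mekk1`.

`expand_variants()` adds the optional rule families on top: parenthesis
rewriting (`AAA(A)` → `aaa-a` and, through hyphen removal, `aaaa`; plus
the parenthetical dropped), space removal (`IL 2 alpha` → `il2alpha`),
general-word removal (`group`, `residue`, `protein`, `atom`) and
stop-word removal (articles and common prepositions). The closure of
these families forms the lookup key set on both the dictionary side and
the query side. The word inventories ship as editable config seeded with
the published examples only — the original expert lists were never
published, so their exact contents are config, not claims.

`max_match()` is greedy leftmost-longest matching over token n-grams
(default cap 8 tokens), with one matching rule beyond the obvious: a
candidate span may not *begin or end* on a stop-word or general-word
token. Those words are droppable during key expansion, so without the
boundary rule a span like `of the androgen receptor` would match the
`androgen receptor` key and swallow the preposition — which then breaks
downstream token patterns such as `transcription of <Protein>`. The rule
is part of the operation's contract and is mirrored in the brute-force
oracle the tests compare against (every substring enumerated, then
leftmost-longest selection).

Mentions from several recognizers are merged by: longer span wins; ties
broken by a configurable type precedence (protein > chemical > disease >
bioprocess by default); result non-overlapping and sorted. The original
system's overlap policy is unstated, so the precedence is config.

## Grounding

A single index hit grounds exactly. For proteins with several candidates,
each candidate identifier is passed through the homolog map (identifiers
absent from the map stand for themselves); if exactly one human
identifier survives, the mention grounds to it as `homolog_to_human`.
If several survive, the entity stays *unresolved* — there is no published
tie-break, and an arbitrary pick would fabricate curation; unresolved
entities are simply never emitted in statements. Non-protein types use
exact lookup only, since the disambiguation ladder is described for
proteins.

## Function classification

Patterns are token templates mixing literals and typed slots, one per
line of a plain-text resource (`function<TAB>template<TAB>max_gap`).
`max_gap` (default 1) is the number of skippable tokens between
consecutive template elements; the published example *enzymatic
activity* under the `<Protein> activity` pattern requires exactly a gap
of one. Slots consume a whole entity span (all its tokens). An entity
receives at most one wrap, first match in pattern-file order winning;
`complex` patterns bind at least two distinct entities into one group.
`tscript` patterns are config additions (the published pattern table
omits them although the worked transcription example uses the wrap).
The published per-function pattern *counts* (15/15/11/9/11) are not
reproducible because the inventories themselves are unpublished; the
shipped file holds the printed examples plus clearly marked additions.

## Semantic role labeling and assembly

`read_ptb()` ingests one bracketed Penn Treebank tree per sentence and
aligns leaves to character spans by in-order search (bracket escapes
`-LRB-`/`-RRB-` handled). `rule_srl()` then applies two rules:

* **patient (ARG1)**: the first NP or S/SBAR sibling following the verb
  inside its parent phrase. The source description covers only the agent
  side; this is the conventional reading consistent with the worked
  parse figure.
* **agent (ARG0)**: among the left-side children of the verb's nearest
  `S` ancestor *at or above grandparent level*, the nearest (rightmost)
  NP. When that S has no left NP the search climbs to the next S. The
  generalization beyond the literal "grandparent S" handles auxiliaries
  and the deliberately imperfect two-verb fixture tree.

`pas_to_svo()` keeps only structures with both core roles; `ARGM-*`
modifiers are ignored. Relation verbs are recognized as `VB*` leaves
whose suffix-stripped lemma is in the relation-verb lexicon (lemma →
`increases`/`decreases`, mirroring the regulation /
positive-regulation / negative-regulation event-type convention).
Lemmatization is a small suffix table (`-s`, `-es`, `-ed`, `-d`,
`-ing`, doubled-consonant forms) — no external lexical resources.
Externally computed predicate–argument records (JSON Lines) pass through
untouched and suppress the rule for their predicates, which is the seam
where learned labelers would plug in.

`assemble()` maps resolved entities inside the subject phrase × inside
the object phrase to the statement cross product, rendering wraps.
`adjust()` counts adjustment keywords token-wise (case-, hyphen- and
period-insensitively) inside the subject and object phrases and flips
the relation on an *odd* count, setting a provenance flag. The parity
rule is this package's choice for the unspecified multi-keyword case: it
models iterated negation ("inhibition of the loss of X"). The scan scope
is the union of the two argument phrases — the published example's
keyword sits inside the subject phrase, and scanning the whole sentence
would flip on keywords unrelated to either argument.

## Scoring

`score()` compares per sentence, as bags (a sentence may carry several
identical projections; each gold item is consumed at most once):

| level | projection |
|---|---|
| term | `(namespace, identifier)` of every leaf abundance |
| function | `(identifier, wrap)` restricted to wrapped terms |
| relation | `(subject id, relation, object id)` |
| bel | full canonical statement |

with `P = TP/(TP+FP)`, `R = TP/(TP+FN)` (0 on zero denominators) and F1
their harmonic mean. Canonical keys normalize whitespace, quoting and
complex member order, so member permutation never affects equality.
Whether the original evaluation matched sets or bags is unstated; bags
are chosen because duplicate-statement sentences exist in corpus data,
and the choice is documented here rather than hidden. A consequence of
the projection definitions, used as a property test: term-level TP can
never be below statement-level TP.

`recover_gold_spans()` re-derives mention boundaries from gold
identifiers (the corpus format does not provide offsets): synonym search
first, then — for numeric gene identifiers only — the recognized mention
whose candidate identifier is numerically nearest.

## Fixtures and the synthetic world

`worked_examples()` packages eight sentences with hand-authored parse
trees. Two of the sentence texts are reconstructions: the transcription
example is quoted in the source only as a fragment, and the two-verb
example only through its caption and the phrase "IL-5 or GM-CSF"; both
are built around the quoted material and marked as reconstructions. The
two-verb tree intentionally hangs the second clause off the first verb
phrase, emulating an imperfect parse, so the agent-recovery climb is
actually exercised. The homolog-disambiguation entries (EGID
16176 → 3553 under a shared key) are a synthetic stand-in pair, not
redistributed vocabulary. Five sentences carry gold that the rules
cannot reach (passive voice, keyword-free `act`, temporal and locative
arguments) — a green worked-example test therefore establishes exact
recovery on the two acceptance sentences and correct FN accounting on
the rest, nothing more.

`generate_synthetic(n, seed)` states a small world: sentences of the
form `[Inhibition of] <A> <verb-ed> <B> [and <C>].` over an opaque
generated dictionary (`HGNC:SYN0001`, surfaces `SYNPR<i>A`), with
defaults chosen once — 30 dictionary entries, trigger probability 0.3,
second-object probability 0.3, noise fraction 0. Gold is computed from
the template semantics, including the parity-correct flip for the
trigger. Unknown-verb noise sentences keep their gold (defined as
`increases` by the template), so they depress recall exactly by their
gold share while precision stays 1 — asserted as an equality, not a
tolerance. What this world does *not* emulate: real parse errors,
nested clauses, anaphora, discontinuous mentions, ambiguous surface
forms; end-to-end F1 = 1 on it validates the plumbing, not corpus-level
performance.

## Numerical and degenerate-input choices

* All offsets are 0-based half-open character spans; `text` always
  equals the sentence slice, enforced by construction and tests.
* Zero-denominator precision/recall/F1 are 0 (so a bundle without
  function wraps scores 0/0/0 at the function level — degenerate, not
  perfect).
* Statement output order is deterministic: sentence order, then
  canonical statement order; duplicates removed on the canonical key.
* The generator saves and restores the caller's RNG state.
* Unparseable gold/prediction lines abort scoring with the offending
  line numbers; per-sentence extraction failures in the CLI are logged
  and skipped without aborting the run.

## Known limitations

Passive voice is not handled (no `by`-phrase demotion rule), which the
packaged L-plastin sentence demonstrates. Only general-category `act`
patterns ship — subcategory activities (kinase, catalytic, transport)
are out of scope. The other two relation types of the original four are
not representable because their names and directionality are not
published; the parser fails loudly on them. Cross-sentence statements,
coreference and statement-level annotations (citations, evidence) are
out of scope.
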