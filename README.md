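# belpipe

Rule-based extraction of **Biological Expression Language (BEL)**
statements from single biomedical sentences, in R.

BEL encodes causal relations among biological entities in one-line
statements such as

```
p(HGNC:MAP3K1) increases tscript(p(HGNC:AR))
```

— the protein MAP3K1 (an *abundance*, head `p`) positively influences the
transcription (*function wrap* `tscript`) of the androgen receptor. Curating
such statements from the literature by hand is slow; `belpipe` implements a
classic rule pipeline that proposes them automatically from a sentence and
its constituency parse, and scores the proposals against gold curation.

## Who this is for

Text-mining researchers and biocurators who need an offline, fully
inspectable baseline for sentence-level BEL extraction: every stage is a
deterministic rule component with plug-in seams where statistical models
(CRF taggers, learned semantic role labelers) would slot in.

## The pipeline

1. **Entity recognition** — greedy leftmost-longest *maximum matching* of
   token n-grams against per-type dictionaries (protein / chemical /
   biological process / disease), after heuristic surface normalization
   (lowercasing; hyphen/period removal; `human`/`h` prefix and plural `s`
   stripping; parenthesis, space-removal, general-word and stop-word
   variants). External NER output can be merged in through a JSON Lines
   plug-in seam.
2. **Entity normalization (grounding)** — mentions are bound to namespace
   identifiers (`HGNC`, `EGID`, `CHEBI`, `GOBP`, `MESHD`). Ambiguous
   protein hits are collapsed through an Entrez-style homolog-to-human map;
   what remains ambiguous stays unresolved and is never emitted.
3. **Function classification** — token patterns with typed slots
   (`<Protein> activity`, `phosphorylation of <Protein>`,
   `<Protein>/<Protein> complex`, …) assign molecular-function wraps
   (`act`, `tscript`, `complex`, `deg`, `pmod`, `tloc`).
4. **Relation classification** — a rule-based semantic role labeler walks
   the Penn Treebank parse: the patient (ARG1) is the first NP/S after the
   verb inside its verb phrase; the agent (ARG0) is the nearest NP among
   the left children of the verb's nearest S ancestor at or above
   grandparent level. PAS → SVO → relation (`increases`/`decreases`, from
   a regulation-verb lexicon), then a polarity adjustment flips the
   relation when an odd number of context keywords (`inhibition`,
   `mutant`, `inactivation`, …) occurs in the subject/object phrases.
5. **Evaluation** — per-sentence bag matching of predicted vs gold
   statements at four levels (term, function, relation, full statement)
   with precision / recall / F1:
   `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`.

## Worked example

```r
library(belpipe)

b <- worked_examples()          # packaged sentences, parses, dictionaries
run_pipeline(b)[, c("sentence_id", "statement", "adjusted")]
```

prints (abridged):

```
  sentence_id                                      statement adjusted
1        fig1   p(HGNC:MAP3K1) increases tscript(p(HGNC:AR))    FALSE
2        fig2           p(HGNC:PTGS2) increases p(HGNC:IL1B)     TRUE
3        fig2            p(HGNC:PTGS2) increases p(HGNC:IL6)     TRUE
4        fig4 a(CHEBI:dexamethasone) decreases p(HGNC:CCL11)    FALSE
5        fig4           p(HGNC:CSF2) increases p(HGNC:CCL11)    FALSE
6        fig4            p(HGNC:IL5) increases p(HGNC:CCL11)    FALSE
```

Row 1 is the transcription example above. Rows 2–3 come from *"Inhibition
of COX2 markedly reduced both IL-1 beta and IL-6 release."*: the verb
*reduced* proposes `decreases`, but the keyword *Inhibition* inside the
subject phrase flips the polarity — hence `increases` with the `adjusted`
provenance flag set. Scoring against the bundled gold:

```r
pred <- run_pipeline(b)
score(b$gold, pred[, c("sentence_id", "statement")], "bel")
#> bel-level: TP=6 FP=0 FN=6  P=1.0000 R=0.5000 F1=0.6667
```

The six missed gold statements belong to sentences the source rules cannot
reach (passive voice, keyword-free functions, temporal/location
arguments) — they are packaged deliberately to exercise the scorer.

A synthetic corpus with known gold structure is available for controlled
experiments:

```r
syn <- generate_synthetic(200, seed = 1)
score(syn$gold, run_pipeline(syn)[, c("sentence_id","statement")], "bel")
#> bel-level: TP=270 FP=0 FN=0  P=1.0000 R=1.0000 F1=1.0000
```

## Command line

```sh
inst/cli/belpipe fixtures --worked-examples --out bundle/
inst/cli/belpipe extract --sentences bundle/sentences.jsonl \
    --trees bundle/trees.ptb --config bundle/pipeline.dcf --out pred.bel
inst/cli/belpipe evaluate --gold bundle/gold.bel --pred pred.bel --level all
```

## Scope and limitations

Only the two causal predicates `increases`/`decreases` are modeled; the
parser rejects anything else explicitly. Statistical NER and SRL components
are represented by plug-in seams (JSON Lines records), not re-trained.
See `vignettes/belpipe-methods.Rmd` for the full account of the rules,
their parameters and the known failure modes.
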