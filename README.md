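# tokenlattice

Tokenization of biomedical text with the **token lattice** design
pattern: deterministic token transducers propose every defensible
reading of each span, a bounded directed acyclic lattice stores them
compactly, and an adapted Viterbi decoder over a part-of-speech hidden
Markov model selects the single most probable tagged token sequence.

## Why a lattice?

Clinical and biomedical strings are ambiguous at the token level, and
the right answer depends on context a left-to-right rule pipeline has
not seen yet:

| Input | Correct tokens | Trap |
|---|---|---|
| `50mg` | `50`, `mg` | fused quantity and unit |
| `patient's` | `patient`, `'s` | possessive clitic |
| `mg/ml` | `mg`, `per`, `ml` | slash means *per* between units |
| `organ/system` | `organ`, `and`, `system` | same slash, different expansion |
| `C1-4` | `C1`, `to`, `4` | elided *to* in a range |
| `Precorrin-3B` | `Precorrin-3B` | must **not** split |

Instead of forcing each rule to commit, every applicable reading enters
the lattice and a POS-tag HMM arbitrates: segmentation and tagging are
decided jointly, so the tag context (for example, *unit → preposition
is likely; unit → conjunction is not*) pays for the right split.

## Worked example

Build the lattice for a description with three independent ambiguity
sites and enumerate its candidate segmentations:

```r
library(tokenlattice)

lat <- build_lattice(text_unit("The patient's 10mg tablet."),
                     default_transducers())
lat
#> <token_lattice unit=u1 chars=26 vertices=11 edges=13>

enumerate_token_sequences(lat)
```

Eight distinct candidates (2 × 2 × 2: possessive split × dose split ×
final period):

```
The | patient's | 10mg | tablet.
The | patient's | 10mg | tablet | .
The | patient's | 10 | mg | tablet.
The | patient's | 10 | mg | tablet | .
The | patient | 's | 10mg | tablet.
The | patient | 's | 10mg | tablet | .
The | patient | 's | 10 | mg | tablet.
The | patient | 's | 10 | mg | tablet | .
```

Train an order-1 model on the bundled synthetic clinical corpus and
decode:

```r
corpus <- generate_tagged_corpus(fixture_spec(seed = 42))$sentences
model  <- hmm_train(corpus, order = 1)
model
#> <hmm_model order=1 alpha=0.1 tags=10 vocab=81 tokens=10808 sentences=1200>

tokenize_unit("Primary Sjogren's syndrome with organ/system involvement (disorder)",
              default_transducers(), model)
#> <tagged_tokens> logprob -41.3315
#> Primary/JJ Sjogren/NNP 's/POS syndrome/NN with/IN organ/NN and/CC system/NN involvement/NN (/PUNCT disorder/NN )/PUNCT

tokenize_unit("Warfarin 5 mg/ml solution", default_transducers(), model)
#> <tagged_tokens> logprob -21.5790
#> Warfarin/NNP 5/CD mg/NNU per/IN ml/NNU solution/NN
```

Note the same `/` expanded two different ways — *and* between nouns,
*per* between units — chosen by the tag transitions, not by a rule.

Evaluation statistics follow the reporting conventions of segmentation
studies (all-or-nothing unit agreement, coin-toss chance level for
kappa, normal-approximation binomial intervals):

```r
cohens_kappa(0.944)
#> [1] 0.888
round(100 * binomial_ci(0.539, 2781), 1)
#>  low high
#> 52.0 55.8
```

## Command-line interface

An `Rscript` entry point is installed at `exec/tokenlattice` inside the
installed package and drives the full pipeline:

```sh
tokenlattice fixtures --out-dir study --seed 42        # synthetic study data
tokenlattice train    --corpus study/corpus.tagged --out study/model.json
tokenlattice tokenize --input study/units.txt --model study/model.json --tagged
tokenlattice evaluate --pred pred.tsv --gold study/gold.tsv --kappa
tokenlattice lattice  --text "The patient's 10mg tablet." --sequences
```

Data goes to files or standard output; log messages go to standard
error. Run configuration (enabled transducer classes, transform tables,
HMM order, smoothing, normalization, seed) round-trips through YAML;
models persist as versioned JSON.

## Package layout

- `R/transducers.R` — token classes and transform tables
- `R/lattice.R` — lattice construction, enumeration, DOT export
- `R/hmm.R` — HMM training, smoothing, scoring, JSON persistence
- `R/decoder.R` — adapted Viterbi and the brute-force oracle
- `R/evaluation.R` — accuracy, intervals, kappa, reports
- `R/fixtures.R` — ground-truth chains, corpus sampler, evaluation sets
- `R/io.R`, `R/cli.R` — file formats, YAML config, CLI subcommands
- `vignettes/token-lattice-tokenization.Rmd` — model and methods notes
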