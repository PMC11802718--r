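# sudspanr

Zero-shot extraction of substance use disorder (SUD) severity specifiers
from unstructured clinical notes.

## What it does, and for whom

DSM-5 SUD diagnoses carry severity specifiers — mild / moderate / severe and
remission status — that clinicians record as free text ("severe etoh use
d/o", "mj ud", "cannabis use disorder, in remission") rather than as
structured codes. `sudspanr` is for clinical-NLP practitioners who want to
recover these spans across 11 SUD categories (alcohol, opioids, cannabis,
sedatives/hypnotics/anxiolytics, cocaine, amphetamines, caffeine,
hallucinogens, nicotine, inhalants, other psychoactive substances) with an
instruction-prompted text-generation model and to evaluate the result
rigorously.

The workflow:

1. **Prompting** — one instruction prompt per category, ending in an
   escape clause ("... please respond \"unanswerable\""); only the category
   noun phrase changes between categories.
2. **Chunking** — notes longer than the model's input budget are split by a
   sliding window with a document stride: window `w = L_max − |prompt|`
   (462 tokens for a 50-token prompt at `L_max = 512`), stride 128, so
   consecutive chunks overlap by `w − 128` tokens and every plausible span
   appears intact in some chunk.
3. **Generation** — a pluggable backend under greedy decoding (temperature
   1, ≤ 100 new tokens). Deterministic oracle / noisy / hallucinating mock
   backends make the whole pipeline testable without a deployed model.
4. **Post-processing** — per (note, category) the per-chunk candidates are
   reduced to one answer by a four-stage cascade: (i) must contain a
   category substance term; (ii) a use-disorder phrase must follow it;
   (iii) the candidate's note-grounded material (maximal common substrings
   of ≥ 5 characters with the note) must itself pass (i)–(ii) — the
   hallucination check; (iv) among multiple distinct survivors, the one at
   minimum Euclidean distance from the category's proxy phrase ("alcohol
   use disorder/dependence") in embedding space wins.
5. **Scoring** — relaxed token-multiset precision / recall / F1
   (P = TP/(TP+FP), R = TP/(TP+FN) over shared tokens) and binary strict
   exact-match F1, macro-averaged over notes per category, plus a
   five-scenario error breakdown and a candidate-count / note-length
   Pearson analysis. A lexicon-driven regex baseline provides the
   rule-based comparison.

Because the clinical corpus such pipelines run on cannot be shared, the
package includes a seeded synthetic note generator emulating its documented
structure (11–10719 tokens per note, median 423; per-category prevalence
3–33%, mean 10%; comorbid multi-SUD statements; checkbox, abbreviated and
remission phrasings; problem-list and rule-out distractors), so every stage
is exercised end to end with known ground truth.

## Worked example

```r
library(sudspanr)

lex  <- load_lexicons()                                  # 11 category lexicons
corp <- generate_corpus(corpus_spec(n_notes = 60, seed = 7), lex)

# a backend that returns the gold span when it sees it, wrapped in noise
# words -- the classic generative error mode (right span, extra words)
res <- run_pipeline(corp$notes, backend_noisy(corp$gold),
                    gold = corp$gold, lexicons = lex)

res$answers[!is_unanswerable(res$answers$text), ][1:2, c("category", "text")]
#>   category text
#> 1 alcohol  response: alcohol use disorder, severity unspecified (see chart review)
#> 2 alcohol  response: moderate alcohol use disorder (see chart review)

res$scores[1:3, c("category", "n_pos", "f1_strict_pos", "f1_relaxed_pos",
                  "recall_relaxed_pos", "f1_strict_combined")]
#>   category n_pos f1_strict_pos f1_relaxed_pos recall_relaxed_pos f1_strict_combined
#> 1 alcohol     24             0          0.628                  1              0.6
#> 2 opioid      10             0          0.653                  1              0.833
#> 3 cannabis     5             0          0.605                  1              0.917
```

Reading the numbers: every positive note's answer fully contains the gold
span (`recall_relaxed_pos = 1`) but none matches it exactly
(`f1_strict_pos = 0`) because of the injected noise words; negative notes
are all correctly rejected, so the combined strict score is the positive
fraction away from 1. Swapping in `backend_oracle(corp$gold)` yields
`f1_strict_combined = 1` in every category — the pipeline recovers every
gold span exactly; `extract_regex()` gives the rule-based baseline for the
same notes.

A thin command-line wrapper with `synth`, `extract`, `regex-extract`,
`evaluate` and `run-all` subcommands is installed at
`system.file("cli", "sudspanr", package = "sudspanr")`.

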