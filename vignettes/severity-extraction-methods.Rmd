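---
title: "Methods: zero-shot extraction of SUD severity specifiers"
author: "sudspanr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: zero-shot extraction of SUD severity specifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sudspanr)
```

## The problem

DSM-5 substance use disorder (SUD) diagnoses carry severity specifiers —
mild, moderate, severe, remission status — that structured billing codes
(ICD-10) cannot represent. Clinicians record them as free text: "severe etoh
use d/o", "mj ud", "cannabis use disorder, in remission", or checkbox blocks
such as "cocaine [] mild (2-3); [] moderate (4-5); [x] severe (6 or more)".
`sudspanr` implements a zero-shot workflow for recovering these severity
spans from unstructured notes across 11 SUD categories (alcohol; opioids;
cannabis; sedatives, hypnotics/anxiolytics; cocaine; amphetamines; caffeine;
hallucinogens; nicotine; inhalants; other psychoactive substances): an
instruction prompt per category, sliding-window chunking of long notes, a
pluggable text-generation backend, a four-stage post-processing cascade, a
rule-based regular-expression baseline, and a strict/relaxed span evaluation
harness — exercised end to end on a seeded synthetic corpus.

## Prompting and chunking

Each category uses one prompt ("Extract the reference to {category} use
disorder diagnosis with surrounding information relevant to it from the
diagnoses section in the following note. If you can't find the answer,
please respond \"unanswerable\". Note: {note}"); only the category noun
phrase changes between categories. Because free-text notes have no reliable
section structure, no section pre-extraction is attempted: the whole note is
presented to the model.

Notes routinely exceed the 512-token input budget of the targeted
encoder-decoder models. `plan_window()` reserves the prompt's own token count
(a 50-token prompt leaves a 462-token window) and `make_chunks()` slides that
window over the note with a document stride of 128 tokens. The stride is the
*advance* between consecutive window start offsets (`start += stride`),
following the reading-comprehension sliding-window convention from which the
technique derives; the alternative "stride = overlap" reading was considered
and rejected. Consecutive chunks then share `462 - 128 = 334` tokens, so any
span of up to 335 tokens appears intact in at least one chunk — far above
realistic diagnosis-span lengths. A final chunk shorter than the window is
kept, not dropped. Chunk boundaries are token-aligned and chunk text is
produced by detokenization; the shipped whitespace tokenizer guarantees that
every single-space-separated phrase survives detokenization, which is the
property the downstream string filters rely on. A real backend may supply
its own subword tokenizer through the same contract.

## Generation backends

Decoding is greedy with temperature 1 and at most 100 new tokens, so a
backend is a deterministic function of its input and candidate files are
byte-reproducible. The 11-billion-parameter instruction-tuned models used in
production are not desk-scale, so the package ships three deterministic
mocks behind the backend contract: an *oracle* (returns the note's gold span
when it appears verbatim in the chunk, else the sentinel), a *noisy* mock
(oracle answers wrapped in fixed extra words, reproducing the dominant
recall-1/strict-0 error mode of generative extractors), and a
*hallucinating* mock (replaces a deterministic pseudo-random subset of
answers with a span for a different substance). Every downstream stage is
thereby testable with known ground truth; a real seq2seq model plugs in via
`new_backend()`.

## Post-processing cascade

Per (note, category), the per-chunk candidates are reduced to one final
answer:

1. drop candidates lacking any category substance term;
2. drop candidates in which no use-disorder phrase ("use disorder",
   "dependence", "use d/o", "ud", ...) occurs **after** the first substance
   term — "following the substance names" is implemented as character
   position ordering, the simplest testable contract;
3. drop candidates whose note-grounded material fails 1-2. The grounded
   material is the union of maximal common substrings of at least `min_len =
   5` characters between the lowercased candidate and note, computed exactly
   by dynamic programming in C++. The length-5 floor comes from the shortest
   real-world use-disorder reference, "mj ud". The stricter literal reading
   — reject if *any* common substring fails the filters — would reject
   nearly every candidate (most 5-character substrings contain no lexicon
   term), so the implemented semantics is "at least one grounded substring
   exists, and the grounded material as a whole passes the lexicon filters";
   `min_len` is exposed as configuration;
4. if more than one *distinct* candidate survives (duplicates from
   overlapping chunks are deduplicated by exact string match first), the
   survivor closest to the category's proxy ground truth (e.g. "alcohol use
   disorder/dependence") in embedding space is selected. Minimum Euclidean
   distance is the default — equivalent to the highest negative-distance
   similarity score — with cosine distance behind a switch; ties break to
   the lowest chunk index. A proxy written with "/" alternatives is expanded
   token-wise ("use disorder/dependence" scores as "use disorder" or "use
   dependence", whichever is closer).

Filtered-out answers are replaced by the sentinel. All matching is plain
substring matching on lowercased, whitespace-collapsed text: word-boundary
matching would break abbreviations such as "use do" and "d/o".

The shipped embedder is a deterministic signed feature-hashing bag of words
plus character trigrams (dimension 256). Counts are deliberately left
unnormalized so Euclidean distance remains sensitive to answer length — the
very property that makes it better than cosine similarity at separating a
concise answer from a verbose multi-diagnosis answer. The embedder is
pluggable; any `embed(text) -> vector` implementation (e.g. a transformer
encoder with mean pooling) satisfies the contract.

## Regex baseline

`build_patterns()` assembles per-category rules from the same lexicon:
optional leading severity and/or parenthetical, the substance name, a
bounded filler gap (at most 40 characters, enough for parentheticals like
"(heroin/ vicodin)" without runaway spans), a use-disorder phrase, and an
optional severity/remission tail; a third pattern covers checkbox and
generic-first forms. Multiple hits are reduced leftmost-first then longest —
standard regex semantics, deterministic. Every non-sentinel answer is by
construction a verbatim substring of the note; the structural limitation is
that rules see no context, so a "r/o alcohol use disorder" rule-out mention
is (deliberately, testably) matched as if it were a diagnosis.

## Evaluation

Relaxed scoring is token-multiset overlap: true positives are tokens shared
between gold span and answer, false negatives gold-only, false positives
answer-only; precision, recall and F1 follow. Tokens are lowercased
whitespace tokens with punctuation isolated — except "/", preserved inside
tokens so "d/o" stays whole. Word-level tokens (not model wordpieces) keep
the metrics backend-independent; multiset (not set) counting makes repeated
words in verbose generations cost precision. Both choices are configuration
points. Conventions: gold and answer both empty scores (1, 1, 1) — no gold
tokens and no false positives is a correct rejection; only the answer empty
scores (1, 0, 0); only the gold empty (0, 1, 0); F1 is 0 when P + R = 0.

Strict scoring is binary exact match on normalized text (casefold plus
whitespace collapse — raw character-by-character equality would be fragile
to incidental spacing). An exact match scores 1; an answer that merely
contains the gold span scores 0; on a note with no gold span the sentinel
scores 1 and any other answer 0. Positive-note records are further labelled
with one of five scenarios, evaluated in order: strict match; recall = 1
(answer contains the span); precision = 1 (span contains the answer); no
overlap; other.

Macro averages are arithmetic means over notes within a category, reported
separately for positive notes, negative notes, and all notes combined (the
combined value is the mean over all notes, not the mean of the two subgroup
means). The candidate-count analysis reports, per category, the fraction of
notes with more than one surviving candidate and the Pearson correlation
between note token length and candidate count, with two-sided significance
stars at 0.05/0.01/0.001 (`stats::cor.test`; the tests cross-check the
estimate against the direct covariance formula).

## Synthetic corpus

The generator emulates the documented statistics of the study corpus it
stands in for: 577 notes over 574 patients with a 57-note development split
by patient; per-category positive prevalence from 3% (caffeine,
hallucinogens, inhalants) to 33% (alcohol) with mean 10%, ordered to
reflect relative SUD frequency in a veteran clinical population; note
lengths log-normal with median 423 tokens, clamped to 11-10719, with
`meanlog = log(423)` and `sdlog = sqrt(2 log(1043/423))` so the mean matches
1043 tokens. Notes are free text with no fixed section order: header, filler
sections, optional distractors, and a diagnoses block holding the gold spans
verbatim.

Per-category positivity is sampled as *independent* Bernoulli draws at the
stated prevalences, which keeps every per-category positive count exactly
binomial — the property the generator-fidelity tests measure. The
documented 24.4% multi-SUD comorbidity rate is a patient-level statistic
that cannot be imposed jointly with those 11 marginals without contradicting
them; it is therefore used where it affects the extraction task: with
probability 0.244 a multi-positive note writes its spans adjacent in a
single semicolon-joined statement (the hardest case for per-category
extraction), otherwise on separate lines.

The diagnosis grammar covers plain, abbreviated, checkbox, remission,
parenthetical, slash-combined and unspecified-severity styles, and can emit
all 13 documented real-world variant strings. Two of those variants
("marijuana user (in remission)" and the checkbox form that names the
substance only after "substance use disorder") fail the pipeline's own
filters (i)-(ii); they remain renderable as realistic surface forms, but
gold spans are rejection-sampled until they pass the filters, so the
oracle-backend test is well-posed: every gold span is recoverable by a
correct pipeline. Distractor blocks — historical problem lists ("previous
encounters problem list includes: {x} cannabis abuse"), rule-out lines,
negated use — always name categories that are *not* positive for the note,
and filler sentences are verified to contain no substance term. Distractor
rates (0.15 past-problem, 0.10 rule-out, 0.15 negated per note) are chosen
as plausible frequencies for their note types.

What the generator does **not** emulate: real clinical language diversity
(typos, neologisms, idiosyncratic formatting), genuinely ambiguous mentions
("stimulant" that a clinician meant as cocaine), PHI-like structure, and —
most importantly — the behavior of a real language model. Passing tests
therefore demonstrate that the *pipeline machinery* (chunking, filtering,
selection, scoring) is correct under controlled backends, not that any
particular model achieves any particular accuracy on real notes.

## Numerical and design choices

- Bare "stimulant" is assigned to the amphetamine lexicon (DSM-5 groups
  amphetamine-type substances under stimulant use disorder); the lexicon
  config is user-replaceable if a deployment prefers otherwise.
- The sentinel check is case-insensitive substring containment
  ("unanswerable" anywhere in the output), since generated casing and
  framing are uncontrolled.
- All tie-breaks are deterministic (lowest chunk index); two runs with the
  same backend, configuration and corpus produce byte-identical outputs.
- Degenerate inputs: an empty note yields zero candidates and a warning; a
  backend error on a chunk is downgraded to a per-chunk sentinel; an
  embedder failure falls back to the lowest-chunk-index survivor with a
  warning; a zero-variance candidate-count column reports the Pearson
  correlation as missing.
- Test problem sizes: the end-to-end suites run the full pipeline at study
  scale (577 notes, all 11 categories) for the oracle, noisy and
  hallucinating backends, 1000-note corpora for distributional checks on the
  generator, and 1000 random token-multiset pairs against a brute-force
  metric oracle.

## Limitations

The lexicons and regex rules are reconstructions from documented examples,
not the original (unpublished) term files; the proxy-selection embedder is a
lexical hashing embedder, so it ranks by surface similarity rather than
semantics — adequate for separating on-category from off-category survivors,
weaker for paraphrases; and no negation or assertion detection is performed
(negated mentions are excluded at the gold-annotation level, mirroring the
annotation rules of the emulated study design).
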