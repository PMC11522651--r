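---
title: "Methods: generative content development and QC for SMS health messaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: generative content development and QC for SMS health messaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bctmsg)
```

## The pipeline and its assumptions

`bctmsg` automates the content step of a brief-message intervention:
turning a theory-grounded catalogue of behavior change techniques (BCTs)
into a bank of candidate SMS messages, and then measuring whether that bank
meets the delivery and readability constraints of the SMS medium. The
package deliberately stops at candidate content: expert review, safety
checking and user testing of messages are human stages outside its scope.

The generation model is a *single-prompt, two-role chat completion* per
technique: a system prompt establishes the conversation (who the assistant
is, style rules, how to treat the technique, and the task of writing 25
diverse messages), and a user prompt carries the technique's database
fields. No conversation history accumulates between techniques, so each
technique's output depends only on its own prompt pair. The assumption
behind attributed prompting is that a fixed template plus per-technique
attribute substitution gives uniform style while the substituted technique
drives the behavioral content.

## The BCT database

Six fields per technique: `number`, `label`, `definition` (required),
`examples`, `theoretical_constructs`, `behavioral_strategies` (optional).
Optional fields are *absent*, never empty strings: absence controls whether
the corresponding prompt section is rendered at all. CSV storage is
RFC 4180 / UTF-8 because definitions freely contain commas and quotes.

The packaged 46-technique table is a **synthetic reconstruction**: numbers,
labels and definitions follow the v1 taxonomy wording, while the
construct/strategy mappings are illustrative stand-ins for evidence-review
mappings. It is ordered so the first techniques are 1.2, 1.4, 2.3, 2.4,
2.7, matching the published example listing. Users with a curated table
drop it in through `load_bct_database()` unchanged.

## Prompt rendering

Templates are plain-text resource files (not string literals) so their
wording can be inspected and diffed. Rendering is pure token substitution:
attribute text is never truncated or re-wrapped. Conditional sections are
resolved at line granularity: a template line referencing an optional
attribute the entry lacks is dropped, and a blank separator line is kept
only if the section below it survives — this yields the documented
formatting ("For example, " on its own line; a two-line-break separator
before "Theoretical Constructs: "; "Behavioral Strategies: " on a new
line). The published prompt text is only available flattened (without its
original paragraph breaks); the packaged transcription restores breaks at
the four component boundaries (setting / style rules / BCT rules / task),
which is the natural reading of that structure. `{bct_label}` substitutes
the Label field alone — the templates never reference the taxonomy number —
and an alternate template can concatenate number and label if desired.

## Generation and post-processing

`temperature` defaults to 0 (most deterministic provider behavior) and
`messages_per_bct` to 25. Assistant text is normalized by splitting on line
breaks, collapsing blanks, stripping surrounding straight/curly quotes, and
(on by default, flag-controlled) stripping leading list numbering — real
chat models frequently number lists even when asked not to. Off-count
responses are kept with a logged warning rather than re-queried: the actual
per-technique counts are recorded in provenance, and downstream statistics
use actual counts. A technique whose backend call fails after 3
exponential-backoff attempts is recorded as a per-technique failure and the
run continues.

The packaged mock backend is a pure function of (prompt, index, seed) built
on a package-local Lehmer (Park–Miller, modulus 2^31 − 1) generator keyed
by a string hash, so it never touches R's global RNG state and the whole
offline pipeline is byte-reproducible. Token usage is reported as a
deterministic word-count proxy so metering plumbing can be exercised
offline.

## Quality control

**Length / deliverability.** Character count is Unicode code points after
NFC normalization (avoiding composed/decomposed ambiguity), spaces
included. The pass rule is `char_count <= 160` *and* GSM-7 encodability;
the septet count (basic table = 1, extension table = 2, from transcribed
GSM 03.38 tables) is surfaced alongside because septets, not characters,
determine true single-SMS delivery.

**Readability.** Flesch-Kincaid grade with sentence splits on runs of
`.!?` and whitespace word tokens (punctuation stripped, case folded).
Syllables come from a deterministic heuristic: maximal `aeiouy` vowel
groups, minus a silent terminal "e" unless it follows "l" (so "make" → 1,
"table" → 2), minimum 1. The heuristic merges adjacent vowels ("diabetes" →
3), a known bias of group-counting; a hyphenation-dictionary backend can be
slotted behind the same contract, but the packaged heuristic is the default
for cross-environment determinism. The adjustment removes ignore words from
*both* the word and syllable tallies (sentence counts unchanged): of the
defensible variants, removing from both is the one consistent with "the
word does not pose a complexity barrier". The default ignore list includes
the plural `medications` alongside `medication`, since tokenization treats
them as distinct tokens and the audience knows both. The pass threshold is
an adjusted grade ≤ 8.0 (the common maximum recommended reading level for
general adult audiences); both the threshold and the list are arguments.
Published bank-level reference statistics (1034/1150 within length, mean
119 characters; 688 raw / 928 adjusted readability passes, mean grades
8.4 / 6.5) are checked by the acceptance suite *when the externally
published message file is supplied*; it is third-party supplementary
content and is not redistributed in this package.

## Diversity analysis

Embeddings are pluggable; the mock backend hashes each text to a seeded
Gaussian vector (optionally unit-normalized, mimicking encoders that return
points on the unit sphere). Mock embeddings preserve *identity* structure —
identical texts embed identically, distinct texts are near-orthogonal in
high dimension — but carry no semantics; passing diversity tests with mocks
therefore validates the arithmetic of the analysis, not semantic claims
about real messages.

The cross-dataset comparison proceeds: multilabel expansion (a message
coded for m techniques becomes m single-coded copies) → distribution
matching (restrict to shared techniques; keep `min(count_A, count_B)`
messages per technique — `first_n` in stored order by default for
reproducibility, a seeded `random` mode for sensitivity checks) → centering
(each data set by *its own* mean, which removes that data set's shared
objective signal) → per-technique mean inner products (the relevance
matrix) → top-k alignment accuracy. Ranking ties break by ascending
taxonomy number, purely for determinism.

Projections: PCA via singular value decomposition with a deterministic sign
convention (each axis oriented so its largest-magnitude loading is
positive); t-SNE via `Rtsne` under a locally-set seed, with the caveat that
t-SNE coordinates are reproducible per environment/library version, which
is why run metadata records the configuration. PCA can be applied per data
set or to the pooled centered representations; `cmd_compare()` writes the
pooled projection.

## Synthetic banks

The generator emulates the *statistical shape* of a generated bank:
per-technique counts, a truncated-normal character-length distribution
(defaults: mean 119, sd 28, range 40–220 — centered on the reference
bank's reported mean length), a target grade band (default 5–9, tuned by
mixing mono- and polysyllabic pool words through the closed-form grade
equation), an exact `ceiling(frac * n)` count of non-GSM-7 messages
(stride-selected rows get a pill emoji), and an exact multilabel count for
comparison banks. Texts are grammatical filler from a packaged phrase pool;
they are *not* linguistically realistic messages, and distributional
realism (topic drift, model idiosyncrasies, failure modes beyond off-count
responses) is out of scope. Each technique draws from its own seeded
substream, so extending a bank with new techniques never perturbs existing
ones.

## Numerical and scale choices

Degenerate inputs are defined, not special-cased: a single embedding
centers to the zero vector; rank-deficient PCA pads a zero second axis; an
empty database renders an empty prompt batch; a grade is undefined (and
excluded from means, counted separately) when exclusion leaves no words.
Test problem sizes are chosen for sub-minute suites: full-scale structure
checks run at the study size (46 × 25 = 1150 messages), statistical
distribution checks at n = 1000 with 3-standard-error tolerances,
oracle-agreement checks at 10⁴ random GSM-7 strings, and t-SNE checks at
n = 80, perplexity 10.

## Known limitations

- The syllable heuristic under-counts adjacent-vowel hiatus ("diabetes")
  and silent-e edge cases ("whale"); grade means shift accordingly
  relative to dictionary-based counters.
- The 46-technique table is a synthetic reconstruction, not the curated
  evidence-review table; users reproducing published numbers must supply
  the original table and message bank.
- Reference top-5/top-10 alignment accuracies from the published
  comparison (67% / 87%) depend on a proprietary embedding endpoint and an
  external comparison data set; offline, the package verifies the
  surrounding machinery by construction (self-alignment, oracles,
  monotonicity) instead.
- The mock chat backend writes template-like filler; it exercises contracts
  and reproducibility, not content quality.
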