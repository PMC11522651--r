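# bctmsg

Content development and quality control for brief-message (SMS) health
interventions built on behavior change techniques (BCTs).

Brief text-message programs are one of the most scalable ways to support
health behaviors such as medication adherence in type 2 diabetes, but their
message banks are usually written by hand, slowly, and behind closed doors.
`bctmsg` implements an end-to-end, reproducible alternative for the content
step of that pipeline:

1. **BCT database** — a structured six-field table (number, label,
   definition, examples, theoretical constructs, behavioral strategies) of
   the techniques selected for the intervention setting. A synthetic
   46-technique reconstruction is packaged
   (`inst/extdata/bct_database_synthetic.csv`).
2. **Attributed prompting** — system and user prompt templates with named
   attribute slots (`{bct_label}`, `{bct_definition}`, ...) filled per
   technique from the database; sections for optional attributes are
   included only when available.
3. **Generation** — one two-role chat-completion call per technique against
   a pluggable backend (a deterministic offline mock is packaged), with
   post-processing of the assistant text into discrete, tagged messages
   (quote/numbering stripping, blank-line collapsing).
4. **Quality control** — per-message SMS deliverability (character count;
   GSM 03.38 septet cost, where basic-table characters cost 1 septet and
   extension-table characters 2; a single SMS carries 160) and readability
   via the Flesch-Kincaid grade level

   `FK = 0.39 (words / sentences) + 11.8 (syllables / words) − 15.59`

   with an ignore-word adjustment that removes unavoidable domain words
   (default `medication`, `medications`) from the word and syllable tallies.
5. **Diversity analysis** — message embeddings through pluggable backends
   (deterministic mock packaged), PCA and seeded t-SNE projections, and a
   cross-dataset comparison: multilabel expansion, per-technique
   distribution matching, centered representations
   `r(x) = emb(x) − (1/|X|) Σ_{x′∈X} emb(x′)`,
   the BCT relevance matrix
   `rel(b₁, b₂) = ⟨ mean_{x∈X₁(b₁)} r(x), mean_{x∈X₂(b₂)} r(x) ⟩`,
   and top-k alignment accuracy over its rows.

## Worked example

```r
library(bctmsg)

db   <- bct_database_fixture()                       # 46 techniques
bank <- generate_bank(db, mock_chat_backend(),
                      generation_config(seed = 1))   # 25 messages per BCT
bank
#> <message_bank> 1150 messages, 46 techniques (backend: mock)

report <- validate_bank(bank)
report
#> <validation_report>
#>   messages: 1150
#>   length:   1150/1150 (100.00%) within 160 chars and GSM-7; mean 111.9 chars
#>   grade:    mean 5.57 raw, 5.57 adjusted; 1029 raw / 1029 adjusted at or below 8.0
```

`1150` is 46 techniques × 25 messages. The length line reports how many
messages fit a single GSM-7 SMS (here all of them — the mock backend writes
from a short, simple phrase pool) and the mean character count; the grade
line reports the mean Flesch-Kincaid grade before and after the ignore-word
adjustment and how many messages meet the 8th-grade reading-level goal.

Diversity of the bank against itself (sanity check: every technique should
align with itself):

```r
E <- embed_bank(bank, mock_embedding_backend(dim = 1536, seed = 1,
                                             unit_norm = TRUE))
R <- center_embeddings(E)
M <- bct_relevance(R, R)
topk_alignment_accuracy(M, 5)
#> [1] 1
```

A thin command-line interface wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "bctmsg.R", package = "bctmsg"))') \
    generate --out-dir run1 --seed 1
```

with subcommands `generate`, `validate`, `analyze`, `compare` and `synth`,
YAML config support (`--config`), and an `effective_config.yaml` written
next to every command's outputs.

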