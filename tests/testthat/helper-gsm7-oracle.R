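# Independent transcription of the GSM 03.38 default alphabet, recorded as
# Unicode code points by table position (not shared with the package's own
# character-string tables). Used as the brute-force septet-length oracle.

gsm7_oracle_basic_codepoints <- local({
  # table positions 0x20-0x3F are ASCII except 0x24, which holds the general
  # currency sign (the dollar sign sits at position 0x02)
  mid_block <- 32L:63L
  mid_block[mid_block == 36L] <- 164L
  c(
    64L, 163L, 36L, 165L, 232L, 233L, 249L, 236L, 242L, 199L, 10L, 216L, 248L,
    13L, 197L, 229L,
    916L, 95L, 934L, 915L, 923L, 937L, 928L, 936L, 931L, 920L, 926L,
    # position 27 is the escape to the extension table, not a character
    198L, 230L, 223L, 201L,
    mid_block,
    161L, 65L:90L, 196L, 214L, 209L, 220L, 167L,
    191L, 97L:122L, 228L, 246L, 241L, 252L, 224L
  )
})

gsm7_oracle_ext_codepoints <- c(12L, 94L, 123L, 125L, 92L, 91L, 126L, 93L,
                                124L, 8364L)

gsm7_oracle_septets <- function(text) {
  cps <- utf8ToInt(stringi::stri_trans_nfc(text))
  cost <- ifelse(cps %in% gsm7_oracle_basic_codepoints, 1L,
                 ifelse(cps %in% gsm7_oracle_ext_codepoints, 2L, NA_integer_))
  if (anyNA(cost)) NA_integer_ else sum(cost)
}

# Seeded random GSM-7 strings drawn from the union of both oracle tables
# (line breaks excluded so the strings are message-like).
gsm7_random_strings <- function(n, max_len = 60, seed = 42) {
  pool <- setdiff(c(gsm7_oracle_basic_codepoints, gsm7_oracle_ext_codepoints),
                  c(10L, 13L))
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      len <- sample(1:max_len, 1)
      intToUtf8(sample(pool, len, replace = TRUE))
    }, character(1))
  })
}
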