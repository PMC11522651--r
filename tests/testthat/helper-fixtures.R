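# Shared in-code fixtures: tiny databases and banks built at test time.

tiny_db <- function(n = 2) {
  entries <- tibble::tibble(
    number = c("1.2", "3.1", "7.1")[seq_len(n)],
    label = c("Problem solving", "Social support (unspecified)",
              "Prompts/cues")[seq_len(n)],
    definition = c("Analyse factors influencing the behaviour.",
                   "Advise on or arrange social support.",
                   "Introduce a stimulus to prompt the behaviour.")[seq_len(n)],
    examples = c("Identify barriers and ways around them.", NA, NA)[seq_len(n)],
    theoretical_constructs = c("Perceived behavioral control", NA,
                               "Cue-behavior association")[seq_len(n)],
    behavioral_strategies = c("Barrier identification", NA, NA)[seq_len(n)]
  )
  bct_database(entries, source = "tiny")
}

tiny_bank <- function(texts, bcts = rep("1.2", length(texts))) {
  message_bank(tibble::tibble(
    bct_number = bcts,
    bct_label = paste("Technique", bcts),
    message_index = stats::ave(seq_along(texts), bcts, FUN = seq_along),
    text = texts
  ))
}
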