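test_that("septet lengths match the GSM 03.38 tables", {
  expect_equal(gsm7_septet_length("Hello"), 5L)
  expect_equal(gsm7_septet_length("€"), 2L)        # extension char costs 2
  expect_true(is.na(gsm7_septet_length("你好"))) # CJK unencodable
  expect_equal(gsm7_septet_length("Hi {ok}"), 3L + 2L + 2L + 2L)
  expect_identical(gsm7_encodable(c("abc", "café", "naïve", "你")),
                   c(TRUE, TRUE, FALSE, FALSE)) # é is in the default
                   # alphabet, the dotted ï is not
  # greek capitals from the basic table cost 1
  expect_equal(gsm7_septet_length("ΔΩ"), 2L)
})

test_that("septet lengths agree with the independently transcribed oracle", {
  strings <- gsm7_random_strings(2000, seed = 4)
  expect_identical(gsm7_septet_length(strings),
                   vapply(strings, gsm7_oracle_septets, integer(1),
                          USE.NAMES = FALSE))
  # and strings with injected unencodable characters go NA in both
  poisoned <- paste0(strings[1:50], "中")
  expect_true(all(is.na(gsm7_septet_length(poisoned))))
})

test_that("syllable heuristic counts vowel groups with the silent-e rule", {
  expect_equal(count_syllables("medication"), 4L)
  expect_equal(count_syllables("a"), 1L)
  expect_equal(count_syllables("make"), 1L)  # silent terminal e
  expect_equal(count_syllables("table"), 2L) # -le keeps its e
  # adjacent vowels merge into one group: "ia" in diabetes counts once
  expect_equal(count_syllables(c("diabetes", "banana", "apple", "the")),
               c(3L, 3L, 2L, 1L))
  expect_equal(count_syllables("Don't!"), 1L) # punctuation stripped
  expect_error(count_syllables("..."), class = "bctmsg_argument_error")
})

test_that("fk_grade evaluates the closed-form formula", {
  expect_equal(fk_grade("The cat sat."), 0.39 * 3 + 11.8 * 1 - 15.59)
  # two sentences, hand tally: words 5, syllables 8
  text <- "Take your medication. It helps."
  expect_equal(fk_grade(text), 0.39 * (5 / 2) + 11.8 * (8 / 5) - 15.59)
  # ignoring an absent token changes nothing
  expect_equal(fk_grade(text, "zzz"), fk_grade(text))
  # ignoring the 4-syllable word lowers the grade
  expect_lt(fk_grade(text, "medication"), fk_grade(text))
  expect_error(fk_grade("medication", "medication"),
               class = "bctmsg_undefined_grade_error")
})

test_that("fk_grade is strictly increasing in mean syllables per word", {
  # same word/sentence counts (9 words, 1 sentence), increasing syllable mass
  texts <- c("Red hats sit on flat mats all day now.",
             "Heavy rivers carry silver pebbles over seven sunny hills.",
             "Incredible elephants deliberately investigate complicated
              mathematical calculations everywhere continuously.")
  grades <- vapply(gsub("\\s+", " ", texts), fk_grade, numeric(1))
  expect_true(all(diff(grades) > 0))
})

test_that("validate_bank scores length, encodability and readability", {
  msgs <- c(
    strrep("a", 159),                        # pass: 159 GSM-7 chars
    paste0(strrep("b", 161)),                # fail: too long
    "Take your pills with care. 你",     # fail: not GSM-7 encodable
    "This regimen necessitates extraordinarily complicated consideration."
  )
  bank <- tiny_bank(msgs, bcts = c("1.2", "1.2", "3.1", "3.1"))
  rep <- validate_bank(bank)
  pm <- rep$per_message
  expect_identical(pm$passes_length, c(TRUE, FALSE, FALSE, TRUE))
  expect_true(is.na(pm$septet_count[3]))
  expect_true(all(pm$septet_count >= pm$char_count, na.rm = TRUE))
  expect_equal(rep$aggregates$n_pass_length, 2L)
  expect_equal(rep$aggregates$pct_pass_length, 50)
  expect_false(pm$passes_readability[4]) # polysyllabic monster fails grade 8
  # adjusted grade <= raw when ignore list removes a multi-syllable word
  expect_true(all(pm$fk_grade_adjusted <= pm$fk_grade_raw + 1e-12))
})

test_that("aggregates are permutation-invariant and internally consistent", {
  bank <- make_synthetic_bank(synthetic_bank_spec(n_bcts = 6,
                                                  messages_per_bct = 10,
                                                  seed = 8))
  rep1 <- validate_bank(bank)
  tbl <- tibble::as_tibble(bank)
  shuffled <- message_bank(tbl[rev(seq_len(nrow(tbl))), ])
  rep2 <- validate_bank(shuffled)
  expect_equal(rep1$aggregates, rep2$aggregates)
  a <- rep1$aggregates
  expect_lte(a$n_pass_length, a$n_total)
  expect_equal(a$pct_pass_length, 100 * a$n_pass_length / a$n_total)
  expect_equal(a$pct_pass_readability_adjusted,
               100 * a$n_pass_readability_adjusted / a$n_total)
})

test_that("reports serialize to JSON/CSV and plots build", {
  bank <- tiny_bank(c("Take your dose now.", "Plan your day well."))
  rep <- validate_bank(bank)
  json <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_validation_report(rep, json, per_message_csv = csv)
  round_trip <- jsonlite::fromJSON(json)
  expect_equal(round_trip$aggregates$n_total, 2L)
  expect_equal(nrow(readr::read_csv(csv, show_col_types = FALSE)), 2L)
  expect_s3_class(plot_length_distribution(rep), "ggplot")
  expect_s3_class(plot_grade_distribution(rep, "raw"), "ggplot")
})
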