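#' GSM 03.38 default alphabet
#'
#' A single SMS carries 160 septets (7-bit units). Characters in the GSM-7
#' basic table cost one septet; characters in the extension table are sent as
#' an escape plus the character and cost two; anything else forces a switch
#' to UCS-2 and the message is not GSM-7 deliverable. The two tables below
#' are transcribed from the 3GPP TS 23.038 default alphabet.
#'
#' @name gsm7
NULL

GSM7_BASIC <- paste0(
  "@£$¥èéùìòÇ\nØø\rÅå",
  "Δ_ΦΓΛΩΠΨΣΘΞ",
  "ÆæßÉ",
  " !\"#¤%&'()*+,-./0123456789:;<=>?",
  "¡ABCDEFGHIJKLMNOPQRSTUVWXYZÄÖÑÜ§",
  "¿abcdefghijklmnopqrstuvwxyzäöñüà"
)
GSM7_EXTENSION <- "\f^{}\\[~]|€"

gsm7_basic_chars <- function() strsplit(GSM7_BASIC, "", fixed = TRUE)[[1]]
gsm7_extension_chars <- function() strsplit(GSM7_EXTENSION, "", fixed = TRUE)[[1]]

#' Septet length of a text under GSM-7 encoding
#'
#' Sums per-character septet costs (basic-table character = 1, extension-table
#' character = 2) over the NFC-normalized text. Returns `NA` when any
#' character is in neither table (the text is not GSM-7 encodable).
#'
#' @param text character vector of message texts.
#' @return Integer vector of septet counts (`NA` where unencodable).
#' @export
gsm7_septet_length <- function(text) {
  basic <- gsm7_basic_chars()
  ext <- gsm7_extension_chars()
  vapply(stringi::stri_trans_nfc(text), function(t) {
    if (is.na(t)) return(NA_integer_)
    chars <- strsplit(t, "", fixed = TRUE)[[1]]
    cost <- ifelse(chars %in% basic, 1L, ifelse(chars %in% ext, 2L, NA_integer_))
    if (anyNA(cost)) NA_integer_ else sum(cost)
  }, integer(1), USE.NAMES = FALSE)
}

#' @rdname gsm7_septet_length
#' @return `gsm7_encodable()`: logical vector, `TRUE` where every character
#'   is in the GSM-7 basic or extension table.
#' @export
gsm7_encodable <- function(text) !is.na(gsm7_septet_length(text))
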