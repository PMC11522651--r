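# Internal deterministic primitives shared by the mock backends and the
# synthetic-bank generator. These never touch R's global RNG state, so mock
# generation is a pure function of its inputs.

MERSENNE31 <- 2147483647 # 2^31 - 1

#' Stable 31-bit string hash (polynomial rolling hash over UTF-8 code points)
#' @noRd
str_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 7
  for (cp in utf8ToInt(enc2utf8(x))) {
    h <- (h * 131 + cp) %% MERSENNE31
  }
  as.integer(h)
}

#' Lehmer (Park-Miller) uniform stream seeded by an arbitrary key string.
#' Returns a function() yielding one U(0,1) deviate per call.
#' @noRd
lehmer_stream <- function(key) {
  state <- str_hash(key)
  if (state == 0L) state <- 1L
  state <- as.double(state)
  function() {
    state <<- (state * 16807) %% MERSENNE31
    state / MERSENNE31
  }
}

#' One standard normal deviate via Box-Muller from a Lehmer stream
#' @noRd
stream_norm <- function(stream, n) {
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stream()
    u2 <- stream()
    if (u1 <= 0) u1 <- .Machine$double.eps
    r <- sqrt(-2 * log(u1))
    out[i] <- r * cos(2 * pi * u2)
    if (i + 1L <= n) out[i + 1L] <- r * sin(2 * pi * u2)
    i <- i + 2L
  }
  out
}

#' Pick one element of x per the stream
#' @noRd
stream_pick <- function(stream, x) {
  x[[1L + floor(stream() * length(x)) %% length(x)]]
}

#' Run code under a temporary R RNG seed, restoring global state afterwards.
#' Used where a dependency (Rtsne, sample()) consumes R's RNG.
#' @noRd
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Order index for taxonomy identifiers like "1.2", "10.4": numeric on
#' major then minor component (lexicographic sort would put "10.1" before "2.3").
#' @noRd
bct_number_order <- function(numbers) {
  parts <- strsplit(numbers, ".", fixed = TRUE)
  major <- vapply(parts, function(p) as.numeric(p[[1L]]), numeric(1))
  minor <- vapply(parts, function(p) as.numeric(p[[2L]]), numeric(1))
  order(major, minor)
}

#' @noRd
is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Parse a section of the packaged phrase pool. The pool file opens with the
# "sentences" section; '# <name>' lines start a new section.
phrase_pool_cache <- new.env(parent = emptyenv())

#' @noRd
phrase_pool_section <- function(section) {
  if (is.null(phrase_pool_cache$pool)) {
    path <- system.file("extdata", "phrase_pool.txt", package = "bctmsg",
                        mustWork = TRUE)
    lines <- readLines(path, encoding = "UTF-8")
    current <- "sentences"
    pool <- list()
    for (ln in lines) {
      if (startsWith(ln, "#")) {
        nm <- trimws(sub("^#+", "", ln))
        if (nm %in% c("simple-words", "complex-words", "sentences")) current <- nm
        next
      }
      if (nzchar(trimws(ln))) pool[[current]] <- c(pool[[current]], trimws(ln))
    }
    phrase_pool_cache$pool <- pool
  }
  phrase_pool_cache$pool[[section]]
}
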