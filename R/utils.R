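#' @keywords internal
"_PACKAGE"

# Logging -----------------------------------------------------------------

.log_levels <- c(debug = 10L, info = 20L, warn = 30L, error = 40L)

#' Set the logging threshold
#'
#' Messages below `level` are suppressed. Logging goes to stderr.
#'
#' @param level One of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @return The previous level, invisibly.
#' @export
set_log_level <- function(level = c("info", "debug", "warn", "error")) {
  level <- match.arg(level)
  old <- getOption("twasmr.log_level", "info")
  options(twasmr.log_level = level)
  invisible(old)
}

pkg_log <- function(level, ...) {
  thr <- .log_levels[[getOption("twasmr.log_level", "info")]]
  if (.log_levels[[level]] >= thr) {
    message(sprintf("[%s] %s", toupper(level), paste0(...)))
  }
  invisible(NULL)
}

# Small helpers ------------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# FNV-1a hash of a character scalar, hex string. Used only to fingerprint
# run configurations in manifests; not cryptographic.
fnv1a <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    # xor and multiply on a 32-bit value stored as double, in 16-bit
    # halves to stay inside exact double-integer range
    hlo <- bitwXor(as.integer(h %% 65536), as.integer(b))
    hhi <- as.integer(h %/% 65536)
    h <- (((hhi * prime) %% 65536) * 65536 + hlo * prime) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

# Derive a stream-specific 31-bit seed from a base seed so that pipeline
# stages draw from independent streams but remain reproducible.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- strtoi(substr(fnv1a(paste0(stream, ":", format(seed))), 1, 7), 16L)
  (as.integer(h) + as.integer(seed)) %% .Machine$integer.max
}
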