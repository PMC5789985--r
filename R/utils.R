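#' @keywords internal
"_PACKAGE"

# Structured log line on stderr. Kept deliberately plain so pipelines can
# grep it; options(enudamage.quiet = TRUE) silences everything.
log_msg <- function(..., level = "INFO") {
  if (isTRUE(getOption("enudamage.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[enudamage %s] %s", level, paste0(...)))
}

# Seed the RNG for the duration of the calling function only, leaving the
# global RNG state untouched. seed = NULL leaves the RNG alone.
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::local_seed(as.integer(seed), .local_envir = envir)
  invisible(NULL)
}

# Deterministic child seeds from one master seed, so that per-replicate /
# per-pedigree random streams are reproducible and mutually independent.
# R integers are 32-bit; derived seeds stay below 2^31.
derive_seeds <- function(seed, n) {
  f <- function() {
    local_seed(seed)
    sample.int(.Machine$integer.max - 1L, n)
  }
  f()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
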