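# Internal condition helpers. Input errors (malformed files, bad arguments)
# and precondition errors (e.g. no blank samples) carry distinct classes so
# callers -- and the command-line wrapper -- can map them to exit codes.

.inputError <- function(...) {
  stop(errorCondition(paste0(...), class = "jumpsieve_input_error"))
}

.preconditionError <- function(...) {
  stop(errorCondition(paste0(...), class = "jumpsieve_precondition_error"))
}

.obsKey <- function(asv_id, sample_id) paste(asv_id, sample_id, sep = "\r")

# deterministic alphabetical order independent of locale
.lexSort <- function(x) {
  x[order(method = "radix", x)]
}

.assertCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min ||
      x != round(x)) {
    .inputError(name, " must be a single integer >= ", min)
  }
  as.integer(x)
}

.assertProb <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    .inputError(name, " must be a single probability in [0, 1]")
  }
  as.numeric(x)
}
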