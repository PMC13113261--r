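# Structured conditions: every FaceSym error carries a subclass so callers
# (and the CLI exit-code mapping) can dispatch on the failure kind.

.fsStop <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("FaceSym_", class, "_error"), "FaceSym_error",
              "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

.fsWarn <- function(class, msg, ...) {
  warning(structure(
    class = c(paste0("FaceSym_", class, "_warning"), "FaceSym_warning",
              "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Structured log line: LEVEL | stage | message. Suppressible via
# options(FaceSym.quiet = TRUE); tests capture with expect_message().
.fsLog <- function(stage, msg, ..., level = "INFO") {
  if (isTRUE(getOption("FaceSym.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("%s | %s | %s", level, stage, sprintf(msg, ...)))
}
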