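## internal helpers shared across modules

ms_abort <- function(message, class) {
  stop(errorCondition(message, class = c(class, "msvalid_error")))
}

ms_warn <- function(message, class) {
  warning(warningCondition(message, class = c(class, "msvalid_warning")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## seeds handed to downstream stages are derived additively from one base
## seed; keep them inside the 32-bit integer range R requires
ms_seed <- function(base, offset) {
  as.integer((as.numeric(base) + as.numeric(offset)) %% .Machine$integer.max)
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.finite(x) && x == as.integer(x) && x >= min
}

is_number <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)
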