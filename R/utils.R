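# internal helpers shared across modules

.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
}

# collapse a character vector for error messages, truncating long lists
.fmt_ids <- function(x, max = 5L) {
  if (length(x) > max) {
    paste0(paste(x[seq_len(max)], collapse = ", "), ", ... (", length(x), " total)")
  } else {
    paste(x, collapse = ", ")
  }
}
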