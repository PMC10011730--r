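# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == round(x)

.is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# consistency constant making the MAD an unbiased estimator of sigma for
# normal data (1 / qnorm(3/4), conventionally rounded)
MAD_CONSISTENCY <- 1.4826
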