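# internal helpers shared across modules

# Deterministic 32-bit seed mixing: keeps derived seeds positive and < 2^31
# so they are always valid arguments to set.seed().
mix_seed <- function(seed, ...) {
  ks <- c(seed, unlist(list(...)))
  h <- 0
  for (k in ks) h <- (h * 69069 + (k %% 2147483647) + 1) %% 2147483647
  as.integer(h %% 2147483629L + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_icustatsel <- function(msg, class) {
  stop(structure(class = c(class, "icustatsel_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_that <- function(ok, msg, class = "icustatsel_argument_error") {
  if (!isTRUE(ok)) stop_icustatsel(msg, class)
  invisible(TRUE)
}
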