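# internal helpers

# run expr under a fixed seed without disturbing the caller's RNG stream
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# half-up decimal rounding, matching printed 2-dp metric tables
roundHalfUp <- function(x, digits = 2L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

stopValidation <- function(fmt, ...) {
  stop(structure(class = c("methylUNet_validation", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

stopIO <- function(fmt, ...) {
  stop(structure(class = c("methylUNet_io", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}
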