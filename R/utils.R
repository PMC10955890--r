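#' @importFrom rlang %||% abort warn
#' @importFrom stats rnorm runif median sd cor quantile
NULL

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# stream. `seed = NULL` leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialize a seed to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# VAS rounding: round half away from zero (base round() is banker's).
round_vas <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Derive a stage seed from a master seed, staying inside 32-bit range.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) {
    return(NULL)
  }
  as.integer((as.double(seed) * 48271 + stage * 10007) %% 2147483647)
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

score_types <- function() c("y1", "y2", "y3", "y4", "y5")

score_type_labels <- function() {
  c(
    y1 = "pre-speech self-efficacy",
    y2 = "post-speech self-evaluation",
    y3 = "judges' feedback",
    y4 = "post-feedback self-evaluation",
    y5 = "post-feedback self-efficacy"
  )
}
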