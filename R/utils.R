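#' @import methods
#' @importFrom stats pt qt rnorm runif setNames na.omit rbinom var
#' @importFrom utils read.csv write.csv head combn
NULL

# Canonical anatomy. Treatable upper-lobe segments per side; the lingula
# (LB4 + LB5) belongs to the left upper lobe but is never treated.
.LEFT_TREATABLE   <- c("LB1", "LB2", "LB3")
.LEFT_MERGED      <- "LB1+2"
.LEFT_LINGULA     <- c("LB4", "LB5")
.RIGHT_TREATABLE  <- c("RB1", "RB2", "RB3")
.LOWER_IDS        <- c(left = "LLL", right = "RLL")
.ALL_SEGMENT_IDS  <- c(.LEFT_TREATABLE, .LEFT_MERGED, .LEFT_LINGULA,
                       .RIGHT_TREATABLE, .LOWER_IDS)

.otherSide <- function(side) ifelse(side == "left", "right", "left")

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is untouched. All stochastic generators in the package route
# their randomness through this helper.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic, locale-independent string ordering (C collation).
cSort <- function(x) sort(x, method = "radix")
cOrder <- function(...) order(..., method = "radix")

.assertNumber <- function(x, name, lower = -Inf, upper = Inf,
                          finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("'%s' = %g is outside [%g, %g]", name, x, lower, upper),
         call. = FALSE)
  invisible(x)
}
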