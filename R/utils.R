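# grams-force per newton; the texture analyzer reports trigger force in g
.G_PER_N <- 101.9716

#' Convert gram-force to newtons
#' @param g numeric, force in gram-force
#' @return force in newtons
#' @keywords internal
gf_to_newton <- function(g) g / .G_PER_N

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_fishtpa <- function(..., class = "fishtpa_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_fishtpa(sprintf("'%s' must be a single finite number", name))
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_fishtpa(sprintf("'%s' = %g is outside the allowed range %s%g, %g%s",
                         name, x,
                         if (strict_lower) "(" else "[", lower, upper,
                         if (strict_upper) ")" else "]"))
  invisible(x)
}

#' Canonical TPA attribute names
#'
#' The twelve texture profile analysis attributes computed from a
#' double-compression curve: seven standard (adhesiveness, chewiness-1,
#' cohesiveness, hardness-1, resilience, springiness, thickness-1) and five
#' extended (chewiness-1b, chewiness-2, hardness-1b, hardness-2,
#' thickness-2).
#'
#' @return character vector of length 12
#' @export
tpa_attribute_names <- function() {
  c("adhesiveness", "chewiness1", "chewiness1b", "chewiness2",
    "cohesiveness", "hardness1", "hardness1b", "hardness2",
    "resilience", "springiness", "thickness1", "thickness2")
}
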