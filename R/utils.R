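#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats sd rbinom runif rnorm setNames aggregate quantile
#' @importFrom stats plogis qlogis wilcox.test chisq.test cor median optim pnorm
#' @importFrom utils head read.table write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")

revcomp_chars <- function(x) {
  # x: character vector of single bases; returns reverse-complement vector
  rev(unname(COMPLEMENT[x]))
}

#' Run code with a fixed RNG seed, restoring global state afterwards
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

#' Derive a deterministic sub-seed from a master seed and a stage label
#' @noRd
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 1103L + h) %% 2147483647)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  invisible(x)
}

# population standard deviation (divides by n, not n-1)
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
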