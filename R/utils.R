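#' @import data.table
#' @importFrom stats dnorm kmeans median pchisq plogis pnorm qnorm quantile
#'   rbeta rbinom rlnorm rnorm runif sd setNames var glm binomial predict
#'   anova rmultinom
#' @importFrom utils head tail write.table packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed
#'
#' Each logical entity class (SNPs, samples, intensities, ...) draws from its
#' own seeded stream so that, e.g., enlarging the SNP set does not perturb the
#' sample metadata draws. Derived seeds stay below 2^31 - 1.
#'
#' @param seed master integer seed
#' @param id small non-negative integer identifying the stream
#' @return an integer seed
#' @keywords internal
stream_seed <- function(seed, id) {
  as.integer((as.double(seed) * 48271 + 1000003 * (id + 1)) %% 2147483647)
}

with_stream <- function(seed, id, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(stream_seed(seed, id))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_fraction <- function(x, what) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
    stopf("'%s' must lie in [0, 1]", what)
  invisible(x)
}

#' Draw from a named univariate distribution
#'
#' Supported: `uniform` (min, max), `beta` (shape1, shape2), `constant`
#' (value). Used for the MAF and Dish-QC distributions of the simulator.
#'
#' @param n number of draws
#' @param dist list with element `name` plus the distribution's parameters
#' @return numeric vector of length `n`
#' @keywords internal
draw_distribution <- function(n, dist) {
  if (!is.list(dist) || is.null(dist$name))
    stopf("distribution must be a list with a 'name' element")
  switch(dist$name,
    uniform = {
      lo <- dist$min %||% 0; hi <- dist$max %||% 1
      if (!is.finite(lo) || !is.finite(hi) || hi < lo)
        stopf("invalid uniform parameters")
      runif(n, lo, hi)
    },
    beta = {
      s1 <- dist$shape1; s2 <- dist$shape2
      if (is.null(s1) || is.null(s2) || s1 <= 0 || s2 <= 0)
        stopf("invalid beta parameters")
      rbeta(n, s1, s2)
    },
    constant = rep(dist$value %||% stopf("constant distribution needs 'value'"), n),
    stopf("unknown distribution '%s'", dist$name)
  )
}

GENOTYPE_LEVELS <- c("AA", "AB", "BB", "NC")
SNP_CATEGORIES <- c("PolyHighResolution", "NoMinorHom", "MonoHighResolution",
                    "CallRateBelowThreshold", "OTV", "Other", "Rescued")
LATENT_CLASSES <- c("poly_resolved", "no_minor_hom", "monomorphic",
                    "low_cr", "otv", "unresolvable")
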