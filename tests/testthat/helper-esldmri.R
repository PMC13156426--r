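# Shared helpers for the test suite.

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Small phantom configuration for fast tests.
test_phantom_config <- function(...) {
  args <- utils::modifyList(
    list(grid_shape = c(48, 48, 64), seed = 42,
         noise_model = "none", sample_effect_sd = 0),
    list(...))
  do.call(phantom_config, args)
}

# Lazily built shared noiseless phantom (48x48x64).
.test_cache <- new.env()
test_phantom <- function() {
  if (is.null(.test_cache$phantom))
    .test_cache$phantom <- generate_phantom(test_phantom_config())
  .test_cache$phantom
}

# Independent evaluation of the GPD sphere series used as an oracle:
# different algebraic grouping (the two-bracket form) and many more terms.
oracle_sphere_signal <- function(b, delta, Delta, D, R, n_terms = 200) {
  x <- oracle_bessel_roots(n_terms)
  gg2 <- if (b == 0) 0 else b / (delta^2 * (Delta - delta / 3))
  a2 <- (x / R)^2
  d <- a2 * D
  num2 <- 2 + exp(-d * (Delta - delta)) - 2 * exp(-d * delta) -
    2 * exp(-d * Delta) + exp(-d * (Delta + delta))
  terms <- (1 / (a2 * (x^2 - 2))) * (2 * delta / d - num2 / d^2)
  exp(-2 * gg2 * sum(terms))
}

# Independent root finder: bisection on j1'(x) expressed through the
# recurrence j1'(x) = j0(x) - 2 j1(x) / x (a different formula from the
# implementation's polynomial-trig form).
oracle_bessel_roots <- function(m) {
  if (!is.null(.test_cache$oracle_roots) &&
      length(.test_cache$oracle_roots) >= m)
    return(.test_cache$oracle_roots[seq_len(m)])
  f <- function(x) {
    j0 <- sin(x) / x
    j1 <- sin(x) / x^2 - cos(x) / x
    j0 - 2 * j1 / x
  }
  roots <- numeric(m)
  found <- 0
  lo <- 1
  step <- 0.01
  flo <- f(lo)
  while (found < m) {
    hi <- lo + step
    fhi <- f(hi)
    if (flo * fhi < 0) {
      a <- lo; b <- hi
      for (i in 1:80) {
        mid <- (a + b) / 2
        if (f(a) * f(mid) <= 0) b <- mid else a <- mid
      }
      found <- found + 1
      roots[found] <- (a + b) / 2
    }
    lo <- hi
    flo <- fhi
  }
  .test_cache$oracle_roots <- roots
  roots
}
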