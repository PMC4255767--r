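# Internal numeric helpers shared across estimators.

# harmonic numbers a1 = sum 1/i and a2 = sum 1/i^2, i = 1..k
harmonic1 <- function(k) if (k < 1) 0 else sum(1 / seq_len(k))
harmonic2 <- function(k) if (k < 1) 0 else sum(1 / seq_len(k)^2)

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic 31-bit child seed from a master seed and a stream index,
# so each locus is reproducible independently of simulation order
child_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 48271) %% 2147483647
  x <- (x + as.double(index) * 69621) %% 2147483647
  as.integer((x * 16807) %% 2147483629 + 1)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
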