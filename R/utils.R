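## internal helpers shared across modules

softplus <- function(x) {
  ## numerically stable log(1 + exp(x))
  ifelse(x > 30, x, log1p(exp(x)))
}

## derive a child seed from a master seed and a stream index; stays < 2^31
childSeed <- function(seed, stream) {
  ((as.numeric(seed) %% 2147483647) * 48271 + 7919 * stream) %% 2147483629
}

## deterministic non-cryptographic hash of an R object (djb2 over deparse)
configHash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

## write a data.frame as CSV with a comment header carrying seed + hash
writeStampedCsv <- function(df, path, seed = NA, hash = "") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# seed=%s config_hash=%s", as.character(seed), hash), con)
  utils::write.csv(format(df, trim = TRUE, digits = 15, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
}

readStampedCsv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

stopIfNot <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

## Pearson correlation + two-sided p from the t transform; NA on zero variance
corTestSafe <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(c(r = NA_real_, p = NA_real_, n = n))
  ct <- stats::cor.test(x, y, method = "pearson")
  c(r = unname(ct$estimate), p = ct$p.value, n = n)
}

## standard error of the mean, NA-tolerant
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
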