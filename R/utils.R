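#' @importFrom stats rnorm runif quantile sd cor var cutree hclust as.dist
#' @importFrom stats fisher.test wilcox.test kmeans setNames aggregate dist
#' @importFrom utils head read.csv write.csv
NULL

## Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

## Derive a stream-specific seed from a master seed; stays below 2^31-1.
deriveSeed <- function(seed, k) {
  as.integer((((as.double(seed) %% 2147483629) * 48271) %% 2147483629 + k) %%
               2147483629)
}

## Deterministic integer salt for a character id (protein-id-salted splits).
idSalt <- function(id) {
  as.integer(sum(utf8ToInt(id) * seq_along(utf8ToInt(id))) %% 1000003L)
}

fsLog <- function(..., verbose = getOption("featscope.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[featscope] ", ...)
}

## Truncated normal (+/- 2 sd) used for weight initialization.
rtruncnorm2 <- function(n, sd = 0.1) {
  x <- rnorm(n, 0, sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

## Column variances of a matrix (population, i.e. denominator n).
colVarsPop <- function(m) {
  colMeans(m * m) - colMeans(m)^2
}

## Short hash of a configuration list, used in output file headers.
configHash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

## Write a data.frame with a provenance header comment line.
writeTableWithHeader <- function(df, file, hash = "", seed = NA, sep = ",") {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# featscope config=%s seed=%s", hash, seed), con)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(file)
}

readTableWithHeader <- function(file, sep = ",") {
  utils::read.table(file, sep = sep, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}
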