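#' @importFrom stats rnorm runif quantile sd var median qnorm dnorm rchisq
#'   optimise nlminb acf glm poisson coef vcov rpois rgamma aggregate offset
#' @importFrom utils read.csv write.csv head modifyList
#' @importFrom methods as is
#' @importFrom Matrix update determinant solve crossprod tcrossprod diag
#'   rowSums colSums t which
NULL

# Pairwise Euclidean distances between two coordinate matrices (km).
# Plain dense computation; all desk-scale problems here are < 10^4 points.
pdist <- function(a, b = a) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Derive a child RNG seed from a base seed and a stage label, staying well
# below .Machine$integer.max so downstream set.seed() calls are valid.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483399L) + 1L
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Full-precision numeric formatting for deterministic CSV round trips.
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 17, format = "g"))
}

#' Write a data frame as CSV with 17-significant-digit numerics
#'
#' Numeric columns are formatted to 17 significant digits so that a write/read
#' round trip reproduces the values bit-exactly and repeated runs of a
#' deterministic pipeline produce byte-identical files.
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- fmt_num(out[[j]])
    }
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a CSV written by [write_table_csv()]
#' @param path file path.
#' @return data frame.
#' @export
read_table_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.csv(path, stringsAsFactors = FALSE)
}

# Posterior summary of a draws vector.
summarise_draws <- function(x) {
  q <- unname(quantile(x, c(0.025, 0.5, 0.975), type = 7))
  c(mean = mean(x), q2.5 = q[1], median = q[2], q97.5 = q[3])
}

# Effective sample size via initial positive sequence of autocorrelations.
ess <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(n)
  r <- acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  k <- 1
  while (k <= length(r) - 1) {
    pair <- r[k] + r[k + 1]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2
  }
  max(1, n / (1 + 2 * s))
}

# Split-chain potential scale reduction factor (single chain, split in two).
split_rhat <- function(x) {
  n <- floor(length(x) / 2)
  if (n < 5) return(NA_real_)
  a <- x[seq_len(n)]
  b <- x[seq_len(n) + n]
  m <- c(mean(a), mean(b))
  w <- mean(c(var(a), var(b)))
  if (w == 0) return(1)
  bvar <- n * var(m)
  sqrt((((n - 1) / n) * w + bvar / n) / w)
}
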