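# Shared helpers: delimited-text reading, quantile transform, seeded RNG.

# Auto-detect comma vs tab from the header line; header row is required.
.readDelim <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
             na.strings = c("", "NA", "NaN"), check.names = FALSE)
}

.writeDelim <- function(x, path, sep = "\t") {
  write.table(x, path, sep = sep, quote = FALSE, row.names = FALSE,
              na = "NA")
}

#' Uniform quantile (empirical-CDF rank) transform
#'
#' Maps values to `rank / n` with average ranks on ties, so that distinct
#' inputs land on `{1/n, 2/n, ..., 1}` and the transform is
#' order-preserving. `NA`s are kept as `NA` and excluded from `n`.
#'
#' @param x numeric vector.
#' @return numeric vector in `(0, 1]` (NA preserved).
#' @examples
#' quantileTransform(c(5, 1, 3))  # 1, 1/3, 2/3
#' @export
quantileTransform <- function(x) {
  n <- sum(!is.na(x))
  if (n == 0L) return(x)
  rank(x, ties.method = "average", na.last = "keep") / n
}

# Evaluate `expr` under a local, restored-after RNG state seeded with `seed`.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}
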