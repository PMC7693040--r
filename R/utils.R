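#' Percent increase between two counts
#'
#' Rounded percent increase of `b` over `a`, the arithmetic used when
#' comparing the number of valid models retained by two training families
#' (e.g. "cross-tissue models were 21% more numerous than elastic net").
#'
#' @param a Baseline count (> 0).
#' @param b Comparison count.
#' @param digits Rounding digits (default 0, i.e. whole percent).
#' @return Percent increase `100 * (b / a - 1)`, rounded.
#' @examples
#' percent_increase(281848, 340104) # 21
#' @export
percent_increase <- function(a, b, digits = 0) {
  stopifnot(is.numeric(a), is.numeric(b), a > 0)
  round(100 * (b / a - 1), digits = digits)
}

# Derive a child seed for a named stage from one master seed; keeps every
# stage on its own reproducible stream while staying within 32-bit range.
child_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Equal-as-possible deterministic fold assignment.
make_folds <- function(n, k, seed) {
  stopifnot(n >= k, k >= 2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

# Population-scale column standardization (glmnet convention: sd with 1/n).
std_cols <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu, "-")
  s <- sqrt(colSums(Xc^2) / n)
  s[s < .Machine$double.eps] <- 1 # constant columns stay zero after centering
  list(X = sweep(Xc, 2L, s, "/"), center = mu, scale = s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
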