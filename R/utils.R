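# Internal helpers shared across modules.

# Run `expr` under a fixed RNG state without clobbering the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Stable per-stage seed derived from a global seed and a stage name, kept
# below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, stage) {
  h <- digest::digest(paste0(stage, ":", seed), algo = "crc32")
  as.integer(strtoi(substr(h, 1, 7), base = 16L) %% .Machine$integer.max)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items, used to
#' compare recovered clusters against planted ground truth. 1 means identical
#' partitions (up to label names), 0 is the expectation under independence.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return a single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

# F_beta score from precision and recall; 0 when both are 0.
f_beta <- function(precision, recall, beta = 0.5) {
  if (precision == 0 && recall == 0) return(0)
  b2 <- beta^2
  (1 + b2) * precision * recall / (b2 * precision + recall)
}

# Coerce any Matrix sparse/dense form to dgCMatrix.
as_dgc <- function(x) {
  methods::as(methods::as(methods::as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}
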