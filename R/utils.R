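#' @keywords internal
"_PACKAGE"

# The twenty proteinogenic amino acids, alphabetical one-letter codes.
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

BASIC_RESIDUES  <- c("K", "R")
ACIDIC_RESIDUES <- c("D", "E")
PAD_CHAR <- "_"

# Approximate human proteome residue frequencies (UniProt-style background),
# renormalized over the 20 standard residues.
BACKGROUND_AA_FREQ <- c(
  A = 0.0702, C = 0.0230, D = 0.0473, E = 0.0710, F = 0.0365,
  G = 0.0658, H = 0.0263, I = 0.0433, K = 0.0572, L = 0.0996,
  M = 0.0213, N = 0.0359, P = 0.0631, Q = 0.0477, R = 0.0564,
  S = 0.0833, T = 0.0536, V = 0.0597, W = 0.0122, Y = 0.0266
)
BACKGROUND_AA_FREQ <- BACKGROUND_AA_FREQ / sum(BACKGROUND_AA_FREQ)

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive an independent integer sub-seed from a master seed
#'
#' Used so that one run seed governs several stochastic stages (simulation
#' identity, condition noise, clustering restarts, motif sampling) through
#' distinct streams. Result always fits in a 32-bit integer.
#' @noRd
derive_seed <- function(seed, offset) {
  as.integer((abs(as.numeric(seed)) %% 1e6) * 1009 + abs(offset) * 9973) %% 2147483646L + 1L
}

#' Geometric mean of positive values (missing values dropped)
#' @noRd
geometric_mean <- function(x) {
  x <- x[is.finite(x) & x > 0]
  if (length(x) == 0L) return(NA_real_)
  exp(mean(log(x)))
}

#' Lognormal noise factors with unit mean and a given coefficient of variation
#' @noRd
lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items, used to
#' score recovery of planted kinetic classes. 1 means identical partitions
#' (up to label permutation), 0 is the expectation under random labeling.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return A number in (-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must label the same items")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Format a half-life for serialization
#'
#' Infinite half-lives (curves never crossing y = 0.5 within the observation
#' window) are serialized as the sentinel string `">W"` where `W` is the
#' window length in minutes.
#' @noRd
format_half_life <- function(h, window) {
  ifelse(is.na(h), NA_character_,
         ifelse(is.infinite(h), sprintf(">%g", window), format(h, digits = 15)))
}

#' Parse serialized half-lives back to numeric (sentinel -> Inf)
#' @noRd
parse_half_life <- function(x) {
  x <- as.character(x)
  out <- suppressWarnings(as.numeric(x))
  out[grepl("^\\s*>", x)] <- Inf
  out
}
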