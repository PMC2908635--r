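## Hairpin self-folding free energy.
##
## Minimum free energy over all single-hairpin structures: a Watson-Crick
## stem of >= 3 bp closed by a loop of >= 3 nt.  Energies are the unified
## DNA nearest-neighbor stack parameters at 37 C plus a hairpin-loop
## length penalty; multiloops, bulges and internal mismatches are out of
## scope (a 60-mer's dominant self-structure is a single hairpin).

## DeltaG37 (kcal/mol) for the stack 5'-XY-3' paired with its complement.
.NN_STACK <- c(
  AA = -1.00, AC = -1.44, AG = -1.28, AT = -0.88,
  CA = -1.45, CC = -1.84, CG = -2.17, CT = -1.28,
  GA = -1.30, GC = -2.24, GG = -1.84, GT = -1.44,
  TA = -0.58, TC = -1.30, TG = -1.45, TT = -1.00)

## Hairpin loop penalty DeltaG37 (kcal/mol) by loop length; linear
## interpolation between tabulated lengths, Jacobson-Stockmayer
## extrapolation beyond 30 nt.
.LOOP_N <- c(3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 12L, 14L, 16L, 18L, 20L,
             25L, 30L)
.LOOP_G <- c(3.5, 3.5, 3.3, 4.0, 4.2, 4.3, 4.5, 4.6, 5.0, 5.1, 5.3, 5.5,
             5.7, 6.1, 6.3)

#' Nearest-neighbor parameter tables used for hairpin evaluation
#'
#' Exposes the stack free energies (37 C, kcal/mol, keyed by the top-strand
#' dinucleotide 5'-XY-3') and the hairpin-loop penalty table so that
#' independent reimplementations can share the same constants.
#'
#' @return a list with elements \code{stack} (named numeric),
#'   \code{loop_n}, \code{loop_g} (penalty table), and \code{loopPenalty},
#'   a function of loop length.
#' @export
hairpinEnergyParams <- function() {
  list(stack = .NN_STACK, loop_n = .LOOP_N, loop_g = .LOOP_G,
       loopPenalty = .loopPenalty)
}

.loopPenalty <- function(n) {
  if (n < 3L) return(Inf)
  if (n <= 30L) return(stats::approx(.LOOP_N, .LOOP_G, xout = n)$y)
  ## 1.75 * R * T * ln(n/30), R in kcal/(mol K), T = 310.15 K
  .LOOP_G[length(.LOOP_G)] + 1.75 * 0.0019872 * 310.15 * log(n / 30)
}

#' Minimum hairpin folding free energy of a probe
#'
#' Evaluates every possible single hairpin (contiguous Watson-Crick stem of
#' at least 3 bp, loop of at least 3 nt) and returns the minimum free
#' energy: the sum of the stem's nearest-neighbor stack terms plus the
#' loop-length penalty at 37 C.  Sequences that admit no such hairpin
#' return \code{Inf} (no stable self-structure; any value > 0 means the
#' probe does not self-fold).
#'
#' @param sequence an ACGT string (character or \code{DNAString}),
#'   length >= 8.
#' @return free energy in kcal/mol.
#' @examples
#' hairpinDeltaG(strrep("A", 60))  # Inf: poly-A cannot pair with itself
#' @export
hairpinDeltaG <- function(sequence) {
  p <- .encodeDna(sequence)
  n <- length(p)
  if (n < 8L) stop("sequence must be at least 8 nt")
  best <- Inf
  ## pair (i, j) complementary iff codes sum to 3 (A=0..T=3)
  for (i in seq_len(n - 8L)) {
    for (j in seq.int(n, i + 8L)) {
      if (p[i] + p[j] != 3L) next
      ## grow the stem inward; candidate at every stem length >= 3
      stack <- 0
      L <- 1L
      maxL <- (j - i - 2L) %/% 2L    # keeps loop >= 3
      while (L < maxL && p[i + L] + p[j - L] == 3L) {
        stack <- stack + .stackEnergy(p[i + L - 1L], p[i + L])
        L <- L + 1L
        if (L >= 3L) {
          g <- stack + .loopPenalty(j - i + 1L - 2L * L)
          if (g < best) best <- g
        }
      }
    }
  }
  best
}

## stack energy from the two successive top-strand codes
.stackEnergy <- function(a, b) {
  .NN_STACK[[4L * a + b + 1L]]
}
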