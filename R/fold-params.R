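# Nearest-neighbour free-energy parameters (37 degrees C, kcal/mol) for
# the hairpin-only folding engine.  Stack free energies are
# Turner-style values for Watson-Crick and G.U wobble pairs; loop
# penalties are tabulated initiation terms.  The engine scores a stem
# as: hairpin-loop initiation + sum over consecutive pair transitions of
# either a stack term (contiguous pairs) or a bulge/internal-loop
# initiation term (no stacking across interrupted helices, no dangles,
# no terminal-pair corrections).

# Pair codes: 1 AU, 2 UA, 3 CG, 4 GC, 5 GU, 6 UG (first base 5' of the
# second within the stem's outer-to-inner reading).
.PAIR_NAMES <- c("AU", "UA", "CG", "GC", "GU", "UG")

# .pairCode[a, b]: pair type of 5' base a with 3' base b (A,C,G,U/T
# encoded 1..4), 0 if not pairable.
.pairCode <- matrix(0L, 4, 4)
.pairCode[1, 4] <- 1L  # A-U
.pairCode[4, 1] <- 2L  # U-A
.pairCode[2, 3] <- 3L  # C-G
.pairCode[3, 2] <- 4L  # G-C
.pairCode[3, 4] <- 5L  # G-U
.pairCode[4, 3] <- 6L  # U-G

# .stackDG[outer, inner]: free energy of stacking the inner pair
# directly on the outer pair.
.stackDG <- matrix(c(
  # inner:  AU     UA     CG     GC     GU     UG      outer:
         -0.93, -1.10, -2.24, -2.08, -0.55, -1.36,   # AU
         -1.33, -0.93, -2.35, -2.11, -1.27, -1.00,   # UA
         -2.11, -2.08, -3.26, -2.36, -1.41, -2.11,   # CG
         -2.35, -2.24, -3.42, -3.26, -1.53, -2.51,   # GC
         -1.36, -1.00, -2.51, -2.11, -0.50,  1.29,   # GU
         -0.55, -1.27, -1.53, -1.41,  0.30, -0.50),  # UG
  nrow = 6, byrow = TRUE, dimnames = list(.PAIR_NAMES, .PAIR_NAMES))

# Hairpin-loop initiation by loop length (3..9); beyond 9 a Jacobson-
# Stockmayer logarithmic extrapolation at RT = 0.6163 kcal/mol is used.
.hairpinLoopDG <- c(5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4)

.loopPenalty <- function(len) {
  ifelse(len <= 9, .hairpinLoopDG[pmax(len, 3) - 2],
         .hairpinLoopDG[7] + 1.75 * 0.6163 * log(len / 9))
}

# Bulge initiation by bulge length (1..3); larger interruptions are not
# allowed in the stem model.
.bulgeDG <- c(3.8, 2.8, 3.2)

# Internal-loop initiation by total unpaired count (2..6, each side
# >= 1 and <= 3) plus a per-nt asymmetry penalty.
.internalDG <- c(1.0, 1.8, 2.0, 2.2, 2.5)
.internalAsym <- 0.6

# Transition cost from an outer pair to the next inner pair with a and
# b unpaired nucleotides on the 5' and 3' sides.
.transDG <- function(outer, inner, a, b) {
  if (a == 0L && b == 0L) return(.stackDG[outer, inner])
  if (a == 0L || b == 0L) return(.bulgeDG[a + b])
  .internalDG[a + b - 1L] + .internalAsym * abs(a - b)
}
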