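# Shared fixtures: the two study peptides and small builders.

CHMAP28_SEQ  <- "GRFKRFRKKLKRLWHKVGPFVGPILHY"  # 27-residue goat cathelicidin
MELITTIN_SEQ <- "GIGAVLKVLTTGLPALISWIKRKRQQ"   # bee-venom lytic control

chmap28  <- function(cterm = "free_acid") parsePeptide(CHMAP28_SEQ, cterm, "ChMAP-28")
melittin <- function() parsePeptide(MELITTIN_SEQ, name = "melittin")

# The worked toy pathway: one activator, one repressor, one half-activator,
# one unknown-role gene.
toyDB <- function() pathwayDB(list(toy = c(A = 1, B = -1, C = 0.5, D = 0)))
toyCNR <- c(A = 10, B = 10, C = 100, D = 5)

# Kinetic panels (percent dead over concentration x time).
necrosisPanel <- function() {
  p <- expand.grid(concentration = c(3, 6), time = c(1, 2, 4))
  p$dead <- c(62, 95, 63, 96, 64, 96)
  p
}
apoptosisPanel <- function() {
  p <- expand.grid(concentration = c(2, 4), time = c(1, 2, 4))
  p$dead <- c(10, 12, 40, 45, 80, 85)
  p
}

ctrlSamples <- function(n = 3) sprintf("ctrl_%d", seq_len(n))
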