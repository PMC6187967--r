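# Universal genetic code bookkeeping for the 61-sense-codon state space.
# Stop codons are excluded from the state space entirely.

.codon_cache <- new.env(parent = emptyenv())

#' Sense-codon table for the universal genetic code
#'
#' Internal lookup shared by the codon substitution model and the simulators:
#' the 61 sense codons (TCAG order within each position), their encoded amino
#' acids, their per-position nucleotides, and the 61 x 61 single-nucleotide
#' change classification used to fill the Goldman-Yang rate matrix.
#'
#' @return A list with elements `codons` (character 61), `aa` (character 61),
#'   `pos` (61 x 3 integer matrix of nucleotide indices into `nt`),
#'   `nt` (the four nucleotides), and `type` (61 x 61 integer matrix:
#'   0 = identical or multi-nucleotide change, 1 = synonymous transversion,
#'   2 = synonymous transition, 3 = non-synonymous transversion,
#'   4 = non-synonymous transition).
#' @keywords internal
codon_table <- function() {
  if (!is.null(.codon_cache$tab)) return(.codon_cache$tab)
  nt <- c("T", "C", "A", "G")
  grid <- expand.grid(p3 = nt, p2 = nt, p1 = nt, stringsAsFactors = FALSE)
  codons64 <- paste0(grid$p1, grid$p2, grid$p3)
  code <- Biostrings::GENETIC_CODE
  aa64 <- unname(code[codons64])
  sense <- aa64 != "*"
  codons <- codons64[sense]
  aa <- aa64[sense]
  pos <- cbind(match(substr(codons, 1, 1), nt),
               match(substr(codons, 2, 2), nt),
               match(substr(codons, 3, 3), nt))
  ns <- length(codons)  # 61
  # transitions: A<->G, C<->T (indices 3<->4 and 1<->2 in `nt`)
  is_ts <- function(a, b) (a + b) %in% c(3L, 7L)
  type <- matrix(0L, ns, ns)
  for (i in seq_len(ns - 1L)) {
    for (j in (i + 1L):ns) {
      diffpos <- which(pos[i, ] != pos[j, ])
      if (length(diffpos) != 1L) next
      ts <- is_ts(pos[i, diffpos], pos[j, diffpos])
      syn <- aa[i] == aa[j]
      t <- if (syn && !ts) 1L else if (syn && ts) 2L else if (!syn && !ts) 3L else 4L
      type[i, j] <- t
      type[j, i] <- t
    }
  }
  tab <- list(codons = codons, aa = aa, pos = pos, nt = nt, type = type)
  .codon_cache$tab <- tab
  tab
}

# map codon strings (uppercased, U -> T) to 1..61 state indices; anything that
# is not an unambiguous sense codon (gap, N, ...) becomes NA (fully missing),
# except stop codons which the caller must have screened out already.
codon_to_state <- function(codons) {
  tab <- codon_table()
  match(codons, tab$codons)
}
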