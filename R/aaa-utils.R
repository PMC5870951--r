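## shared sequence helpers (loaded first)

.STOPS <- c("TAA", "TAG", "TGA")

.revcomp <- function(s) {
  if (!nchar(s)) return(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

## standard genetic code, vectorized codon lookup; codons containing N (or
## any partial/ambiguous codon) translate to X
.translate_str <- function(s) {
  n3 <- nchar(s) %/% 3L * 3L
  if (n3 == 0L) return("")
  cod <- substring(s, seq.int(1L, n3, 3L), seq.int(3L, n3, 3L))
  aa <- unname(Biostrings::GENETIC_CODE[cod])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

## isoleucine and leucine are isobaric and indistinguishable by the MS
## workflow the database serves; all peptide matching folds I onto L
.il <- function(x) chartr("I", "L", toupper(x))

## the nine single-nucleotide substitutions of ATG
.NEAR_COGNATE <- c("CTG", "GTG", "TTG", "AAG", "ACG", "AGG",
                   "ATA", "ATC", "ATT")

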