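# a 701-bp contig whose SNP turns word_ref into word_alt (one mismatch),
# planting a recognition site present in exactly one allele
site_fixture <- function(word_ref, word_alt, seed = 1) {
  set.seed(seed)
  stopifnot(nchar(word_ref) == nchar(word_alt))
  d <- which(strsplit(word_ref, "")[[1]] != strsplit(word_alt, "")[[1]])
  stopifnot(length(d) == 1)
  left <- random_dna(340)
  seq <- paste0(left, word_ref, random_dna(701 - 340 - nchar(word_ref)))
  list(genome = c(tig = seq),
       snp = data.frame(chrom = "tig", pos = 340 + d,
                        ref = substring(word_ref, d, d),
                        alt = substring(word_alt, d, d)))
}
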