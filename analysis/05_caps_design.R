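#!/usr/bin/env Rscript
# Convert candidate SNPs into CAPS assays on a demonstration contig set:
# for each of the eight marker enzymes, a SNP is planted that destroys its
# recognition site in the alternate allele, flanks are extracted (300 bp
# each side), a differential enzyme and primer pair chosen, and per-allele
# fragment sizes predicted. A dCAPS design (primer-introduced mismatch) is
# demonstrated for a SNP with no natural differential enzyme.

suppressPackageStartupMessages(library(fleshmap))
dir.create("results", showWarnings = FALSE)

enzymes <- load_enzymes()
words <- list(XmnI = c("GAAGGGGTTC", "GACGGGGTTC"),
              HpyCH4V = c("TGCA", "TGGA"),
              NsiI = c("ATGCAT", "ATGAAT"),
              ScaI = c("AGTACT", "AGTCCT"),
              DraI = c("TTTAAA", "TTTCAA"),
              FokI = c("GGATG", "GGCTG"),
              MnlI = c("CCTC", "CATC"),
              TaqI = c("TCGA", "TAGA"))

random_dna <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

rows <- list()
set.seed(42)
for (nm in names(words)) {
  w <- words[[nm]]
  d <- which(strsplit(w[1], "")[[1]] != strsplit(w[2], "")[[1]])
  contig <- paste0(random_dna(340), w[1], random_dna(701 - 340 - nchar(w[1])))
  snp <- data.frame(chrom = paste0("amp_", nm), pos = 340 + d,
                    ref = substring(w[1], d, d),
                    alt = substring(w[2], d, d))
  genome <- setNames(contig, snp$chrom)
  fl <- extract_flanks(genome, snp)
  assays <- design_caps(fl, enzymes, tm_range = c(45, 65))
  for (a in assays) {
    rows[[length(rows) + 1]] <- data.frame(
      marker = a$marker_name, type = a$assay_type, enzyme = a$enzyme,
      snp = paste0(a$snp$ref, "/", a$snp$alt), snp_pos = a$snp$pos,
      forward = a$primers$forward$seq, reverse = a$primers$reverse$seq,
      product_bp = a$primers$product_size,
      fragments_ref = paste(a$fragments_ref, collapse = "+"),
      fragments_alt = paste(a$fragments_alt, collapse = "+"))
  }
}
assays_tab <- do.call(rbind, rows)
print(assays_tab[, c("marker", "type", "enzyme", "snp", "fragments_ref",
                     "fragments_alt")])
write.table(assays_tab, "results/caps_assays.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("designed", nrow(assays_tab), "CAPS assays\n")

# dCAPS fallback demonstration: C/G SNP with no natural differential site;
# one primer mismatch completes ScaI for the reference allele only
seq <- paste0(random_dna(345), "AGAACT", random_dna(350))
snp <- data.frame(chrom = "amp_dcaps", pos = 350, ref = "C", alt = "G")
fl <- extract_flanks(setNames(seq, "amp_dcaps"), snp)
if (nrow(differential_enzymes(fl, enzymes)) == 0) {
  dc <- design_dcaps(fl, enzymes, primer_3prime_window = 6,
                     tm_range = c(40, 65))
  cat("dCAPS designs found:", length(dc), "\n")
  if (length(dc)) print(dc[[1]])
}
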