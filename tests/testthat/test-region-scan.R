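test_that("window counts tile correctly and conserve totals", {
  sites <- data.frame(chrom = "chr2",
                      pos = round(seq(27600000, 27880000,
                                      length.out = 272)))
  wc <- window_counts(sites, 4e6)
  nz <- wc[wc$snp_count > 0, ]
  expect_equal(nrow(nz), 1)
  expect_equal(nz$window_start, 24000001)
  expect_equal(nz$window_end, 28000000)
  expect_equal(nz$snp_count, 272)
  expect_equal(sum(wc$snp_count), nrow(sites))
})

test_that("window boundaries follow the [k*w+1, (k+1)*w] convention", {
  sites <- data.frame(chrom = "c1", pos = c(4000000, 4000001))
  wc <- window_counts(sites, 4e6)
  expect_equal(wc$snp_count, c(1, 1))
  expect_equal(window_counts(data.frame(chrom = character(0),
                                        pos = numeric(0)))$snp_count,
               integer(0))
})

test_that("cluster detection recovers planted clusters and applies the
           threshold", {
  set.seed(9)
  mk <- function(chrom, lo, hi, n)
    data.frame(chrom = chrom, pos = sort(sample(lo:hi, n)))
  sites <- rbind(mk("chr2", 27600000, 27880000, 272),
                 mk("chr5", 27240000, 27250000, 3),
                 mk("chr9", 18290000, 18300000, 8))
  reg <- detect_clusters(sites, min_snps = 3)
  expect_equal(nrow(reg), 3)
  expect_equal(reg$snp_count, c(272, 3, 8))
  expect_equal(reg$start_bp,
               vapply(split(sites$pos, sites$chrom), min, numeric(1),
                      USE.NAMES = FALSE))
  reg4 <- detect_clusters(sites, min_snps = 4)
  expect_equal(nrow(reg4), 2)  # the 3-SNP cluster disappears
  expect_false("chr5" %in% reg4$chrom)
  empty <- detect_clusters(data.frame(chrom = character(0),
                                      pos = numeric(0)))
  expect_equal(nrow(empty), 0)
})

test_that("detected regions are disjoint, sorted and above threshold", {
  set.seed(10)
  sites <- data.frame(
    chrom = sample(c("c1", "c2"), 400, replace = TRUE),
    pos = sample.int(4e7, 400))
  reg <- detect_clusters(sites, min_snps = 3)
  if (nrow(reg) > 1) {
    same <- reg$chrom[-1] == reg$chrom[-nrow(reg)]
    expect_true(all(reg$start_bp[-1][same] > reg$end_bp[-nrow(reg)][same]))
  }
  expect_true(all(reg$snp_count >= 3))
})

test_that("effect classification handles the canonical codon examples", {
  fx <- gen_genome_fixture(2, seed = 41)
  # GGA>GGG at a third codon position is synonymous (both glycine)
  syn <- fx$snps[fx$snps$truth_effect == "synonymous", ][1, ]
  got <- classify_effect(syn, fx$genes, fx$genome)
  expect_equal(got$context, "exon")
  expect_equal(got$coding_effect, "synonymous")
  # GGG>GCG at a second position is non-synonymous (Gly -> Ala)
  non <- fx$snps[fx$snps$truth_effect == "non_synonymous", ][1, ]
  expect_equal(classify_effect(non, fx$genes, fx$genome)$coding_effect,
               "non_synonymous")
  inter <- fx$snps[fx$snps$truth_context == "intergenic", ][1, ]
  got <- classify_effect(inter, fx$genes, fx$genome)
  expect_equal(got$context, "intergenic")
  expect_equal(got$coding_effect, "not_applicable")
  expect_true(is.na(got$gene_id))
})

test_that("minus-strand SNPs are classified through the
           reverse-complemented codon", {
  fx <- gen_genome_fixture(4, seed = 42)
  minus_genes <- fx$genes$ID[fx$genes$type == "gene" &
                               fx$genes$strand == "-"]
  sub <- fx$snps[fx$snps$gene_id %in% minus_genes &
                   fx$snps$truth_effect != "not_applicable", ]
  expect_gt(nrow(sub), 0)
  for (i in seq_len(nrow(sub))) {
    expect_equal(classify_effect(sub[i, ], fx$genes,
                                 fx$genome)$coding_effect,
                 sub$truth_effect[i])
  }
})

test_that("effect classification agrees with full-protein translation
           diffing", {
  fx <- gen_genome_fixture(6, seed = 43)
  coding <- fx$snps[fx$snps$truth_effect != "not_applicable", ]
  for (i in seq_len(nrow(coding))) {
    expect_equal(
      classify_effect(coding[i, ], fx$genes, fx$genome)$coding_effect,
      oracle_protein_effect(coding[i, ], fx$genes, fx$genome))
  }
})

test_that("malformed gene models and ref mismatches raise errors", {
  fx <- gen_genome_fixture(2, seed = 44)
  broken <- fx$genes
  cds_row <- which(broken$type == "CDS")[1]
  broken$end[cds_row] <- broken$end[cds_row] + 1L  # CDS length % 3 != 0
  snp <- fx$snps[fx$snps$truth_effect == "synonymous" &
                   fx$snps$gene_id == "gene1", ][1, ]
  expect_error(classify_effect(snp, broken, fx$genome), "divisible by 3")
  bad_snp <- snp
  bad_snp$ref <- setdiff(c("A", "C", "G", "T"), snp$ref)[1]
  expect_error(classify_effect(bad_snp, fx$genes, fx$genome), "mismatch")
  # indels receive context only
  indel <- snp
  indel$alt <- paste0(indel$ref, "A")
  got <- classify_effect(indel, fx$genes, fx$genome)
  expect_equal(got$coding_effect, "not_applicable")
})
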