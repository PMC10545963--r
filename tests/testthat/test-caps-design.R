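test_that("flank extraction builds allele sequences differing only at the
           SNP", {
  set.seed(51)
  genome <- c(tig = random_dna(1200))
  pos <- 601
  snp <- data.frame(chrom = "tig", pos = pos,
                    ref = substring(genome, pos, pos),
                    alt = setdiff(c("A", "C", "G", "T"),
                                  substring(genome, pos, pos))[1])
  fl <- extract_flanks(genome, snp)
  expect_equal(nchar(fl$allele_ref), 601)
  expect_equal(fl$snp_index, 301)
  diffs <- which(strsplit(fl$allele_ref, "")[[1]] !=
                   strsplit(fl$allele_alt, "")[[1]])
  expect_equal(diffs, 301)
  # truncation near the contig edge warns
  snp5 <- data.frame(chrom = "tig", pos = 5,
                     ref = substring(genome, 5, 5),
                     alt = setdiff(c("A", "C", "G", "T"),
                                   substring(genome, 5, 5))[1])
  expect_warning(fl5 <- extract_flanks(genome, snp5), "truncated")
  expect_equal(nchar(fl5$upstream), 4)
  # ref mismatch is a data error
  bad <- snp; bad$ref <- setdiff(c("A", "C", "G", "T"), snp$ref)[1]
  expect_error(extract_flanks(genome, bad), "mismatch")
})

test_that("site finding matches simple literal expectations", {
  eco <- data.frame(name = "EcoRI", recognition = "GAATTC", cut_offset = 1)
  expect_equal(find_sites("AAGAATTCAA", eco), 3L)
  xmn <- data.frame(name = "XmnI", recognition = "GAANNNNTTC",
                    cut_offset = 5)
  expect_equal(find_sites("TTGAAGGGGTTCAA", xmn), 3L)
  # palindromic site reported once per position
  expect_equal(find_sites("AAGAATTCAAGAATTC", eco), c(3L, 11L))
})

test_that("site finding equals the naive both-strand IUPAC scanner", {
  enzymes <- load_enzymes()
  set.seed(52)
  for (rep in 1:60) {
    seq <- random_dna(600)
    for (i in seq_len(nrow(enzymes))) {
      expect_identical(find_sites(seq, enzymes[i, ]),
                       as.integer(naive_iupac_scan(
                         seq, enzymes$recognition[i])),
                       label = paste(enzymes$name[i], "rep", rep))
    }
  }
  # non-palindromic enzymes are found on the reverse strand too
  fok <- enzymes[enzymes$name == "FokI", ]
  expect_equal(find_sites("AAACATCCAAA", fok),
               as.integer(naive_iupac_scan("AAACATCCAAA", "GGATG")))
  expect_length(find_sites("AAACATCCAAA", fok), 1)
})

test_that("differential enzymes are exactly those whose SNP-spanning site
           exists in one allele", {
  enzymes <- load_enzymes()
  fx <- site_fixture("GAATTC", "GACTTC", seed = 53)
  fl <- extract_flanks(fx$genome, fx$snp)
  d <- differential_enzymes(fl, enzymes)
  expect_true("EcoRI" %in% d$name)
  expect_true(all(d$position <= fl$snp_index &
                    d$position + nchar(d$recognition) - 1 >= fl$snp_index))
  eco <- d[d$name == "EcoRI", ]
  expect_equal(eco$allele_with_site, "ref")
  # a SNP that changes no site in the table yields an empty result:
  # verify against a naive per-enzyme scan of both alleles
  set.seed(54)
  for (tries in 1:20) {
    genome <- c(tig = random_dna(700))
    ref <- substring(genome, 350, 350)
    snp <- data.frame(chrom = "tig", pos = 350, ref = ref,
                      alt = setdiff(c("A", "C", "G", "T"), ref)[1])
    fl2 <- extract_flanks(genome, snp)
    d2 <- differential_enzymes(fl2, enzymes)
    naive_any <- any(vapply(seq_len(nrow(enzymes)), function(i) {
      w <- nchar(enzymes$recognition[i])
      sr <- naive_iupac_scan(fl2$allele_ref, enzymes$recognition[i])
      sa <- naive_iupac_scan(fl2$allele_alt, enzymes$recognition[i])
      du <- union(setdiff(sr, sa), setdiff(sa, sr))
      any(du <= fl2$snp_index & du + w - 1 >= fl2$snp_index)
    }, logical(1)))
    expect_equal(nrow(d2) > 0, naive_any)
  }
})

test_that("fragment sizes always sum to the amplicon length", {
  eco <- data.frame(name = "EcoRI", recognition = "GAATTC", cut_offset = 1)
  amp <- paste0(strrep("A", 249), "GAATTC", strrep("C", 345))
  fr <- fragment_sizes(amp, eco)
  expect_equal(sum(fr), 600)
  expect_equal(fr, c(250L, 350L))
  expect_equal(fragment_sizes(random_dna(600),
                              data.frame(name = "x",
                                         recognition = "AAAAAAAAAAAA",
                                         cut_offset = 1)), 600L)
  # overlapping sites: two cuts, three fragments, sum conserved
  hpy <- data.frame(name = "HpyCH4V", recognition = "TGCA", cut_offset = 2)
  amp2 <- paste0(random_dna(100), "TGCATGCA", random_dna(92))
  fr2 <- fragment_sizes(amp2, hpy)
  expect_gte(length(fr2), 3)
  expect_equal(sum(fr2), 200)
})

test_that("CAPS design yields verifiably differential assays", {
  enzymes <- load_enzymes()
  fx <- site_fixture("GAATTC", "GACTTC", seed = 56)
  fl <- extract_flanks(fx$genome, fx$snp)
  assays <- design_caps(fl, enzymes)
  expect_gt(length(assays), 0)
  for (a in assays) {
    expect_false(identical(sort(a$fragments_ref), sort(a$fragments_alt)))
    expect_equal(sum(a$fragments_ref), nchar(a$amplicon_ref))
    expect_equal(sum(a$fragments_alt), nchar(a$amplicon_alt))
    expect_equal(a$assay_type, "CAPS")
    # primers bracket the SNP without overlapping it
    expect_lt(a$primers$forward$end, fl$snp_index)
    expect_gt(a$primers$reverse$start, fl$snp_index)
  }
})

test_that("primer picking is deterministic and honours constraints", {
  set.seed(57)
  genome <- c(tig = random_dna(1200))
  snp <- data.frame(chrom = "tig", pos = 601,
                    ref = substring(genome, 601, 601),
                    alt = setdiff(c("A", "C", "G", "T"),
                                  substring(genome, 601, 601))[1])
  fl <- extract_flanks(genome, snp)
  p1 <- pick_primers(fl)
  p2 <- pick_primers(fl)
  expect_identical(p1, p2)
  expect_false(is.null(p1))
  expect_lt(p1$forward$end, fl$snp_index)   # product contains the SNP
  expect_gt(p1$reverse$start, fl$snp_index)
  expect_true(p1$product_size >= 100 && p1$product_size <= 601)
  expect_true(all(c(p1$forward$tm, p1$reverse$tm) >= 55))
  expect_true(all(c(p1$forward$tm, p1$reverse$tm) <= 62))
  # impossible Tm range fails with a diagnostic
  expect_warning(bad <- pick_primers(fl, tm_range = c(90, 95)), "primer")
  expect_null(bad)
})

test_that("dCAPS search finds a designed single-mismatch assay and is the
           fallback only", {
  enzymes <- load_enzymes()
  # template carries AGAACT at 346-351 with the SNP C/G at 350: neither
  # allele has a site, but an A>T mismatch at 348 completes ScaI AGTACT
  # for the ref allele only (alt gives AGTAGT)
  set.seed(58)
  seq <- paste0(random_dna(345), "AGAACT", random_dna(350))
  genome <- c(tig = seq)
  snp <- data.frame(chrom = "tig", pos = 350, ref = "C", alt = "G")
  fl <- extract_flanks(genome, snp)
  nat <- differential_enzymes(fl, enzymes)
  if (nrow(nat) > 0) {
    expect_error(design_dcaps(fl, enzymes), "fallback")
  } else {
    # the anchored mismatch primer sits in an AT-rich stretch, so allow a
    # wider Tm band than the default for this fixture
    assays <- design_dcaps(fl, enzymes, primer_3prime_window = 6,
                           tm_range = c(40, 65))
    expect_true("ScaI" %in% vapply(assays, `[[`, character(1), "enzyme"))
    for (a in assays) {
      expect_equal(a$assay_type, "dCAPS")
      expect_false(is.null(a$introduced_mismatch))
      expect_lte(abs(a$introduced_mismatch$position - fl$snp_index), 6)
      expect_false(identical(sort(a$fragments_ref),
                             sort(a$fragments_alt)))
      expect_equal(sum(a$fragments_ref), nchar(a$amplicon_ref))
    }
    # window = 0 always yields nothing
    expect_length(design_dcaps(fl, enzymes, primer_3prime_window = 0,
                               tm_range = c(40, 65)), 0)
  }
})

test_that("dCAPS refuses when a natural differential enzyme exists", {
  enzymes <- load_enzymes()
  fx <- site_fixture("GAATTC", "GACTTC", seed = 59)
  fl <- extract_flanks(fx$genome, fx$snp)
  expect_error(design_dcaps(fl, enzymes), "fallback")
})
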