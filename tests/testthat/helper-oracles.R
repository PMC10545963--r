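# Independent oracles used to cross-check the implementation.

IUPAC_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L, R = 5L, Y = 10L, S = 6L,
                W = 9L, K = 12L, M = 3L, B = 14L, D = 13L, H = 11L,
                V = 7L, N = 15L)

iupac_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

scan_one_strand <- function(seq_mask, pat_mask) {
  L <- length(seq_mask)
  w <- length(pat_mask)
  if (w > L) return(integer(0))
  n <- L - w + 1
  ok <- rep(TRUE, n)
  for (k in seq_len(w)) {
    ok <- ok & bitwAnd(seq_mask[k:(n + k - 1)], pat_mask[k]) > 0L
  }
  which(ok)
}

# every-offset IUPAC scanner over both strands (bitmask per base)
naive_iupac_scan <- function(seq, recognition) {
  sm <- unname(IUPAC_MASK[strsplit(seq, "")[[1]]])
  fwd <- scan_one_strand(sm, unname(IUPAC_MASK[strsplit(recognition,
                                                        "")[[1]]]))
  rc <- iupac_revcomp(recognition)
  rev <- scan_one_strand(sm, unname(IUPAC_MASK[strsplit(rc, "")[[1]]]))
  sort(unique(c(fwd, rev)))
}

# direct definition of the diagnostic set: all three ICY lines share one
# homozygous class, all three CY lines share the other
brute_force_specific <- function(m) {
  icy <- names(m$groups)[m$groups %in% c("ICY-H", "ICY-L")]
  cy <- names(m$groups)[m$groups == "CY"]
  hom <- c("hom_ref", "hom_alt")
  hits <- vapply(seq_len(nrow(m$sites)), function(i) {
    a <- m$calls[i, icy]
    b <- m$calls[i, cy]
    all(a %in% hom) && length(unique(a)) == 1 &&
      all(b %in% hom) && length(unique(b)) == 1 && a[1] != b[1]
  }, logical(1))
  which(hits)
}

random_class_matrix <- function(seed, n_sites) {
  set.seed(seed)
  groups <- default_groups()
  classes <- c("hom_ref", "hom_alt", "het", "etc", "missing")
  calls <- matrix(sample(classes, n_sites * 6, replace = TRUE,
                         prob = c(0.4, 0.4, 0.08, 0.08, 0.04)),
                  n_sites, 6, dimnames = list(NULL, names(groups)))
  sites <- data.frame(chrom = "c1", pos = seq_len(n_sites),
                      ref = "A", alt = "G")
  genotype_matrix(sites, calls, groups)
}

# full-CDS substitution + translation diff for a coding SNP
oracle_protein_effect <- function(site, genes, genome) {
  gid <- genes$gene_id[genes$type == "CDS" & genes$seqid == site$chrom &
                         genes$start <= site$pos & genes$end >= site$pos][1]
  cds <- genes[genes$type == "CDS" & genes$gene_id == gid, ]
  cds <- cds[order(cds$start), ]
  protein <- function(g) {
    pieces <- substring(g[[site$chrom]], cds$start, cds$end)
    s <- paste(pieces, collapse = "")
    d <- Biostrings::DNAString(s)
    if (cds$strand[1] == "-") d <- Biostrings::reverseComplement(d)
    as.character(Biostrings::translate(d, no.init.codon = TRUE))
  }
  mut <- genome
  stopifnot(substring(mut[[site$chrom]], site$pos, site$pos) == site$ref)
  substring(mut[[site$chrom]], site$pos, site$pos) <- site$alt
  if (protein(genome) == protein(mut)) "synonymous" else "non_synonymous"
}

# F2 two-locus class probabilities by explicit gamete enumeration
enumerate_f2_probs <- function(r) {
  gam <- expand.grid(l1 = 0:1, l2 = 0:1)
  pg <- ifelse(gam$l1 == gam$l2, (1 - r) / 2, r / 2)
  probs <- matrix(0, 3, 3, dimnames = list(c("a", "h", "b"),
                                           c("a", "h", "b")))
  for (i in 1:4) {
    for (j in 1:4) {
      g1 <- gam[i, ]; g2 <- gam[j, ]
      cls <- function(x) c("a", "h", "b")[x + 1]
      probs[cls(g1$l1 + g2$l1), cls(g1$l2 + g2$l2)] <-
        probs[cls(g1$l1 + g2$l1), cls(g1$l2 + g2$l2)] + pg[i] * pg[j]
    }
  }
  probs
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
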