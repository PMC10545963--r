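#' Default six-line group scheme
#'
#' Two severely reddish incomplete-canary-yellow lines (ICY-H), one slightly
#' reddish line (ICY-L) and three canary-yellow lines (CY), named after the
#' resequenced inbreds.
#'
#' @return named character vector sample -> group.
#' @export
default_groups <- function() {
  c(PS186 = "ICY-H", PS189 = "ICY-H", PS187 = "ICY-L",
    PS188 = "CY", PS160 = "CY", PS190 = "CY")
}

#' Truth specification for a simulated resequencing panel
#'
#' Defaults emulate the study conditions: a 272-SNP diagnostic region at
#' 27.60--27.88 Mb on chromosome 2 plus two small clusters (3 SNPs at
#' 27.24--27.25 Mb on chromosome 5, 8 SNPs at 18.29--18.30 Mb on chromosome
#' 9), background variation at 1e-5 sites/bp, 2% missing calls and 30x mean
#' depth.
#'
#' @param diagnostic_region list with \code{chrom}, \code{start_bp},
#'   \code{end_bp}.
#' @param n_diagnostic_snps SNP count planted in the diagnostic region.
#' @param extra_regions list of further planted clusters, each a list with
#'   \code{chrom}, \code{start_bp}, \code{end_bp}, \code{n}.
#' @param background_snp_rate per-bp probability of a background variant
#'   site.
#' @param missing_rate fraction of calls with no reads, in \verb{[0, 1]}.
#' @param mean_depth mean sequencing depth per call (Poisson).
#' @param ambiguous_frac fraction of calls whose read rate is forced into
#'   the undistinguishable 0.6--0.9 band.
#' @param chrom_lengths named vector of simulated chromosome lengths (bp).
#' @param seed integer RNG seed; identical seeds reproduce identical panels.
#' @return list of class \code{panel_truth}.
#' @export
panel_truth <- function(
    diagnostic_region = list(chrom = "chr2", start_bp = 27600000,
                             end_bp = 27880000),
    n_diagnostic_snps = 272,
    extra_regions = list(
      list(chrom = "chr5", start_bp = 27240000, end_bp = 27250000, n = 3),
      list(chrom = "chr9", start_bp = 18290000, end_bp = 18300000, n = 8)),
    background_snp_rate = 1e-5,
    missing_rate = 0.02,
    mean_depth = 30,
    ambiguous_frac = 0,
    chrom_lengths = c(chr2 = 36e6, chr5 = 34e6, chr9 = 38e6),
    seed = 1) {
  stopifnot(diagnostic_region$start_bp < diagnostic_region$end_bp,
            n_diagnostic_snps >= 0,
            background_snp_rate >= 0, background_snp_rate <= 1,
            missing_rate >= 0, missing_rate <= 1,
            ambiguous_frac >= 0, ambiguous_frac <= 1,
            diagnostic_region$chrom %in% names(chrom_lengths))
  structure(list(diagnostic_region = diagnostic_region,
                 n_diagnostic_snps = n_diagnostic_snps,
                 extra_regions = extra_regions,
                 background_snp_rate = background_snp_rate,
                 missing_rate = missing_rate, mean_depth = mean_depth,
                 ambiguous_frac = ambiguous_frac,
                 chrom_lengths = chrom_lengths, seed = as.integer(seed)),
            class = "panel_truth")
}

sample_alleles <- function(n) {
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  list(ref = ref, alt = unname(alt))
}

#' Generate a resequencing-style genotype panel with planted truth
#'
#' Simulates six inbred lines in three groups. Inside each planted
#' diagnostic region every ICY line is homozygous for one allele and every
#' CY line for the other (orientation random per site). Background sites
#' are either shared cultivar-vs-reference differences (alternate allele in
#' all six lines) or private to a single line -- the two classes that
#' dominate real resequencing panels of related inbreds -- so at
#' \code{missing_rate = 0} the filtering cascade recovers exactly the
#' planted diagnostic set. Per-call read rates come from a depth model:
#' depth ~ Poisson(\code{mean_depth}), alt reads ~ Binomial(depth, p) with p
#' near 0/1 for homozygous truth; calls with no reads are missing, and each
#' line's true base is retained as the consensus used for imputation.
#'
#' @param truth a \code{\link{panel_truth}}.
#' @param groups named character vector sample -> group; all three groups
#'   must be non-empty.
#' @return object of class \code{reseq_panel}: \code{matrix}
#'   (\code{\link{genotype_matrix}} with consensus), \code{rates},
#'   \code{depths}, \code{alt_reads} (site x sample), and \code{truth}
#'   (the spec plus the planted site table with per-line true classes).
#' @export
gen_resequencing_panel <- function(truth = panel_truth(),
                                   groups = default_groups()) {
  stopifnot(inherits(truth, "panel_truth"))
  if (!all(GROUP_LEVELS %in% groups)) {
    stop("groups must assign at least one sample to each of ",
         paste(GROUP_LEVELS, collapse = ", "))
  }
  set.seed(truth$seed)
  samples <- names(groups)
  icy <- samples[groups %in% c("ICY-H", "ICY-L")]
  cy <- samples[groups == "CY"]

  regions <- c(list(c(truth$diagnostic_region,
                      n = truth$n_diagnostic_snps)), truth$extra_regions)
  site_list <- list()
  for (rg in regions) {
    if (rg$n == 0) next
    pos <- sort(sample(seq(rg$start_bp, rg$end_bp), rg$n))
    al <- sample_alleles(rg$n)
    site_list[[length(site_list) + 1]] <- data.frame(
      chrom = rg$chrom, pos = pos, ref = al$ref, alt = al$alt,
      kind = "diagnostic")
  }
  n_bg <- stats::rpois(1, truth$background_snp_rate *
                         sum(truth$chrom_lengths))
  if (n_bg > 0) {
    ch <- sample(names(truth$chrom_lengths), n_bg, replace = TRUE,
                 prob = truth$chrom_lengths)
    pos <- vapply(truth$chrom_lengths[ch], function(L)
      sample.int(L, 1), integer(1))
    al <- sample_alleles(n_bg)
    site_list[[length(site_list) + 1]] <- data.frame(
      chrom = ch, pos = pos, ref = al$ref, alt = al$alt,
      kind = sample(c("bg_shared", "bg_private"), n_bg, replace = TRUE,
                    prob = c(0.7, 0.3)))
  }
  sites <- do.call(rbind, site_list)
  if (is.null(sites)) {
    sites <- data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        kind = character(0))
  }
  sites <- sites[!duplicated(paste(sites$chrom, sites$pos)), , drop = FALSE]
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  n <- nrow(sites)

  # true genotype per line: TRUE = carries the alternate allele (homozygous)
  truth_alt <- matrix(FALSE, n, length(samples),
                      dimnames = list(NULL, samples))
  diag_rows <- which(sites$kind == "diagnostic")
  icy_gets_alt <- sample(c(TRUE, FALSE), length(diag_rows), replace = TRUE)
  truth_alt[diag_rows[icy_gets_alt], icy] <- TRUE
  truth_alt[diag_rows[!icy_gets_alt], cy] <- TRUE
  truth_alt[sites$kind == "bg_shared", ] <- TRUE
  priv_rows <- which(sites$kind == "bg_private")
  if (length(priv_rows)) {
    priv_line <- sample(samples, length(priv_rows), replace = TRUE)
    truth_alt[cbind(priv_rows, match(priv_line, samples))] <- TRUE
  }

  depths <- matrix(stats::rpois(n * length(samples), truth$mean_depth),
                   n, length(samples), dimnames = list(NULL, samples))
  depths[matrix(stats::runif(n * length(samples)) < truth$missing_rate,
                n, length(samples))] <- 0L
  p_alt <- ifelse(truth_alt, 0.998, 0.002)
  alt_reads <- matrix(stats::rbinom(n * length(samples), depths, p_alt),
                      n, length(samples), dimnames = list(NULL, samples))
  if (truth$ambiguous_frac > 0) {
    amb <- matrix(stats::runif(n * length(samples)) < truth$ambiguous_frac,
                  n, length(samples)) & depths > 0
    alt_reads[amb] <- stats::rbinom(sum(amb), depths[amb],
                                    stats::runif(sum(amb), 0.6, 0.9))
  }
  rates <- ifelse(depths > 0, alt_reads / depths, NA_real_)
  calls <- matrix(classify_read_rate(as.vector(rates)), n, length(samples),
                  dimnames = list(NULL, samples))
  consensus <- ifelse(truth_alt,
                      matrix(sites$alt, n, length(samples)),
                      matrix(sites$ref, n, length(samples)))
  dimnames(consensus) <- list(NULL, samples)
  m <- genotype_matrix(sites[, c("chrom", "pos", "ref", "alt")], calls,
                       groups, consensus = consensus)
  truth$sites <- cbind(sites, as.data.frame(truth_alt))
  structure(list(matrix = m, rates = rates, depths = depths,
                 alt_reads = alt_reads, truth = truth, groups = groups),
            class = "reseq_panel")
}

#' @export
print.reseq_panel <- function(x, ...) {
  cat("simulated resequencing panel:", nrow(x$matrix$sites), "sites,",
      sum(x$truth$sites$kind == "diagnostic"), "planted diagnostic\n")
  invisible(x)
}

#' Simulation specification for an F2 population
#'
#' Defaults emulate the mapping population: 135 plants, nine markers and a
#' completely dominant trait whose recessive class is the maternal ('a')
#' side.
#'
#' @param n_plants number of F2 individuals.
#' @param marker_positions_cm named, sorted, non-negative map positions of
#'   the markers (cM).
#' @param trait_position_cm map position of the trait locus (cM).
#' @param dominance \code{"a_recessive"} (maternal-homozygous class shows
#'   the recessive phenotype 'a', as for ICY) or \code{"b_recessive"}.
#' @param seed integer RNG seed.
#' @return list of class \code{f2_sim_spec}.
#' @export
f2_sim_spec <- function(n_plants = 135,
                        marker_positions_cm = c(
                          M1 = 0, M2 = 6.3, M3 = 6.3, M4 = 7.6, M5 = 7.9,
                          M6 = 8.7, M7 = 8.7, M8 = 8.7, M9 = 13.8),
                        trait_position_cm = 8.7,
                        dominance = c("a_recessive", "b_recessive"),
                        seed = 1) {
  dominance <- match.arg(dominance)
  stopifnot(n_plants >= 1, all(marker_positions_cm >= 0),
            !is.unsorted(marker_positions_cm), trait_position_cm >= 0)
  if (is.null(names(marker_positions_cm))) {
    names(marker_positions_cm) <- paste0("M", seq_along(marker_positions_cm))
  }
  structure(list(n_plants = as.integer(n_plants),
                 marker_positions_cm = marker_positions_cm,
                 trait_position_cm = trait_position_cm,
                 dominance = dominance, seed = as.integer(seed)),
            class = "f2_sim_spec")
}

#' Simulate an F2 population of a dominant single-locus trait
#'
#' Gametes are formed locus by locus along the map: the allele at the first
#' locus is drawn uniformly and successive loci recombine independently
#' with probability given by the Kosambi inverse of the cM gap (no
#' interference). Marker genotypes are coded a/h/b
#' (maternal-homozygous/heterozygous/paternal-homozygous) and the trait
#' phenotype a/b follows from the trait-locus genotype under complete
#' dominance.
#'
#' @param spec an \code{\link{f2_sim_spec}}.
#' @return data.frame: \code{plant_id}, one a/h/b column per marker, and
#'   \code{trait} (a/b); the trait-locus genotype is kept in attribute
#'   \code{"trait_genotype"}.
#' @export
gen_f2_population <- function(spec = f2_sim_spec()) {
  stopifnot(inherits(spec, "f2_sim_spec"))
  set.seed(spec$seed)
  loci_pos <- c(spec$marker_positions_cm,
                trait = spec$trait_position_cm)
  ord <- order(loci_pos)
  loci_pos <- loci_pos[ord]
  k <- length(loci_pos)
  r_gap <- kosambi_inverse(diff(loci_pos))
  gamete <- function() {
    g <- matrix(0L, spec$n_plants, k)
    g[, 1] <- stats::rbinom(spec$n_plants, 1, 0.5)
    for (j in seq_len(k - 1)) {
      swap <- stats::rbinom(spec$n_plants, 1, r_gap[j])
      g[, j + 1] <- (g[, j] + swap) %% 2L
    }
    g
  }
  geno <- gamete() + gamete()  # 0 = a (maternal hom), 1 = h, 2 = b
  colnames(geno) <- names(loci_pos)
  code <- c("a", "h", "b")
  out <- data.frame(plant_id = sprintf("F2_%03d", seq_len(spec$n_plants)))
  for (mk in names(spec$marker_positions_cm)) {
    out[[mk]] <- code[geno[, mk] + 1L]
  }
  tg <- code[geno[, "trait"] + 1L]
  out$trait <- if (spec$dominance == "a_recessive") {
    ifelse(tg == "a", "a", "b")  # only the recessive homozygote shows 'a'
  } else {
    ifelse(tg == "b", "b", "a")
  }
  attr(out, "trait_genotype") <- tg
  out
}

#' Generate a toy genome, gene models and planted SNPs with known effects
#'
#' Builds one contig with \code{n_genes} two-exon genes on alternating
#' strands. Each gene carries planted SNPs with truth labels covering every
#' annotation class: intergenic, 5'UTR exon, intron, two synonymous coding
#' changes (GGA>GGG, CTG>CTA) and two non-synonymous ones (GGG>GCG,
#' ATG>ACG), with minus-strand genes stored reverse-complemented in the
#' contig.
#'
#' @param n_genes number of genes (>= 0).
#' @param seed integer RNG seed.
#' @return list with \code{genome} (named character vector), \code{genes}
#'   (gene-model table in the \code{\link{read_gff3}} layout) and
#'   \code{snps} (data.frame with \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{truth_context}, \code{truth_effect},
#'   \code{gene_id}).
#' @export
gen_genome_fixture <- function(n_genes = 10, seed = 1) {
  stopifnot(n_genes >= 0)
  set.seed(seed)
  gap <- 120L; utr <- 6L
  exon1_cds <- 45L; intron <- 30L; exon2_cds <- 60L
  gene_len <- utr + exon1_cds + intron + exon2_cds
  total <- gap + n_genes * (gene_len + gap)
  genome_chars <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  chrom <- "tig1"
  genes <- list(); snps <- list()
  # planted codons: list(cds_codon_index, ref_codon, alt_sense_base,
  # base_offset_in_codon, effect)
  plants <- list(
    list(idx = 5L, codon = "GGA", alt = "G", off = 3L,
         effect = "synonymous"),
    list(idx = 10L, codon = "GGG", alt = "C", off = 2L,
         effect = "non_synonymous"),
    list(idx = 20L, codon = "CTG", alt = "A", off = 3L,
         effect = "synonymous"),
    list(idx = 25L, codon = "ATG", alt = "C", off = 2L,
         effect = "non_synonymous"))
  for (i in seq_len(n_genes)) {
    g0 <- gap + (i - 1L) * (gene_len + gap)  # base before the gene
    strand <- if (i %% 2 == 1) "+" else "-"
    gid <- paste0("gene", i); mid <- paste0("mRNA", i)
    if (strand == "+") {
      utr_start <- g0 + 1L
      cds1 <- c(g0 + utr + 1L, g0 + utr + exon1_cds)
      cds2 <- c(cds1[2] + intron + 1L, cds1[2] + intron + exon2_cds)
      exon1 <- c(utr_start, cds1[2]); exon2 <- cds2
      map_cds <- function(p) {  # sense CDS position -> genomic
        if (p <= exon1_cds) cds1[1] + p - 1L
        else cds2[1] + (p - exon1_cds) - 1L
      }
      sense_to_genome <- identity
    } else {
      # sense runs right-to-left: UTR at the genomic right end
      cds2 <- c(g0 + 1L, g0 + exon2_cds)           # 3' part of sense CDS
      cds1 <- c(cds2[2] + intron + 1L, cds2[2] + intron + exon1_cds)
      exon1 <- c(cds1[1], cds1[2] + utr); exon2 <- cds2
      utr_start <- cds1[2] + 1L
      map_cds <- function(p) {
        if (p <= exon1_cds) cds1[2] - p + 1L
        else cds2[2] - (p - exon1_cds) + 1L
      }
      sense_to_genome <- function(b) unname(complement_base(b))
    }
    for (pl in plants) {
      cpos <- (pl$idx - 1L) * 3L
      for (kk in 1:3) {
        gpos <- map_cds(cpos + kk)
        genome_chars[gpos] <- sense_to_genome(substring(pl$codon, kk, kk))
      }
      snp_g <- map_cds(cpos + pl$off)
      snps[[length(snps) + 1]] <- data.frame(
        chrom = chrom, pos = snp_g,
        ref = sense_to_genome(substring(pl$codon, pl$off, pl$off)),
        alt = sense_to_genome(pl$alt),
        truth_context = "exon", truth_effect = pl$effect, gene_id = gid)
    }
    intron_pos <- if (strand == "+") cds1[2] + intron %/% 2L else
      cds2[2] + intron %/% 2L
    inter_pos <- g0 - gap %/% 2L + 1L
    utr_pos <- utr_start + 2L
    for (extra in list(
      list(pos = intron_pos, ctx = "intron", gene = gid),
      list(pos = inter_pos, ctx = "intergenic", gene = NA_character_),
      list(pos = utr_pos, ctx = "exon_utr", gene = gid))) {
      ref <- genome_chars[extra$pos]
      snps[[length(snps) + 1]] <- data.frame(
        chrom = chrom, pos = extra$pos, ref = ref,
        alt = sample(setdiff(c("A", "C", "G", "T"), ref), 1),
        truth_context = extra$ctx, truth_effect = "not_applicable",
        gene_id = extra$gene)
    }
    gene_lo <- min(exon1[1], exon2[1]); gene_hi <- max(exon1[2], exon2[2])
    rows <- data.frame(
      seqid = chrom, source = "sim",
      type = c("gene", "mRNA", "exon", "exon", "CDS", "CDS"),
      start = c(gene_lo, gene_lo, exon1[1], exon2[1], cds1[1], cds2[1]),
      end = c(gene_hi, gene_hi, exon1[2], exon2[2], cds1[2], cds2[2]),
      score = ".", strand = strand, phase = ".",
      ID = c(gid, mid, paste0(mid, ".exon1"), paste0(mid, ".exon2"),
             paste0(mid, ".cds1"), paste0(mid, ".cds2")),
      Parent = c(NA, gid, mid, mid, mid, mid), gene_id = gid)
    genes[[length(genes) + 1]] <- rows
  }
  genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(seqid = character(0), source = character(0),
               type = character(0), start = integer(0), end = integer(0),
               score = character(0), strand = character(0),
               phase = character(0), ID = character(0),
               Parent = character(0), gene_id = character(0))
  snps <- if (length(snps)) do.call(rbind, snps) else NULL
  genome <- stats::setNames(paste(genome_chars, collapse = ""), chrom)
  rownames(genes) <- NULL
  if (!is.null(snps)) rownames(snps) <- NULL
  list(genome = genome, genes = genes, snps = snps)
}
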