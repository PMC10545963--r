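#' Count SNPs in non-overlapping genomic windows
#'
#' Tiles each chromosome into fixed-size windows (default 4 Mb, the scale at
#' which density clusters stand out against the genome background) and counts
#' the sites falling in each tile \verb{[k*w+1, (k+1)*w]}. Counts are
#' conserved: per chromosome they sum to the number of input sites.
#'
#' @param sites data.frame with columns \code{chrom} and \code{pos}
#'   (1-based).
#' @param window_size_bp window length in bp; default 4,000,000.
#' @param chrom_lengths optional named vector of chromosome lengths; when
#'   given, every tile up to the chromosome end is reported (zeros
#'   included), otherwise tiling stops at the last observed site.
#' @return data.frame with columns \code{chrom}, \code{window_start},
#'   \code{window_end}, \code{snp_count}.
#' @export
window_counts <- function(sites, window_size_bp = 4e6,
                          chrom_lengths = NULL) {
  stopifnot(window_size_bp > 0)
  w <- as.numeric(window_size_bp)
  chroms <- if (!is.null(chrom_lengths)) names(chrom_lengths) else
    sort(unique(as.character(sites$chrom)))
  out <- lapply(chroms, function(ch) {
    pos <- sites$pos[sites$chrom == ch]
    last <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else
      if (length(pos)) max(pos) else 0
    if (last == 0) return(NULL)
    n_tiles <- ceiling(last / w)
    k <- (pos - 1) %/% w
    cnt <- tabulate(k + 1, nbins = n_tiles)
    data.frame(chrom = ch,
               window_start = (seq_len(n_tiles) - 1) * w + 1,
               window_end = seq_len(n_tiles) * w,
               snp_count = cnt)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), window_start = numeric(0),
                      window_end = numeric(0), snp_count = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Detect candidate regions from window SNP density
#'
#' Merges maximal runs of adjacent windows whose counts reach
#' \code{min_snps}, then refines each merged run to the smallest interval
#' bounded by the minimum and maximum SNP position inside it. The default
#' \code{min_snps = 3} admits the smallest cluster scale of interest
#' (a 3-SNP cluster).
#'
#' @param sites data.frame with \code{chrom}, \code{pos}.
#' @param min_snps minimum SNP count for a window to seed a region.
#' @param window_size_bp window length in bp (default 4 Mb).
#' @return data.frame of candidate regions: \code{chrom}, \code{start_bp},
#'   \code{end_bp}, \code{snp_count}, sorted and disjoint.
#' @export
detect_clusters <- function(sites, min_snps = 3, window_size_bp = 4e6) {
  stopifnot(min_snps >= 1)
  wc <- window_counts(sites, window_size_bp)
  hot <- wc[wc$snp_count >= min_snps, , drop = FALSE]
  if (nrow(hot) == 0) {
    return(data.frame(chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), snp_count = integer(0)))
  }
  k <- hot$window_start %/% window_size_bp  # tile index
  run_break <- c(TRUE, !(hot$chrom[-1] == hot$chrom[-nrow(hot)] &
                           diff(k) == 1))
  run_id <- cumsum(run_break)
  out <- lapply(split(seq_len(nrow(hot)), run_id), function(i) {
    ch <- hot$chrom[i[1]]
    span_lo <- min(hot$window_start[i])
    span_hi <- max(hot$window_end[i])
    pos <- sites$pos[sites$chrom == ch & sites$pos >= span_lo &
                       sites$pos <= span_hi]
    data.frame(chrom = ch, start_bp = min(pos), end_bp = max(pos),
               snp_count = length(pos))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

complement_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]
}

translate_codon <- function(codon) {
  Biostrings::GENETIC_CODE[[codon]]
}

gene_cds <- function(genes, gene_id) {
  cds <- genes[genes$type == "CDS" & genes$gene_id == gene_id, , drop = FALSE]
  cds[order(cds$start), , drop = FALSE]
}

build_cds_seq <- function(cds, genome) {
  pieces <- substring(genome[[cds$seqid[1]]], cds$start, cds$end)
  if (cds$strand[1] == "-") {
    pieces <- rev(vapply(pieces, function(p)
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(p))),
      character(1)))
  }
  paste(pieces, collapse = "")
}

cds_coordinate <- function(cds, pos) {
  # 1-based position within the spliced CDS (sense orientation)
  if (cds$strand[1] == "+") {
    i <- which(cds$start <= pos & cds$end >= pos)
    sum(cds$end[cds$end < pos] - cds$start[cds$end < pos] + 1) +
      (pos - cds$start[i] + 1)
  } else {
    i <- which(cds$start <= pos & cds$end >= pos)
    sum(cds$end[cds$start > pos] - cds$start[cds$start > pos] + 1) +
      (cds$end[i] - pos + 1)
  }
}

#' Classify the genic context and coding effect of a SNP
#'
#' Locates a site against gene models: intergenic when outside all gene
#' spans, intron when inside a gene but outside its exons, exon otherwise.
#' For exonic sites inside a CDS, the reference and alternate codons are
#' compared after splicing (minus-strand genes are reverse-complemented) and
#' the effect is synonymous or non-synonymous under the standard genetic
#' code. Indels (multi-base alleles) receive context only.
#'
#' @param site one-row data.frame (or list) with \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}.
#' @param genes gene-model table from \code{\link{read_gff3}}.
#' @param genome named list/vector of chromosome sequences from
#'   \code{\link{read_fasta}}.
#' @return list with \code{context} (\code{"intergenic"}, \code{"intron"},
#'   \code{"exon"}), \code{coding_effect} (\code{"synonymous"},
#'   \code{"non_synonymous"}, \code{"not_applicable"}) and \code{gene_id}
#'   (\code{NA} if intergenic).
#' @export
classify_effect <- function(site, genes, genome) {
  chrom <- as.character(site$chrom)
  pos <- as.integer(site$pos)
  ref <- as.character(site$ref)
  alt <- as.character(site$alt)
  is_indel <- nchar(ref) > 1 || nchar(alt) > 1
  g <- genes[genes$type == "gene" & genes$seqid == chrom &
               genes$start <= pos & genes$end >= pos, , drop = FALSE]
  if (nrow(g) == 0) {
    return(list(context = "intergenic", coding_effect = "not_applicable",
                gene_id = NA_character_))
  }
  gid <- g$ID[1]
  feats <- genes[genes$gene_id == gid & genes$seqid == chrom, , drop = FALSE]
  in_exon <- any(feats$type == "exon" & feats$start <= pos & feats$end >= pos)
  in_cds <- any(feats$type == "CDS" & feats$start <= pos & feats$end >= pos)
  if (!in_exon && !in_cds) {
    return(list(context = "intron", coding_effect = "not_applicable",
                gene_id = gid))
  }
  if (!in_cds || is_indel) {
    return(list(context = "exon", coding_effect = "not_applicable",
                gene_id = gid))
  }
  cds <- gene_cds(genes, gid)
  total_len <- sum(cds$end - cds$start + 1)
  if (total_len %% 3 != 0) {
    stop("CDS length of gene ", gid, " not divisible by 3")
  }
  genome_base <- substring(genome[[chrom]], pos, pos)
  if (genome_base != ref) {
    stop("reference allele mismatch at ", chrom, ":", pos,
         " (genome ", genome_base, ", site ", ref, ")")
  }
  cds_seq <- build_cds_seq(cds, genome)
  cpos <- cds_coordinate(cds, pos)
  alt_sense <- if (cds$strand[1] == "-") complement_base(alt) else alt
  codon_idx <- (cpos - 1) %/% 3
  off <- (cpos - 1) %% 3 + 1
  ref_codon <- substring(cds_seq, 3 * codon_idx + 1, 3 * codon_idx + 3)
  alt_codon <- ref_codon
  substring(alt_codon, off, off) <- alt_sense
  eff <- if (translate_codon(ref_codon) == translate_codon(alt_codon))
    "synonymous" else "non_synonymous"
  list(context = "exon", coding_effect = eff, gene_id = gid)
}

#' Annotate a table of SNPs against gene models
#'
#' Vectorised driver over \code{\link{classify_effect}}.
#'
#' @param sites data.frame with \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}.
#' @inheritParams classify_effect
#' @return the input with \code{context}, \code{coding_effect} and
#'   \code{gene_id} columns appended.
#' @export
classify_effects <- function(sites, genes, genome) {
  res <- lapply(seq_len(nrow(sites)), function(i)
    classify_effect(sites[i, ], genes, genome))
  sites$context <- vapply(res, `[[`, character(1), "context")
  sites$coding_effect <- vapply(res, `[[`, character(1), "coding_effect")
  sites$gene_id <- vapply(res, `[[`, character(1), "gene_id")
  sites
}
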