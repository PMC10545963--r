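#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF v4.x (via \pkg{vcfR}), keeps biallelic SNP records (others
#' are dropped with a message giving the count), and classifies each
#' sample's call from the alt-supporting read fraction computed from the AD
#' field when present (\code{\link{classify_read_rate}}); records without AD
#' fall back to the GT field. Positions are 1-based; sample order is
#' preserved.
#'
#' @param path VCF file (plain text).
#' @param groups named character vector (sample -> group) or path to a
#'   two-column \code{sample<TAB>group} TSV.
#' @return a \code{\link{genotype_matrix}}.
#' @export
read_vcf <- function(path, groups) {
  if (is.character(groups) && length(groups) == 1 && file.exists(groups)) {
    groups <- read_groups(groups)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  samples <- colnames(vcf@gt)[-1]
  if (nrow(fix) == 0) {
    calls <- matrix(character(0), 0, length(samples),
                    dimnames = list(NULL, samples))
    return(genotype_matrix(
      data.frame(chrom = character(0), pos = integer(0),
                 ref = character(0), alt = character(0)),
      calls, groups))
  }
  keep <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  keep[is.na(keep)] <- FALSE
  if (any(!keep)) {
    message("dropped ", sum(!keep), " non-biallelic/non-SNP record(s)")
  }
  sites <- data.frame(chrom = fix$CHROM[keep],
                      pos = as.integer(fix$POS[keep]),
                      ref = fix$REF[keep], alt = fix$ALT[keep])
  ad <- vcfR::extract.gt(vcf, element = "AD")[keep, , drop = FALSE]
  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  calls <- matrix("missing", nrow(sites), length(samples),
                  dimnames = list(NULL, samples))
  for (s in samples) {
    has_ad <- !is.na(ad[, s]) & ad[, s] != "." & ad[, s] != ""
    if (any(has_ad)) {
      parts <- strsplit(ad[has_ad, s], ",", fixed = TRUE)
      refn <- as.numeric(vapply(parts, `[`, character(1), 1))
      altn <- as.numeric(vapply(parts, `[`, character(1), 2))
      tot <- refn + altn
      rate <- ifelse(tot > 0, altn / tot, NA_real_)
      calls[has_ad, s] <- classify_read_rate(rate)
    }
    fallback <- !has_ad & !is.na(gt[, s])
    if (any(fallback)) {
      g <- gsub("|", "/", gt[fallback, s], fixed = TRUE)
      calls[fallback, s] <- ifelse(
        g %in% c("0/0"), "hom_ref",
        ifelse(g %in% c("1/1"), "hom_alt",
               ifelse(g %in% c("0/1", "1/0"), "het", "missing")))
    }
  }
  genotype_matrix(sites, calls, groups)
}

#' Read a sample-to-group assignment TSV
#'
#' @param path two-column TSV \code{sample<TAB>group}, no header.
#' @return named character vector sample -> group.
#' @export
read_groups <- function(path) {
  tab <- utils::read.delim(path, header = FALSE,
                           col.names = c("sample", "group"),
                           stringsAsFactors = FALSE)
  stats::setNames(tab$group, tab$sample)
}

gt_string <- function(class) {
  c(hom_ref = "0/0", hom_alt = "1/1", het = "0/1",
    etc = "./.", missing = "./.")[class]
}

#' Write a simulated resequencing panel as VCF v4.2
#'
#' Emits GT and AD per sample from the panel's simulated read counts;
#' missing calls carry \code{./.} with no AD. Output is deterministic text,
#' so identical panels write byte-identical files.
#'
#' @param panel a \code{reseq_panel} from
#'   \code{\link{gen_resequencing_panel}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "reseq_panel"))
  m <- panel$matrix
  samples <- colnames(m$calls)
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>",
            names(panel$truth$chrom_lengths),
            as.integer(panel$truth$chrom_lengths)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,Description=",
           "\"Allelic depths (ref,alt)\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  n <- nrow(m$sites)
  body <- character(n)
  for (i in seq_len(n)) {
    cells <- vapply(samples, function(s) {
      d <- panel$depths[i, s]
      if (d == 0) return("./.:.")
      a <- panel$alt_reads[i, s]
      paste0(gt_string(m$calls[i, s]), ":", d - a, ",", a)
    }, character(1))
    body[i] <- paste(c(m$sites$chrom[i], m$sites$pos[i], ".",
                       m$sites$ref[i], m$sites$alt[i], ".", "PASS", ".",
                       "GT:AD", cells), collapse = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector or list of sequences.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(seqs)), path)
  invisible(path)
}

#' Read GFF3 gene models
#'
#' Minimal strict GFF3 reader for gene/mRNA/exon/CDS rows: 1-based
#' inclusive coordinates, attributes parsed for ID and Parent, and every
#' feature resolved to its owning gene by walking the Parent chain.
#'
#' @param path GFF3 file.
#' @param contig_lengths optional named vector; features beyond a contig
#'   end raise an error.
#' @return data.frame with columns \code{seqid}, \code{source},
#'   \code{type}, \code{start}, \code{end}, \code{score}, \code{strand},
#'   \code{phase}, \code{ID}, \code{Parent}, \code{gene_id}.
#' @export
read_gff3 <- function(path, contig_lengths = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(seqid = character(0), source = character(0),
                      type = character(0), start = integer(0),
                      end = integer(0), score = character(0),
                      strand = character(0), phase = character(0),
                      ID = character(0), Parent = character(0),
                      gene_id = character(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 9)
  if (length(bad)) stop("malformed GFF3 line ", bad[1])
  f <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(f) <- c("seqid", "source", "type", "start", "end", "score",
                "strand", "phase", "attributes")
  f$start <- as.integer(f$start)
  f$end <- as.integer(f$end)
  attr_field <- function(attrs, key) {
    vapply(strsplit(attrs, ";", fixed = TRUE), function(kv) {
      hit <- kv[startsWith(kv, paste0(key, "="))]
      if (length(hit)) sub("^[^=]*=", "", hit[1]) else NA_character_
    }, character(1))
  }
  f$ID <- attr_field(f$attributes, "ID")
  f$Parent <- attr_field(f$attributes, "Parent")
  parent_of <- stats::setNames(f$Parent, f$ID)
  type_of <- stats::setNames(f$type, f$ID)
  resolve_gene <- function(id, parent) {
    cur <- if (!is.na(id) && !is.na(type_of[id]) && type_of[id] == "gene")
      id else parent
    steps <- 0
    while (!is.na(cur) && !is.na(type_of[cur]) && type_of[cur] != "gene" &&
           steps < 10) {
      cur <- parent_of[cur]
      steps <- steps + 1
    }
    unname(cur)
  }
  f$gene_id <- mapply(resolve_gene, f$ID, f$Parent, USE.NAMES = FALSE)
  if (!is.null(contig_lengths)) {
    over <- f$end > contig_lengths[f$seqid]
    if (any(over, na.rm = TRUE)) {
      stop("feature beyond contig end at line ", which(over)[1])
    }
  }
  f$attributes <- NULL
  f
}

#' Write gene models as GFF3
#'
#' @param features data.frame in the \code{\link{read_gff3}} layout.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_gff3 <- function(features, path) {
  attrs <- paste0("ID=", features$ID,
                  ifelse(is.na(features$Parent), "",
                         paste0(";Parent=", features$Parent)))
  lines <- paste(features$seqid, features$source, features$type,
                 features$start, features$end, features$score,
                 features$strand, features$phase, attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Convert 1-based inclusive regions to BED (0-based half-open)
#'
#' All 0/1-based coordinate arithmetic in the package is centralised here.
#'
#' @param regions data.frame with \code{chrom}, and either
#'   \code{start_bp}/\code{end_bp} or \code{pos} (single-base features).
#' @return data.frame with \code{chrom}, \code{start}, \code{end} in BED
#'   convention.
#' @export
to_bed <- function(regions) {
  if ("pos" %in% names(regions) && !"start_bp" %in% names(regions)) {
    data.frame(chrom = regions$chrom, start = regions$pos - 1,
               end = regions$pos)
  } else {
    data.frame(chrom = regions$chrom, start = regions$start_bp - 1,
               end = regions$end_bp)
  }
}

#' Write regions as BED text
#'
#' @param regions data.frame accepted by \code{\link{to_bed}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(regions, path) {
  bed <- to_bed(regions)
  writeLines(paste(bed$chrom, format(bed$start, scientific = FALSE,
                                     trim = TRUE),
                   format(bed$end, scientific = FALSE, trim = TRUE),
                   sep = "\t"), path)
  invisible(path)
}
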