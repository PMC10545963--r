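#' Load a restriction-enzyme table
#'
#' Reads a TSV of enzymes with IUPAC-degenerate recognition sequences and a
#' top-strand cut offset (bases after the match start at which cleavage
#' occurs). The packaged table covers the enzymes used for the flesh-colour
#' CAPS markers (XmnI, HpyCH4V, NsiI, ScaI, DraI, FokI, MnlI, TaqI) plus
#' EcoRI; Type IIS enzymes (FokI, MnlI) cut downstream of their recognition
#' site, which the offset encodes.
#'
#' @param path TSV with columns \code{name}, \code{recognition},
#'   \code{cut_offset}; defaults to the packaged table.
#' @return data.frame of enzymes.
#' @export
load_enzymes <- function(path = system.file("extdata", "enzymes.tsv",
                                            package = "fleshmap")) {
  enz <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "recognition", "cut_offset") %in% names(enz)))
  if (any(nchar(enz$recognition) == 0)) stop("empty recognition sequence")
  enz
}

#' Extract the flanking sequence pair around a SNP
#'
#' Pulls \code{flank_bp} bases on each side of the SNP (600 bp of context
#' for a 300-bp flank) and builds the two allele sequences, which differ at
#' exactly the SNP base; a full-length pair is \code{2*flank_bp + 1} long.
#' Flanks are truncated with a warning near contig edges.
#'
#' @param genome named list/vector of contig sequences
#'   (\code{\link{read_fasta}}).
#' @param snp one-row data.frame or list with \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}.
#' @param flank_bp flank length on each side (default 300).
#' @return list of class \code{flank_pair}: \code{snp}, \code{upstream},
#'   \code{downstream}, \code{allele_ref}, \code{allele_alt},
#'   \code{snp_index} (1-based SNP offset within the allele sequences).
#' @export
extract_flanks <- function(genome, snp, flank_bp = 300) {
  chrom <- as.character(snp$chrom)
  pos <- as.integer(snp$pos)
  seq <- genome[[chrom]]
  if (is.null(seq)) stop("contig not in genome: ", chrom)
  L <- nchar(seq)
  if (pos < 1 || pos > L) stop("SNP position outside contig ", chrom)
  base <- substring(seq, pos, pos)
  if (base != snp$ref) {
    stop("reference allele mismatch at ", chrom, ":", pos,
         " (genome ", base, ", site ", snp$ref, ")")
  }
  lo <- max(1, pos - flank_bp)
  hi <- min(L, pos + flank_bp)
  if (lo > pos - flank_bp || hi < pos + flank_bp) {
    warning("flank truncated at contig edge for ", chrom, ":", pos)
  }
  up <- substring(seq, lo, pos - 1)
  down <- substring(seq, pos + 1, hi)
  structure(list(
    snp = list(chrom = chrom, pos = pos, ref = as.character(snp$ref),
               alt = as.character(snp$alt)),
    upstream = up, downstream = down,
    allele_ref = paste0(up, snp$ref, down),
    allele_alt = paste0(up, snp$alt, down),
    snp_index = nchar(up) + 1L), class = "flank_pair")
}

#' Find restriction-enzyme recognition sites in a sequence
#'
#' Reports every 1-based position (forward-strand coordinates) at which the
#' enzyme's IUPAC-degenerate recognition sequence matches the sequence on
#' either strand: forward matches of the pattern plus matches of its reverse
#' complement (relevant for non-palindromic enzymes). Palindromic sites are
#' reported once per position; overlapping matches are all reported.
#'
#' @param seq character string over A/C/G/T.
#' @param enzyme one-row data.frame or list with \code{recognition} (and
#'   \code{name}, \code{cut_offset}).
#' @return sorted integer vector of match start positions.
#' @export
find_sites <- function(seq, enzyme) {
  subj <- Biostrings::DNAString(seq)
  pat <- Biostrings::DNAString(toupper(enzyme$recognition))
  hits <- Biostrings::start(Biostrings::matchPattern(pat, subj,
                                                     fixed = FALSE))
  rc <- Biostrings::reverseComplement(pat)
  if (as.character(rc) != as.character(pat)) {
    hits <- c(hits, Biostrings::start(
      Biostrings::matchPattern(rc, subj, fixed = FALSE)))
  }
  sort(unique(as.integer(hits)))
}

site_covers_snp <- function(positions, snp_index, width) {
  positions[positions <= snp_index & positions + width - 1 >= snp_index]
}

#' Enzymes that cut exactly one allele at a SNP
#'
#' Scans both allele sequences of a flank pair with every enzyme in the
#' table and keeps enzymes whose match-position sets differ between the
#' alleles; only differential matches whose recognition footprint overlaps
#' the SNP are causal, and only those are returned.
#'
#' @param flanks a \code{flank_pair} from \code{\link{extract_flanks}}.
#' @param enzymes enzyme table (\code{\link{load_enzymes}}).
#' @return data.frame with one row per causal differential match:
#'   \code{name}, \code{recognition}, \code{cut_offset}, \code{position},
#'   \code{allele_with_site} (\code{"ref"} or \code{"alt"}).
#' @export
differential_enzymes <- function(flanks, enzymes) {
  stopifnot(inherits(flanks, "flank_pair"))
  out <- list()
  for (i in seq_len(nrow(enzymes))) {
    e <- enzymes[i, ]
    w <- nchar(e$recognition)
    sr <- find_sites(flanks$allele_ref, e)
    sa <- find_sites(flanks$allele_alt, e)
    ref_only <- site_covers_snp(setdiff(sr, sa), flanks$snp_index, w)
    alt_only <- site_covers_snp(setdiff(sa, sr), flanks$snp_index, w)
    if (length(ref_only)) {
      out[[length(out) + 1]] <- data.frame(
        name = e$name, recognition = e$recognition,
        cut_offset = e$cut_offset, position = ref_only,
        allele_with_site = "ref")
    }
    if (length(alt_only)) {
      out[[length(out) + 1]] <- data.frame(
        name = e$name, recognition = e$recognition,
        cut_offset = e$cut_offset, position = alt_only,
        allele_with_site = "alt")
    }
  }
  if (length(out) == 0) {
    return(data.frame(name = character(0), recognition = character(0),
                      cut_offset = integer(0), position = integer(0),
                      allele_with_site = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Predicted restriction-fragment sizes of an amplicon
#'
#' Cuts the amplicon at every recognition match (both strands) at the
#' enzyme's cut offset from the match start and returns the ordered fragment
#' lengths. Lengths always sum to the amplicon length; with no match the
#' amplicon is returned whole.
#'
#' @param amplicon character string over A/C/G/T.
#' @param enzyme one-row enzyme record with \code{recognition} and
#'   \code{cut_offset}.
#' @return integer vector of fragment lengths (5' to 3').
#' @export
fragment_sizes <- function(amplicon, enzyme) {
  L <- nchar(amplicon)
  pos <- find_sites(amplicon, enzyme)
  cuts <- pos - 1L + as.integer(enzyme$cut_offset)
  cuts <- sort(unique(cuts[cuts > 0 & cuts < L]))
  as.integer(diff(c(0L, cuts, L)))
}

primer_tm <- function(seq) {
  n <- nchar(seq)
  gc <- nchar(gsub("[AT]", "", seq))
  64.9 + 41 * (gc - 16.4) / n
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

forward_candidates <- function(seq, max_end, len_range, tm_range,
                               min_start = 1L) {
  out <- list()
  for (s in seq(min_start, max_end)) {
    for (l in seq(len_range[1], len_range[2])) {
      e <- s + l - 1
      if (e > max_end) next
      p <- substring(seq, s, e)
      tm <- primer_tm(p)
      if (tm >= tm_range[1] && tm <= tm_range[2]) {
        out[[length(out) + 1]] <- list(seq = p, start = s, end = e, tm = tm)
      }
    }
  }
  out
}

#' Pick a deterministic primer pair bracketing a SNP
#'
#' A simple length/GC/Tm picker: scans candidate primers of
#' \code{len_range} length whose Tm (by the formula
#' \eqn{64.9 + 41 (GC - 16.4)/N}) lies in \code{tm_range}, rejects primers
#' overlapping the SNP, and requires the product to contain the SNP with a
#' size inside \code{product_range}. Tie-breaking is leftmost start, then
#' shortest, then smallest Tm distance to the range midpoint, so the choice
#' is deterministic.
#'
#' @param flanks a \code{flank_pair}.
#' @param product_range allowed amplicon length (bp), default
#'   \code{c(100, 601)}.
#' @param len_range primer length range, default 18--25.
#' @param tm_range primer melting-temperature range (deg C), default 55--62.
#' @param seq optional sequence to design on (defaults to the reference
#'   allele sequence; used internally for dCAPS mismatch templates).
#' @return list with \code{forward}, \code{reverse} (each \code{seq},
#'   \code{start}, \code{end}, \code{tm} in template coordinates) and
#'   \code{product_size}; \code{NULL} with a warning when no pair satisfies
#'   the constraints.
#' @export
pick_primers <- function(flanks, product_range = c(100, 601),
                         len_range = c(18, 25), tm_range = c(55, 62),
                         seq = NULL) {
  stopifnot(inherits(flanks, "flank_pair"))
  if (is.null(seq)) seq <- flanks$allele_ref
  L <- nchar(seq)
  si <- flanks$snp_index
  mid <- mean(tm_range)
  fwd <- forward_candidates(seq, si - 1L, len_range, tm_range)
  if (length(fwd) == 0) {
    warning("no forward primer satisfies the length/Tm constraints")
    return(NULL)
  }
  ord <- order(vapply(fwd, `[[`, numeric(1), "start"),
               vapply(fwd, function(x) x$end - x$start, numeric(1)),
               abs(vapply(fwd, `[[`, numeric(1), "tm") - mid))
  for (f in fwd[ord]) {
    best <- NULL
    for (e in seq(si + 1L, L)) {
      for (l in seq(len_range[1], len_range[2])) {
        s <- e - l + 1
        if (s <= si) next
        prod <- e - f$start + 1
        if (prod < product_range[1] || prod > product_range[2]) next
        p <- substring(seq, s, e)
        tm <- primer_tm(p)
        if (tm < tm_range[1] || tm > tm_range[2]) next
        cand <- list(seq = revcomp(p), start = s, end = e, tm = tm)
        if (is.null(best)) best <- cand
      }
      if (!is.null(best)) break
    }
    if (!is.null(best)) {
      return(list(forward = f, reverse = best,
                  product_size = best$end - f$start + 1))
    }
  }
  warning("no primer pair satisfies the product-size constraints")
  NULL
}

make_assay <- function(flanks, enzyme_row, primers, assay_type,
                       introduced_mismatch = NULL,
                       template_ref = NULL, template_alt = NULL) {
  if (is.null(template_ref)) template_ref <- flanks$allele_ref
  if (is.null(template_alt)) template_alt <- flanks$allele_alt
  f <- primers$forward$start
  r <- primers$reverse$end
  amp_ref <- substring(template_ref, f, r)
  amp_alt <- substring(template_alt, f, r)
  fr <- fragment_sizes(amp_ref, enzyme_row)
  fa <- fragment_sizes(amp_alt, enzyme_row)
  if (identical(sort(fr), sort(fa))) return(NULL)  # not differential
  structure(list(
    marker_name = paste0(flanks$snp$chrom, "_", flanks$snp$pos),
    snp = flanks$snp, assay_type = assay_type,
    enzyme = enzyme_row$name, recognition = enzyme_row$recognition,
    primers = primers, introduced_mismatch = introduced_mismatch,
    amplicon_ref = amp_ref, amplicon_alt = amp_alt,
    fragments_ref = fr, fragments_alt = fa), class = "caps_assay")
}

#' Design CAPS assays for a SNP with naturally differential enzymes
#'
#' For every enzyme that cuts exactly one allele at the SNP
#' (\code{\link{differential_enzymes}}), picks a primer pair bracketing the
#' SNP and predicts per-allele fragment sizes; assays whose two allele
#' amplicons digest identically are discarded.
#'
#' @inheritParams pick_primers
#' @param enzymes enzyme table.
#' @return list of \code{caps_assay} objects (possibly empty).
#' @export
design_caps <- function(flanks, enzymes, product_range = c(100, 601),
                        len_range = c(18, 25), tm_range = c(55, 62)) {
  diff <- differential_enzymes(flanks, enzymes)
  if (nrow(diff) == 0) return(list())
  primers <- pick_primers(flanks, product_range, len_range, tm_range)
  if (is.null(primers)) return(list())
  out <- list()
  for (i in seq_len(nrow(diff))) {
    a <- make_assay(flanks, diff[i, ], primers, "CAPS")
    if (!is.null(a)) out[[length(out) + 1]] <- a
  }
  out
}

#' Design dCAPS assays by introducing a primer mismatch
#'
#' Fallback when no enzyme naturally differentiates the alleles: searches
#' single-base substitutions within \code{primer_3prime_window} bases on
#' either side of the SNP such that the modified template plus one allele
#' completes a recognition site overlapping the SNP for exactly one allele.
#' The mismatch is carried by the primer whose 3' end abuts the SNP, and the
#' assay records it. Candidates are enumerated deterministically (distance
#' from the SNP, upstream before downstream, base A<C<G<T, enzyme table
#' order).
#'
#' @inheritParams design_caps
#' @param primer_3prime_window how far from the SNP (bp) a mismatch may be
#'   introduced; it must fit inside the mismatch primer. Default 12.
#' @return list of validated \code{caps_assay} objects with
#'   \code{assay_type = "dCAPS"}; empty when no design exists.
#' @export
design_dcaps <- function(flanks, enzymes, primer_3prime_window = 12,
                         product_range = c(100, 601),
                         len_range = c(18, 25), tm_range = c(55, 62)) {
  stopifnot(inherits(flanks, "flank_pair"))
  if (primer_3prime_window <= 0) return(list())
  natural <- differential_enzymes(flanks, enzymes)
  if (nrow(natural) > 0) {
    stop("SNP already has a naturally differential enzyme (",
         paste(unique(natural$name), collapse = ", "),
         "); dCAPS is the fallback for SNPs without one")
  }
  si <- flanks$snp_index
  L <- nchar(flanks$allele_ref)
  out <- list()
  for (d in seq_len(primer_3prime_window)) {
    for (p in c(si - d, si + d)) {
      if (p < 1 || p > L) next
      cur <- substring(flanks$allele_ref, p, p)
      for (b in setdiff(c("A", "C", "G", "T"), cur)) {
        mod_ref <- flanks$allele_ref
        substring(mod_ref, p, p) <- b
        mod_alt <- flanks$allele_alt
        substring(mod_alt, p, p) <- b
        for (i in seq_len(nrow(enzymes))) {
          e <- enzymes[i, ]
          w <- nchar(e$recognition)
          sr <- site_covers_snp(find_sites(mod_ref, e), si, w)
          sa <- site_covers_snp(find_sites(mod_alt, e), si, w)
          if ((length(sr) > 0) == (length(sa) > 0)) next
          primers <- dcaps_primers(flanks, mod_ref, p, product_range,
                                   len_range, tm_range)
          if (is.null(primers)) next
          a <- make_assay(flanks, e, primers, "dCAPS",
                          introduced_mismatch = list(position = p, base = b),
                          template_ref = mod_ref, template_alt = mod_alt)
          if (!is.null(a)) out[[length(out) + 1]] <- a
        }
      }
    }
  }
  out
}

dcaps_primers <- function(flanks, template, mismatch_pos, product_range,
                          len_range, tm_range) {
  si <- flanks$snp_index
  L <- nchar(template)
  mid <- mean(tm_range)
  if (mismatch_pos < si) {
    # mismatch on the forward primer, 3' end just before the SNP
    e <- si - 1L
    for (l in seq(len_range[1], len_range[2])) {
      s <- e - l + 1
      if (s < 1 || s > mismatch_pos) next
      p <- substring(template, s, e)
      tm <- primer_tm(p)
      if (tm < tm_range[1] || tm > tm_range[2]) next
      f <- list(seq = p, start = s, end = e, tm = tm)
      rev <- dcaps_reverse(template, si, f$start, product_range, len_range,
                           tm_range)
      if (!is.null(rev)) {
        return(list(forward = f, reverse = rev,
                    product_size = rev$end - f$start + 1))
      }
    }
    return(NULL)
  }
  # mismatch on the reverse primer, 3' end just after the SNP
  s <- si + 1L
  for (l in seq(len_range[1], len_range[2])) {
    e <- s + l - 1
    if (e > L || e < mismatch_pos) next
    p <- substring(template, s, e)
    tm <- primer_tm(p)
    if (tm < tm_range[1] || tm > tm_range[2]) next
    rev <- list(seq = revcomp(p), start = s, end = e, tm = tm)
    fwd <- forward_candidates(template, si - 1L, len_range, tm_range)
    for (f in fwd) {
      prod <- rev$end - f$start + 1
      if (prod >= product_range[1] && prod <= product_range[2]) {
        return(list(forward = f, reverse = rev, product_size = prod))
      }
    }
  }
  NULL
}

dcaps_reverse <- function(template, snp_index, f_start, product_range,
                          len_range, tm_range) {
  L <- nchar(template)
  for (e in seq(snp_index + 1L, L)) {
    for (l in seq(len_range[1], len_range[2])) {
      s <- e - l + 1
      if (s <= snp_index) next
      prod <- e - f_start + 1
      if (prod < product_range[1] || prod > product_range[2]) next
      p <- substring(template, s, e)
      tm <- primer_tm(p)
      if (tm < tm_range[1] || tm > tm_range[2]) next
      return(list(seq = revcomp(p), start = s, end = e, tm = tm))
    }
  }
  NULL
}

#' @export
print.caps_assay <- function(x, ...) {
  cat(sprintf("%s assay %s: %s %s>%s, enzyme %s\n", x$assay_type,
              x$marker_name, x$snp$chrom, x$snp$ref, x$snp$alt, x$enzyme))
  cat("  fragments ref:", paste(x$fragments_ref, collapse = "+"),
      " alt:", paste(x$fragments_alt, collapse = "+"), "\n")
  invisible(x)
}
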