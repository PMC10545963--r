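GT_CLASSES <- c("hom_ref", "hom_alt", "het", "etc", "missing")
GROUP_LEVELS <- c("ICY-H", "ICY-L", "CY")

#' Classify a per-sample genotype call from its alt-allele read rate
#'
#' Calls are classified from the fraction of reads supporting the alternate
#' allele: homozygous when the rate is at least 90% (alt) or at most 10%
#' (ref), heterozygous when it lies in the inclusive 40--60% band, and
#' \code{"etc"} when it falls in neither band and so cannot be distinguished
#' as homozygous or heterozygous. An absent rate (\code{NA}) is
#' \code{"missing"}.
#'
#' @param rate numeric vector of alt-supporting read fractions in
#'   \verb{[0, 1]}; \code{NA} for absent calls.
#' @return character vector of classes among \code{"hom_ref"},
#'   \code{"hom_alt"}, \code{"het"}, \code{"etc"}, \code{"missing"}.
#' @examples
#' classify_read_rate(c(0.95, 0.5, 0.75, 0.02, NA))
#' @export
classify_read_rate <- function(rate) {
  if (!is.numeric(rate) && !all(is.na(rate))) {
    stop("read rate must be numeric")
  }
  rate <- as.numeric(rate)
  bad <- !is.na(rate) & (rate < 0 | rate > 1)
  if (any(bad)) {
    stop("read rate outside [0, 1]: ", paste(rate[bad], collapse = ", "))
  }
  out <- rep("etc", length(rate))
  out[is.na(rate)] <- "missing"
  out[!is.na(rate) & rate >= 0.90] <- "hom_alt"
  out[!is.na(rate) & rate <= 0.10] <- "hom_ref"
  out[!is.na(rate) & rate >= 0.40 & rate <= 0.60] <- "het"
  out
}

#' Construct a genotype matrix object
#'
#' The sites-by-samples grid of classified genotype calls that the filtering
#' cascade operates on. Sites are sorted by (chrom, pos); every sample must
#' carry a group label (ICY-H, ICY-L or CY).
#'
#' @param sites data.frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt} (1-based positions, single-base alleles).
#' @param calls character matrix, rows matching \code{sites}, one column per
#'   sample, values among the five genotype classes.
#' @param groups named character vector mapping sample name to group.
#' @param consensus optional character matrix of per-line consensus bases
#'   (same shape as \code{calls}) used for imputation of missing calls.
#' @return an object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(sites, calls, groups, consensus = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  calls <- as.matrix(calls)
  if (nrow(sites) != nrow(calls)) {
    stop("sites and calls disagree on the number of rows")
  }
  if (nrow(calls) > 0 && !all(calls %in% GT_CLASSES)) {
    stop("unknown genotype class in calls")
  }
  if (is.null(colnames(calls)) || !all(colnames(calls) %in% names(groups))) {
    stop("every calls column must be a named sample present in groups")
  }
  if (!all(groups[colnames(calls)] %in% GROUP_LEVELS)) {
    stop("groups must map samples to ICY-H, ICY-L or CY")
  }
  if (nrow(sites) > 0 && any(sites$ref == sites$alt)) {
    stop("ref and alt alleles must differ")
  }
  if (nrow(sites) > 0 && any(sites$pos < 1)) stop("positions are 1-based")
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  calls <- calls[ord, , drop = FALSE]
  if (!is.null(consensus)) {
    consensus <- as.matrix(consensus)[ord, , drop = FALSE]
    stopifnot(identical(dim(consensus), dim(calls)))
  }
  rownames(sites) <- NULL
  structure(
    list(sites = sites, calls = calls,
         groups = groups[colnames(calls)], consensus = consensus),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$sites), "sites x",
      ncol(x$calls), "samples\n")
  tab <- table(factor(x$groups, levels = GROUP_LEVELS))
  cat("groups:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Build the integrated SNP matrix as a union over per-line variant lists
#'
#' Takes one variant table per sequenced line and assembles the union of all
#' variant positions; a line without a record at a union site is recorded as
#' \code{"missing"} there, pending consensus imputation.
#'
#' @param per_sample_variants named list (one element per sample) of
#'   data.frames with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt} and either \code{rate} (alt read fraction, classified via
#'   \code{\link{classify_read_rate}}) or \code{class}.
#' @param groups named character vector mapping sample to group.
#' @return a \code{\link{genotype_matrix}} over the union of sites.
#' @export
build_union_matrix <- function(per_sample_variants, groups) {
  stopifnot(is.list(per_sample_variants),
            !is.null(names(per_sample_variants)))
  samples <- names(per_sample_variants)
  all_sites <- do.call(rbind, lapply(per_sample_variants, function(v) {
    if (nrow(v) == 0) return(v[, c("chrom", "pos", "ref", "alt")])
    v[, c("chrom", "pos", "ref", "alt")]
  }))
  if (is.null(all_sites) || nrow(all_sites) == 0) {
    calls <- matrix(character(0), nrow = 0, ncol = length(samples),
                    dimnames = list(NULL, samples))
    return(genotype_matrix(
      data.frame(chrom = character(0), pos = integer(0),
                 ref = character(0), alt = character(0)),
      calls, groups))
  }
  key <- paste(all_sites$chrom, all_sites$pos)
  conflict <- tapply(all_sites$ref, key, function(r) length(unique(r)) > 1)
  if (any(conflict)) {
    stop("conflicting ref alleles across lines at: ",
         paste(names(conflict)[conflict], collapse = ", "))
  }
  sites <- all_sites[!duplicated(key), , drop = FALSE]
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  skey <- paste(sites$chrom, sites$pos)
  calls <- matrix("missing", nrow = nrow(sites), ncol = length(samples),
                  dimnames = list(NULL, samples))
  for (s in samples) {
    v <- per_sample_variants[[s]]
    if (nrow(v) == 0) next
    cls <- if ("class" %in% names(v)) v$class else classify_read_rate(v$rate)
    idx <- match(paste(v$chrom, v$pos), skey)
    calls[idx, s] <- cls
  }
  genotype_matrix(sites, calls, groups)
}

#' Impute missing calls from each line's consensus base
#'
#' A missing call becomes homozygous-reference if the line's consensus base
#' at the site equals the reference allele, homozygous-alternate if it
#' equals the alternate allele, and \code{"etc"} otherwise (consensus N or a
#' third allele cannot be distinguished). Non-missing calls are never
#' altered; a missing call with no consensus base stays missing with a
#' warning. The operation is idempotent.
#'
#' @param m a \code{\link{genotype_matrix}} with a \code{consensus} slot.
#' @return the imputed \code{\link{genotype_matrix}}.
#' @export
impute_from_consensus <- function(m) {
  stopifnot(inherits(m, "genotype_matrix"))
  miss <- which(m$calls == "missing", arr.ind = TRUE)
  if (nrow(miss) == 0) return(m)
  if (is.null(m$consensus)) {
    warning("no consensus bases available; missing calls left as-is")
    return(m)
  }
  cons <- m$consensus[miss]
  ref <- m$sites$ref[miss[, 1]]
  alt <- m$sites$alt[miss[, 1]]
  new <- ifelse(is.na(cons) | cons == "", NA,
                ifelse(cons == ref, "hom_ref",
                       ifelse(cons == alt, "hom_alt", "etc")))
  if (anyNA(new)) {
    warning(sum(is.na(new)), " missing calls had no consensus base")
    new[is.na(new)] <- "missing"
  }
  m$calls[miss] <- new
  m
}

#' Per-sample genotype class summary
#'
#' Counts of total, homozygous, heterozygous and undistinguishable ("etc")
#' calls per sample, in the style of a resequencing SNP-detection summary
#' table.
#'
#' @param m a \code{\link{genotype_matrix}}.
#' @return data.frame with one row per sample.
#' @export
class_summary <- function(m) {
  stopifnot(inherits(m, "genotype_matrix"))
  do.call(rbind, lapply(colnames(m$calls), function(s) {
    cl <- m$calls[, s]
    data.frame(sample = s, group = unname(m$groups[s]),
               total = sum(cl != "missing"),
               homozygous = sum(cl %in% c("hom_ref", "hom_alt")),
               heterozygous = sum(cl == "het"),
               etc = sum(cl == "etc"),
               missing = sum(cl == "missing"))
  }))
}
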