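#' Sites monomorphic within a sample group
#'
#' A site is monomorphic within a group when every sample of the group
#' carries the same homozygous class there (all \code{hom_ref} or all
#' \code{hom_alt}); any heterozygous, undistinguishable or missing call
#' breaks monomorphism. This is the strict-homozygosity reading of
#' "homozygous SNPs monomorphic within the group".
#'
#' @param m a \code{\link{genotype_matrix}}.
#' @param group one of \code{"ICY-H"}, \code{"ICY-L"}, \code{"CY"}.
#' @return integer vector of row indices into \code{m$sites}.
#' @export
monomorphic_within <- function(m, group) {
  stopifnot(inherits(m, "genotype_matrix"))
  samples <- names(m$groups)[m$groups == group]
  if (length(samples) == 0) stop("unknown or empty group: ", group)
  sub <- m$calls[, samples, drop = FALSE]
  hom <- sub == "hom_ref" | sub == "hom_alt"
  same <- rowSums(sub == sub[, 1]) == ncol(sub)
  which(rowSums(hom) == ncol(sub) & same)
}

group_shared_class <- function(m, sites, group) {
  samples <- names(m$groups)[m$groups == group]
  m$calls[sites, samples[1]]
}

#' Sites polymorphic between two monomorphic groups
#'
#' Restricted to sites monomorphic within both groups (the comparable set),
#' keeps those where the two groups' shared homozygous classes differ.
#'
#' @param m a \code{\link{genotype_matrix}}.
#' @param siteset_a,siteset_b row-index outputs of
#'   \code{\link{monomorphic_within}} for the two groups.
#' @param group_a,group_b the group names the site sets belong to.
#' @return integer vector of row indices (subset of both inputs).
#' @export
polymorphic_between <- function(m, siteset_a, siteset_b, group_a, group_b) {
  comparable <- intersect(siteset_a, siteset_b)
  if (length(comparable) == 0) return(integer(0))
  ca <- group_shared_class(m, comparable, group_a)
  cb <- group_shared_class(m, comparable, group_b)
  sort(comparable[ca != cb])
}

#' Run the full group-specific SNP selection cascade
#'
#' Reproduces the bulked-contrast cascade: sites monomorphic within the
#' ICY-H group and within the CY group, the comparable intersection, the
#' subset polymorphic between the two groups, and then arbitration with the
#' ICY-L line: the polymorphic set is partitioned into sites where ICY-L
#' shares the ICY-H class, sites where ICY-L shares the CY class, and an
#' unassigned remainder (ICY-L het/etc/missing). The final diagnostic set is
#' the ICY-L-agrees-with-ICY-H subset: the sites where all three ICY lines
#' share one homozygous allele and all three CY lines the other — the only
#' partition member specific to the ICY/CY contrast. All intermediate sets
#' and counts are retained for audit.
#'
#' @param m a \code{\link{genotype_matrix}} with samples in all three groups.
#' @return an object of class \code{cascade_report}: list with
#'   \code{steps} (named list of integer site-index vectors),
#'   \code{counts} (named integer vector) and \code{final_sites}
#'   (data.frame of the final diagnostic sites).
#' @export
run_cascade <- function(m) {
  stopifnot(inherits(m, "genotype_matrix"))
  mono_icy_h <- monomorphic_within(m, "ICY-H")
  mono_cy <- monomorphic_within(m, "CY")
  comparable <- intersect(mono_icy_h, mono_cy)
  poly <- polymorphic_between(m, mono_icy_h, mono_cy, "ICY-H", "CY")
  arb <- arbitrate_with_third_group(m, poly)
  steps <- c(list(
    monomorphic_icy_h = mono_icy_h,
    monomorphic_cy = mono_cy,
    comparable_between_groups = sort(comparable),
    polymorphic_icy_h_vs_cy = poly), arb)
  rep <- structure(
    list(steps = steps,
         counts = vapply(steps, length, integer(1)),
         final_sites = m$sites[arb$final_specific, , drop = FALSE]),
    class = "cascade_report")
  rep
}

#' Arbitrate a between-group polymorphic set with the ICY-L line
#'
#' @param m a \code{\link{genotype_matrix}}.
#' @param polymorphic_set row indices from \code{\link{polymorphic_between}}
#'   over ICY-H vs CY.
#' @return named list of integer index vectors:
#'   \code{icy_l_matches_icy_h}, \code{icy_l_matches_cy},
#'   \code{icy_l_unassigned}, \code{final_specific} (identical to the first).
#' @export
arbitrate_with_third_group <- function(m, polymorphic_set) {
  stopifnot(inherits(m, "genotype_matrix"))
  ps <- sort(polymorphic_set)
  icy_l_samples <- names(m$groups)[m$groups == "ICY-L"]
  if (length(ps) == 0) {
    e <- integer(0)
    return(list(icy_l_matches_icy_h = e, icy_l_matches_cy = e,
                icy_l_unassigned = e, final_specific = e))
  }
  ch <- group_shared_class(m, ps, "ICY-H")
  cc <- group_shared_class(m, ps, "CY")
  lsub <- m$calls[ps, icy_l_samples, drop = FALSE]
  l_uniform <- rowSums(lsub == lsub[, 1]) == ncol(lsub)
  lcl <- lsub[, 1]
  match_h <- l_uniform & lcl == ch
  match_c <- l_uniform & lcl == cc
  list(icy_l_matches_icy_h = ps[match_h],
       icy_l_matches_cy = ps[match_c],
       icy_l_unassigned = ps[!(match_h | match_c)],
       final_specific = ps[match_h])
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("SNP selection cascade:\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-28s %d\n", nm, x$counts[[nm]]))
  }
  invisible(x)
}

#' Final diagnostic sites of a cascade report as a data.frame
#'
#' @param report a \code{cascade_report} from \code{\link{run_cascade}}.
#' @return data.frame of sites (chrom, pos, ref, alt).
#' @export
final_sites <- function(report) {
  stopifnot(inherits(report, "cascade_report"))
  report$final_sites
}
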