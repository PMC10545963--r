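C_LEVELS <- c("CC", "Cc", "cc")
C2_LEVELS <- c("C2C2", "C2c2", "c2c2")

#' Predict watermelon flesh phenotype from the two-locus genotype
#'
#' The epistasis model for flesh colour: a recessive homozygote at the C
#' locus (the LCYB-based locus) gives red flesh (R) irrespective of the C2
#' locus; otherwise a dominant allele at the C2 locus (the PPR-linked locus)
#' gives canary yellow (CY); a C2 recessive homozygote with a dominant C
#' allele gives incomplete canary yellow (ICY). Both dominant alleles are
#' therefore required for full canary yellow.
#'
#' @param c_locus genotype at the C locus: \code{"CC"}, \code{"Cc"} or
#'   \code{"cc"} (vectorised).
#' @param c2_locus genotype at the C2 locus: \code{"C2C2"}, \code{"C2c2"} or
#'   \code{"c2c2"}.
#' @return character vector of phenotype classes \code{"CY"}, \code{"ICY"},
#'   \code{"R"}.
#' @examples
#' predict_phenotype("CC", "c2c2")  # ICY
#' predict_phenotype("cc", "C2C2")  # R
#' @export
predict_phenotype <- function(c_locus, c2_locus) {
  if (!all(c_locus %in% C_LEVELS)) {
    stop("invalid C-locus genotype: ",
         paste(setdiff(c_locus, C_LEVELS), collapse = ", "))
  }
  if (!all(c2_locus %in% C2_LEVELS)) {
    stop("invalid C2-locus genotype: ",
         paste(setdiff(c2_locus, C2_LEVELS), collapse = ", "))
  }
  ifelse(c_locus == "cc", "R",
         ifelse(c2_locus %in% c("C2C2", "C2c2"), "CY", "ICY"))
}

#' Score genotype-phenotype concordance over a germplasm panel
#'
#' Applies \code{\link{predict_phenotype}} to each line of a marker-typed
#' panel and compares with the observed phenotype. The two C-locus markers
#' (Lcyb and Clcyb.600) are collapsed to one C-locus genotype; a
#' disagreement between them is reported as a data conflict for the line
#' rather than silently resolved.
#'
#' @param panel data.frame with columns \code{line_id}, \code{phenotype}
#'   (CY/ICY/R), \code{lcyb}, \code{clcyb600} (CC/Cc/cc) and \code{m7}
#'   (C2C2/C2c2/c2c2).
#' @return list with \code{table} (the panel plus \code{c_locus},
#'   \code{predicted}, \code{match}), \code{n_match}, \code{n_total}.
#' @export
concordance_table <- function(panel) {
  if (!is.data.frame(panel) || nrow(panel) == 0) {
    stop("panel must be a non-empty data.frame")
  }
  need <- c("line_id", "phenotype", "lcyb", "clcyb600", "m7")
  stopifnot(all(need %in% names(panel)))
  conflict <- panel$lcyb != panel$clcyb600
  if (any(conflict)) {
    stop("C-locus marker conflict (Lcyb vs Clcyb.600) for line(s): ",
         paste(panel$line_id[conflict], collapse = ", "))
  }
  bad_c <- !(panel$lcyb %in% C_LEVELS)
  bad_c2 <- !(panel$m7 %in% C2_LEVELS)
  if (any(bad_c | bad_c2)) {
    stop("malformed genotype for line(s): ",
         paste(panel$line_id[bad_c | bad_c2], collapse = ", "))
  }
  panel$c_locus <- panel$lcyb
  panel$predicted <- predict_phenotype(panel$c_locus, panel$m7)
  panel$match <- panel$predicted == panel$phenotype
  list(table = panel, n_match = sum(panel$match), n_total = nrow(panel))
}

parse_homozygous <- function(g, levels) {
  if (!g %in% levels[c(1, 3)]) {
    stop("parent must be homozygous; got ", g)
  }
  g
}

#' Expected F2 phenotype segregation for a cross of homozygous parents
#'
#' Enumerates the F2 genotype classes of a two-locus cross (via all gamete
#' combinations of the F1, loci unlinked in expectation) with Mendelian
#' frequencies, maps each through \code{\link{predict_phenotype}} and
#' aggregates the expected phenotype ratio. A cross of an ICY line
#' (CC c2c2) with a CY line (CC C2C2) yields the 3:1 CY:ICY ratio observed
#' for a single dominant locus.
#'
#' @param parent1,parent2 lists with \code{c_locus} and \code{c2_locus},
#'   both homozygous (e.g. \code{list(c_locus = "CC", c2_locus = "c2c2")}).
#' @return named numeric vector of expected phenotype class probabilities.
#' @export
f2_expected_segregation <- function(parent1, parent2) {
  p1c <- parse_homozygous(parent1$c_locus, C_LEVELS)
  p2c <- parse_homozygous(parent2$c_locus, C_LEVELS)
  p1c2 <- parse_homozygous(parent1$c2_locus, C2_LEVELS)
  p2c2 <- parse_homozygous(parent2$c2_locus, C2_LEVELS)
  gamete <- function(hom) substring(hom, 1, nchar(hom) / 2)
  f1_c <- c(gamete(p1c), gamete(p2c))
  f1_c2 <- c(gamete(p1c2), gamete(p2c2))
  # F2 genotype class frequencies per locus from the F1's two alleles
  locus_classes <- function(alleles, levels) {
    combos <- expand.grid(a1 = alleles, a2 = alleles,
                          stringsAsFactors = FALSE)
    geno <- apply(combos, 1, function(x) {
      s <- x[order(substr(x, 1, 1) %in% letters)]  # dominant allele first
      paste0(s[1], s[2])
    })
    tab <- table(geno) / length(geno)
    tab[intersect(levels, names(tab))]
  }
  cls_c <- locus_classes(f1_c, C_LEVELS)
  cls_c2 <- locus_classes(f1_c2, C2_LEVELS)
  out <- c(CY = 0, ICY = 0, R = 0)
  for (i in seq_along(cls_c)) {
    for (j in seq_along(cls_c2)) {
      ph <- predict_phenotype(names(cls_c)[i], names(cls_c2)[j])
      out[ph] <- out[ph] + cls_c[i] * cls_c2[j]
    }
  }
  out[out > 0]
}

#' Load the packaged germplasm evaluation panel
#'
#' The published 27-line watermelon panel (CY, ICY and red-fleshed inbreds)
#' genotyped with the two LCYB-gene C-locus markers (Lcyb, Clcyb.600) and
#' the PPR-gene C2-locus marker (M7), transcribed to TSV.
#'
#' @param path panel TSV; defaults to the packaged file.
#' @return data.frame suitable for \code{\link{concordance_table}}.
#' @export
load_germplasm_panel <- function(path = system.file(
  "extdata", "germplasm_panel.tsv", package = "fleshmap")) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
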