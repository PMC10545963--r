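#' Chi-square goodness-of-fit test against an integer segregation ratio
#'
#' Tests observed class counts against expected counts proportional to a
#' Mendelian ratio (e.g. 3:1 for a single dominant locus in an F2), with
#' \eqn{\chi^2 = \sum (O-E)^2/E}, df = classes - 1 and an upper-tail
#' p-value.
#'
#' @param observed non-negative integer counts per class.
#' @param ratio integer ratio vector of the same length (scale-invariant).
#' @return list with \code{chi2}, \code{df}, \code{p_value},
#'   \code{expected}.
#' @examples
#' chisq_ratio_test(c(94, 41), c(3, 1))  # chi2 = 2.076, p = 0.149
#' @export
chisq_ratio_test <- function(observed, ratio) {
  stopifnot(length(observed) == length(ratio), length(observed) >= 2,
            all(observed >= 0), sum(observed) > 0)
  if (any(ratio <= 0)) stop("ratio classes must be positive")
  expected <- sum(observed) * ratio / sum(ratio)
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       expected = expected)
}

#' Kosambi mapping function and its inverse
#'
#' Converts a recombination fraction to map distance,
#' \eqn{d = 25 \ln((1+2r)/(1-2r))} centimorgans, allowing for partial
#' crossover interference; \code{kosambi_inverse} is the analytic inverse
#' \eqn{r = \tanh(d/50)/2}.
#'
#' @param r recombination fraction(s) in \verb{[0, 0.5)}.
#' @param d_cm map distance(s) in centimorgans, \eqn{\ge 0}.
#' @return map distance in cM (\code{kosambi}) or recombination fraction
#'   (\code{kosambi_inverse}).
#' @examples
#' kosambi(0.25)          # 25 * log(3) = 27.465 cM
#' kosambi_inverse(8.7)   # ~0.0861
#' @export
kosambi <- function(r) {
  if (any(r < 0 | r >= 0.5)) {
    stop("recombination fraction must lie in [0, 0.5); r = 0.5 maps to ",
         "infinite distance")
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi
#' @export
kosambi_inverse <- function(d_cm) {
  if (any(d_cm < 0)) stop("map distance must be non-negative")
  tanh(d_cm / 50) / 2
}

#' F2 two-locus joint class probabilities (codominant x codominant)
#'
#' Joint probabilities of the nine a/h/b x a/h/b F2 classes for two loci in
#' coupling at recombination fraction r, assuming no crossover interference.
#'
#' @param r recombination fraction in \verb{[0, 0.5]}.
#' @return 3x3 matrix (rows/cols named a, h, b) summing to 1.
#' @export
f2_joint_probs <- function(r) {
  p <- (1 - r) / 2  # parental gametes AB, ab
  q <- r / 2        # recombinant gametes Ab, aB
  m <- matrix(c(
    p^2,      2 * p * q,         q^2,
    2 * p * q, 2 * p^2 + 2 * q^2, 2 * p * q,
    q^2,      2 * p * q,         p^2),
    nrow = 3, byrow = TRUE, dimnames = list(c("a", "h", "b"),
                                            c("a", "h", "b")))
  m
}

f2_dominant_probs <- function(r) {
  # marker a/h/b x trait phenotype (a = recessive class, b = dominant class)
  j <- f2_joint_probs(r)
  cbind(a = j[, "a"], b = j[, "h"] + j[, "b"])
}

loglik_table <- function(counts, probfun, r) {
  p <- probfun(r)
  keep <- counts > 0
  if (any(p[keep] <= 0)) return(-Inf)
  sum(counts[keep] * log(p[keep]))
}

rf_ml <- function(counts, probfun) {
  counts <- as.matrix(counts)
  if (sum(counts) == 0) stop("degenerate all-zero contingency table")
  ll <- function(r) loglik_table(counts, probfun, r)
  grid <- seq(0, 0.5, by = 1e-3)
  lg <- vapply(grid, ll, numeric(1))
  i <- which.max(lg)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(ll, lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-9)
  cand_r <- c(0, 0.5, grid[i], opt$maximum)
  cand_ll <- c(ll(0), ll(0.5), lg[i], opt$objective)
  best <- which.max(cand_ll)
  r_hat <- cand_r[best]
  lod <- (cand_ll[best] - ll(0.5)) / log(10)
  list(r_hat = r_hat, LOD = lod, loglik = cand_ll[best])
}

#' Two-point recombination fraction for a codominant marker pair
#'
#' Maximum-likelihood estimate of the recombination fraction from the 3x3
#' a/h/b x a/h/b F2 contingency table under the two-locus class
#' probabilities (coupling phase, no interference), by grid search at 1e-3
#' with local refinement. LOD is the log10 likelihood ratio against
#' independence (r = 0.5).
#'
#' @param counts 3x3 matrix of plant counts, rows locus 1 (a/h/b), columns
#'   locus 2 (a/h/b).
#' @return list with \code{r_hat} in \verb{[0, 0.5]} and \code{LOD}.
#' @export
rf_codominant_pair <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(identical(dim(counts), c(3L, 3L)))
  rf_ml(counts, f2_joint_probs)
}

#' Two-point recombination fraction between a codominant marker and a
#' dominant trait
#'
#' As \code{\link{rf_codominant_pair}} but for a 3x2 table of marker a/h/b
#' against trait phenotype class (a = homozygous-recessive phenotype, b =
#' dominant phenotype collapsing the heterozygous and dominant-homozygous
#' trait genotypes).
#'
#' @param counts 3x2 matrix, rows marker a/h/b, columns trait a/b.
#' @return list with \code{r_hat} and \code{LOD}.
#' @export
rf_dominant_trait <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(identical(dim(counts), c(3L, 2L)))
  rf_ml(counts, f2_dominant_probs)
}

pair_table <- function(records, locus1, locus2) {
  x <- records[[locus1]]
  y <- records[[locus2]]
  keep <- x %in% c("a", "h", "b") & y %in% c("a", "h", "b")
  table(factor(x[keep], levels = c("a", "h", "b")),
        factor(y[keep], levels = c("a", "h", "b")))
}

#' Assemble a linkage map along a fixed physical order
#'
#' Estimates adjacent-pair recombination fractions along an externally fixed
#' locus order (markers mapped in accordance with their physical genomic
#' order) and accumulates Kosambi distances; cosegregating loci share a
#' position. Marker-marker pairs use the codominant estimator; pairs
#' involving the trait column use the dominant-trait estimator. Missing
#' calls are dropped pairwise.
#'
#' @param records data.frame of F2 records: one row per plant, one column
#'   per locus with values a/h/b (markers) or a/b (trait), missing as
#'   \code{"-"} or \code{NA}.
#' @param order character vector of locus (column) names in physical order.
#' @param trait name of the trait column in \code{order}, or \code{NULL}
#'   when mapping markers only.
#' @param lod_min linkage declaration threshold (default 2.0); adjacent
#'   pairs under it are flagged, not dropped, so the fixed order is kept.
#' @return object of class \code{linkage_map}: data.frame \code{loci}
#'   (locus, position_cm, r_adjacent, lod_adjacent) plus the pairwise
#'   \code{r}/\code{LOD} matrices.
#' @export
build_map <- function(records, order, trait = NULL, lod_min = 2.0) {
  stopifnot(length(order) >= 2, all(order %in% names(records)))
  est <- function(l1, l2) {
    if (!is.null(trait) && (l1 == trait || l2 == trait)) {
      mk <- if (l1 == trait) l2 else l1
      m <- records[[mk]]
      t <- records[[trait]]
      keep <- m %in% c("a", "h", "b") & t %in% c("a", "b")
      if (!any(keep)) stop("no informative plants for pair ", l1, "/", l2)
      tab <- table(factor(m[keep], levels = c("a", "h", "b")),
                   factor(t[keep], levels = c("a", "b")))
      rf_dominant_trait(tab)
    } else {
      tab <- pair_table(records, l1, l2)
      if (sum(tab) == 0) stop("no informative plants for pair ", l1, "/", l2)
      rf_codominant_pair(tab)
    }
  }
  n <- length(order)
  r_adj <- lod_adj <- rep(NA_real_, n)
  pos <- numeric(n)
  for (i in seq_len(n - 1)) {
    fit <- est(order[i], order[i + 1])
    r_adj[i + 1] <- fit$r_hat
    lod_adj[i + 1] <- fit$LOD
    pos[i + 1] <- pos[i] + kosambi(min(fit$r_hat, 0.5 - 1e-9))
  }
  rmat <- lodmat <- matrix(NA_real_, n, n, dimnames = list(order, order))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      fit <- est(order[i], order[j])
      rmat[i, j] <- rmat[j, i] <- fit$r_hat
      lodmat[i, j] <- lodmat[j, i] <- fit$LOD
    }
  }
  structure(list(
    loci = data.frame(locus = order, position_cm = pos,
                      r_adjacent = r_adj, lod_adjacent = lod_adj,
                      linked = is.na(lod_adj) | lod_adj >= lod_min),
    r_pairwise = rmat, lod_pairwise = lodmat, lod_min = lod_min),
    class = "linkage_map")
}

#' @export
print.linkage_map <- function(x, ...) {
  cat("linkage map (", nrow(x$loci), " loci, ",
      sprintf("%.1f", max(x$loci$position_cm)), " cM):\n", sep = "")
  print(x$loci, row.names = FALSE)
  invisible(x)
}

#' Count unambiguous recombinant plants between a marker and the trait
#'
#' Under dominance only definite recombination events are countable: marker
#' class b (paternal homozygote, dominant-parent alleles) combined with the
#' recessive trait phenotype is definitely recombinant, as is marker class a
#' combined with the dominant phenotype only in the homozygous case --
#' which phenotype alone cannot resolve, so the count is of plants whose
#' marker/trait pair is impossible without recombination.
#'
#' @param marker,trait vectors of a/h/b marker calls and a/b trait classes.
#' @return integer count of definite recombinants.
#' @export
count_definite_recombinants <- function(marker, trait) {
  keep <- marker %in% c("a", "h", "b") & trait %in% c("a", "b")
  m <- marker[keep]
  t <- trait[keep]
  # trait 'a' = homozygous recessive at the trait locus: any marker allele
  # from the dominant parent (h or b) is a recombinant gamete.
  sum((t == "a" & m == "b") * 2L + (t == "a" & m == "h") * 1L)
}
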