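test_that("read-rate classification matches the stated bands", {
  expect_equal(classify_read_rate(0.95), "hom_alt")
  expect_equal(classify_read_rate(0.90), "hom_alt")
  expect_equal(classify_read_rate(0.10), "hom_ref")
  expect_equal(classify_read_rate(0.05), "hom_ref")
  expect_equal(classify_read_rate(c(0.40, 0.50, 0.60)),
               c("het", "het", "het"))
  expect_equal(classify_read_rate(c(0.75, 0.11, 0.399, 0.601, 0.899)),
               rep("etc", 5))
  expect_equal(classify_read_rate(NA), "missing")
  expect_error(classify_read_rate(1.2), "outside")
  expect_error(classify_read_rate(-0.1), "outside")
})

test_that("the five classes partition [0,1] plus absent", {
  grid <- c(seq(0, 1, by = 1e-3), NA)
  cls <- classify_read_rate(grid)
  expect_true(all(cls %in% c("hom_ref", "hom_alt", "het", "etc",
                             "missing")))
  # piecewise-constant, total: every rate gets exactly one class
  expect_length(cls, length(grid))
  expect_false(anyNA(cls))
})

test_that("union matrix covers the union of sites and flags absences", {
  groups <- default_groups()
  v1 <- data.frame(chrom = "c1", pos = c(1, 2), ref = "A", alt = "G",
                   rate = c(1, 0))
  v2 <- data.frame(chrom = "c1", pos = c(2, 3), ref = "A", alt = "G",
                   rate = c(0.5, 1))
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      rate = numeric(0))
  per <- list(PS186 = v1, PS189 = v2, PS187 = empty, PS188 = empty,
              PS160 = empty, PS190 = empty)
  m <- build_union_matrix(per, groups)
  expect_equal(m$sites$pos, c(1, 2, 3))
  expect_equal(m$calls[, "PS186"], c("hom_alt", "hom_ref", "missing"))
  expect_equal(m$calls[, "PS189"], c("missing", "het", "hom_alt"))
})

test_that("union matrix is permutation invariant and handles empty input", {
  groups <- default_groups()
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      rate = numeric(0))
  set.seed(42)
  mk <- function(pos) data.frame(chrom = "c1", pos = pos, ref = "A",
                                 alt = "G", rate = 1)
  per <- list(PS186 = mk(c(5, 1, 9)), PS189 = mk(c(9, 2)),
              PS187 = empty, PS188 = mk(7), PS160 = empty, PS190 = empty)
  m1 <- build_union_matrix(per, groups)
  m2 <- build_union_matrix(per[c(4, 2, 1, 3, 6, 5)], groups)
  expect_equal(m1$sites, m2$sites)
  expect_equal(m1$calls[, colnames(m1$calls)],
               m2$calls[, colnames(m1$calls)])
  expect_equal(nrow(m1$sites), 5)  # |union of positions|
  m0 <- build_union_matrix(list(PS186 = empty, PS189 = empty,
                                PS187 = empty, PS188 = empty,
                                PS160 = empty, PS190 = empty), groups)
  expect_equal(nrow(m0$sites), 0)
})

test_that("conflicting ref alleles across lines raise a data error", {
  groups <- default_groups()
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      rate = numeric(0))
  per <- list(
    PS186 = data.frame(chrom = "c1", pos = 5, ref = "A", alt = "G",
                       rate = 1),
    PS189 = data.frame(chrom = "c1", pos = 5, ref = "C", alt = "G",
                       rate = 1),
    PS187 = empty, PS188 = empty, PS160 = empty, PS190 = empty)
  expect_error(build_union_matrix(per, groups), "conflicting ref")
})

test_that("consensus imputation follows the decision table and is
           idempotent", {
  groups <- default_groups()
  sites <- data.frame(chrom = "c1", pos = 1:3, ref = "A", alt = "G")
  calls <- matrix("missing", 3, 6,
                  dimnames = list(NULL, names(groups)))
  calls[, 2:6] <- "hom_alt"
  cons <- matrix("A", 3, 6, dimnames = list(NULL, names(groups)))
  cons[2, 1] <- "G"
  cons[3, 1] <- "N"
  m <- genotype_matrix(sites, calls, groups, consensus = cons)
  imp <- impute_from_consensus(m)
  expect_equal(imp$calls[, 1], c("hom_ref", "hom_alt", "etc"))
  expect_equal(imp$calls[, 2:6], m$calls[, 2:6])  # non-missing untouched
  expect_equal(impute_from_consensus(imp)$calls, imp$calls)  # idempotent
})

test_that("imputation without a consensus base warns and leaves missing", {
  groups <- default_groups()
  sites <- data.frame(chrom = "c1", pos = 1, ref = "A", alt = "G")
  calls <- matrix(c("missing", rep("hom_alt", 5)), 1, 6,
                  dimnames = list(NULL, names(groups)))
  m <- genotype_matrix(sites, calls, groups)
  expect_warning(imp <- impute_from_consensus(m), "consensus")
  expect_equal(unname(imp$calls[1, 1]), "missing")
})
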