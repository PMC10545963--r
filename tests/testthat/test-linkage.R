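test_that("chi-square ratio test reproduces the textbook cases", {
  x <- chisq_ratio_test(c(94, 41), c(3, 1))
  expect_equal(x$chi2, 2.0765, tolerance = 1e-3)
  expect_equal(x$df, 1)
  expect_equal(x$p_value, 0.149, tolerance = 1e-2)
  expect_equal(chisq_ratio_test(c(75, 25), c(3, 1))$chi2, 0)
  expect_equal(chisq_ratio_test(c(60, 40), c(1, 1))$chi2, 4.0)
})

test_that("chi-square is ratio-scale invariant and validates input", {
  a <- chisq_ratio_test(c(50, 30, 20), c(2, 1, 1))
  b <- chisq_ratio_test(c(50, 30, 20), c(200, 100, 100))
  expect_equal(a$chi2, b$chi2)
  expect_error(chisq_ratio_test(c(10), c(1)))
  expect_error(chisq_ratio_test(c(10, 5), c(1, 0)), "positive")
})

test_that("Kosambi transform round-trips and hits known values", {
  expect_equal(kosambi(0), 0)
  expect_equal(kosambi(0.25), 25 * log(3), tolerance = 1e-9)
  expect_equal(kosambi_inverse(8.7), 0.0861, tolerance = 1e-3)
  r <- seq(0, 0.49, by = 0.01)
  expect_lt(max(abs(r - kosambi_inverse(kosambi(r)))), 1e-10)
  expect_error(kosambi(0.5), "infinite")
  expect_error(kosambi_inverse(-1))
})

test_that("perfect cosegregation gives r = 0 exactly for both
           estimators", {
  co <- matrix(0, 3, 3); diag(co) <- c(30, 70, 35)
  fit <- rf_codominant_pair(co)
  expect_identical(fit$r_hat, 0)
  expect_gt(fit$LOD, 2)
  dom <- matrix(c(34, 0, 0, 0, 68, 33), 3, 2)
  fitd <- rf_dominant_trait(dom)
  expect_identical(fitd$r_hat, 0)
  expect_gt(fitd$LOD, 2)
  expect_error(rf_codominant_pair(matrix(0, 3, 3)), "all-zero")
})

test_that("the ML estimate beats every grid point (likelihood oracle)", {
  set.seed(61)
  for (s in 1:5) {
    f2 <- gen_f2_population(f2_sim_spec(
      n_plants = 200, marker_positions_cm = c(MA = 0, MB = 10),
      trait_position_cm = 60, seed = 600 + s))
    tab <- table(factor(f2$MA, c("a", "h", "b")),
                 factor(f2$MB, c("a", "h", "b")))
    fit <- rf_codominant_pair(tab)
    ll <- function(r) {
      p <- fleshmap::f2_joint_probs(r)
      sum(tab[tab > 0] * log(p[tab > 0]))
    }
    grid <- seq(0, 0.5, by = 1e-3)
    expect_gte(ll(fit$r_hat) + 1e-9, max(vapply(grid, ll, numeric(1))))
  }
})

test_that("independent loci give r near 0.5 and negligible LOD", {
  f2 <- gen_f2_population(f2_sim_spec(
    n_plants = 1000, marker_positions_cm = c(MA = 0, MB = 500),
    trait_position_cm = 250, seed = 62))
  tab <- table(factor(f2$MA, c("a", "h", "b")),
               factor(f2$MB, c("a", "h", "b")))
  fit <- rf_codominant_pair(tab)
  expect_gt(fit$r_hat, 0.45)
  expect_lt(fit$LOD, 2)  # unlinked at the LOD 2.0 threshold
})

test_that("recombination fractions are recovered from simulated F2s", {
  d <- kosambi(0.10)
  est_co <- est_dom <- numeric(40)
  for (s in 1:40) {
    f2 <- gen_f2_population(f2_sim_spec(
      n_plants = 500, marker_positions_cm = c(MA = 0, MB = d),
      trait_position_cm = 0, seed = 700 + s))
    tab <- table(factor(f2$MA, c("a", "h", "b")),
                 factor(f2$MB, c("a", "h", "b")))
    est_co[s] <- rf_codominant_pair(tab)$r_hat
    tabd <- table(factor(f2$MB, c("a", "h", "b")),
                  factor(f2$trait, c("a", "b")))
    est_dom[s] <- rf_dominant_trait(tabd)$r_hat
  }
  expect_equal(mean(est_co), 0.10, tolerance = 0.02 / 0.1)
  expect_gt(mean(est_co), 0.08); expect_lt(mean(est_co), 0.12)
  expect_gt(mean(est_dom), 0.07); expect_lt(mean(est_dom), 0.13)
})

test_that("map assembly follows the fixed order and places cosegregating
           loci together", {
  # three markers with zero recombination collapse to one position
  rec <- data.frame(M1 = rep(c("a", "h", "b"), times = c(30, 70, 35)))
  rec$M2 <- rec$M1; rec$M3 <- rec$M1
  map <- build_map(rec, c("M1", "M2", "M3"))
  expect_equal(map$loci$position_cm, c(0, 0, 0))
  f2 <- gen_f2_population(f2_sim_spec(n_plants = 400, seed = 63))
  ord <- c("M1", "M2", "M3", "M4", "M5", "M6", "trait", "M7", "M8", "M9")
  map2 <- build_map(f2, ord, trait = "trait")
  expect_equal(map2$loci$position_cm[1], 0)
  expect_true(all(diff(map2$loci$position_cm) >= 0))
  # trait cosegregates with M6-M8 in the generating model (all at 8.7 cM)
  pos <- setNames(map2$loci$position_cm, map2$loci$locus)
  expect_equal(unname(pos["trait"]), unname(pos["M7"]))
})

test_that("ten-marker map positions are recovered within 20% at n = 500", {
  truth_cm <- seq(0, 18, by = 2)
  names(truth_cm) <- paste0("M", 1:10)
  f2 <- gen_f2_population(f2_sim_spec(
    n_plants = 500, marker_positions_cm = truth_cm,
    trait_position_cm = 100, seed = 64))
  map <- build_map(f2, names(truth_cm))
  expect_lt(abs(max(map$loci$position_cm) - 18) / 18, 0.2)
  expect_lt(max(abs(map$loci$position_cm - truth_cm)) / 18, 0.2)
})

test_that("definite recombinant counting is conservative under
           dominance", {
  marker <- c("a", "h", "b", "b", "h", "a")
  trait <- c("a", "b", "b", "a", "a", "b")
  # plants 4 (b with recessive trait: 2 recombinant gametes) and
  # 5 (h with recessive trait: 1) are definite; plant 6 (a with dominant
  # phenotype) is ambiguous and not counted
  expect_equal(count_definite_recombinants(marker, trait), 3L)
  expect_equal(count_definite_recombinants(c("a", "b"), c("a", "b")), 0L)
})
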