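mk_lib <- function(labels, scores = seq_along(labels)) {
  ranked_library(seq_along(labels), scores, labels)
}

test_that("ranked libraries sort ascending with stable ties", {
  lib <- ranked_library(c("a", "b", "c", "d"), c(2, 1, 2, 0),
                        c("decoy", "active", "decoy", "active"))
  expect_equal(lib$id, c("d", "b", "a", "c"))   # ties a,c keep input order
  expect_error(ranked_library("x", 1, "hit"), "active")
  expect_error(ranked_library(c("x", "y"), c(1, NA), c("active", "decoy")),
               "finite")
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tscore\tlabel", "c1\t-9.1\tactive", "c2\t-7.5\tdecoy"), p)
  rl <- read_ranked_library(p, sep = "\t")
  expect_s3_class(rl, "ranked_library")
  expect_equal(rl$score, c(-9.1, -7.5))
})

test_that("enrichment factors match their defining ratio", {
  lib <- mk_lib(c("active", "active", rep("decoy", 8)))
  expect_equal(enrichment_factor(lib, 0.1), 5)        # (1/1)/(2/10)
  bottom <- mk_lib(c(rep("decoy", 8), "active", "active"))
  expect_equal(enrichment_factor(bottom, 0.1), 0)
  expect_equal(enrichment_factor(lib, 1.0), 1)
  expect_equal(enrichment_factor(bottom, 1.0), 1)
  expect_error(enrichment_factor(mk_lib(rep("decoy", 5)), 0.1), "no actives")
  expect_error(enrichment_factor(lib, 0), "top_fraction")
})

test_that("EF under uniformly random ranking averages 1", {
  set.seed(99)
  N <- 100; n_act <- 10
  efs <- vapply(1:10000, function(i) {
    lab <- sample(c(rep("active", n_act), rep("decoy", N - n_act)))
    k <- 10  # top 10%
    (sum(lab[1:k] == "active") / k) / (n_act / N)
  }, numeric(1))
  se <- sd(efs) / sqrt(length(efs))
  expect_lt(abs(mean(efs) - 1), 3 * se)
})

test_that("BEDROC separates perfect from worst ranking and weights early ranks", {
  perfect <- mk_lib(c(rep("active", 10), rep("decoy", 990)))
  worst <- mk_lib(c(rep("decoy", 990), rep("active", 10)))
  expect_gte(bedroc(perfect), 0.99)
  expect_lte(bedroc(worst), 0.01)
  expect_error(bedroc(mk_lib(rep("active", 5))), "no decoys")
  # about 80% of the exponential rank weight sits in the top 8% at alpha 20
  expect_equal(round(100 * bedroc_weight_fraction(20, 0.08)), 80)
  # rank-only: invariant to monotone score transforms
  set.seed(7)
  sc <- rnorm(200)
  lab <- sample(c(rep("active", 20), rep("decoy", 180)))
  l1 <- ranked_library(1:200, sc, lab)
  l2 <- ranked_library(1:200, exp(sc / 2) - 5, lab)
  expect_equal(bedroc(l1), bedroc(l2), tolerance = 1e-12)
})

test_that("enrichment AUC equals the all-pairs oracle, including ties", {
  expect_equal(enrichment_auc(mk_lib(c("active", "active", "decoy", "decoy"))), 1)
  expect_equal(enrichment_auc(mk_lib(c("decoy", "decoy", "active", "active"))), 0)
  expect_equal(enrichment_auc(mk_lib(c("active", "decoy", "active", "decoy"))),
               0.75)
  set.seed(12)
  for (rep in 1:8) {
    N <- sample(20:200, 1)
    n_act <- sample(2:(N %/% 2), 1)
    scores <- sample(round(rnorm(N), 1))    # rounding plants ties
    lab <- sample(c(rep("active", n_act), rep("decoy", N - n_act)))
    lib <- ranked_library(seq_len(N), scores, lab)
    expect_identical(enrichment_auc(lib) == oracle_auc_allpairs(lib), TRUE)
  }
})

test_that("ACT-50% finds the smallest covering top fraction", {
  expect_equal(act_fraction(mk_lib(c("active", "active", rep("decoy", 8)))),
               0.1)
  expect_equal(act_fraction(mk_lib(c(rep("decoy", 8), "active", "active"))),
               0.9)
  expect_equal(act_fraction(mk_lib(rep("active", 10))), 0.5)
  # promoting an active never increases ACT-50%
  lab <- c("decoy", "decoy", "active", "decoy", "active", rep("decoy", 5))
  base <- act_fraction(mk_lib(lab))
  promoted <- act_fraction(mk_lib(c("active", lab[-5])))
  expect_lte(promoted, base)
})

test_that("Mann-Whitney U: exact small-sample p-values and symmetry", {
  r <- mann_whitney_u(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$p, 0.1)               # 2 most extreme of C(6,3) orderings
  expect_equal(r$method, "exact enumeration")
  expect_equal(mann_whitney_u(c(10, 11, 12), c(1, 2, 3))$p, 0.1)
  ident <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gte(ident$p, 0.9)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
  # agrees with the independent enumeration oracle, with ties
  set.seed(5)
  for (rep in 1:6) {
    a <- sample(1:6, 4, replace = TRUE)
    b <- sample(1:6, 4, replace = TRUE)
    expect_equal(mann_whitney_u(a, b)$p, oracle_mw_exact(a, b),
                 tolerance = 1e-12)
  }
  # agrees with stats::wilcox.test exact p on untied data
  set.seed(6)
  a <- rnorm(5); b <- rnorm(6) + 1
  expect_equal(mann_whitney_u(a, b)$p,
               stats::wilcox.test(a, b, exact = TRUE)$p.value,
               tolerance = 1e-9)
})

# At the sizes where the implementation hands over from enumeration to the
# tie-corrected normal approximation (just above exact_max), the two routes
# must agree closely.
test_that("Mann-Whitney normal approximation tracks exact enumeration", {
  set.seed(8)
  worst <- 0
  for (rep in 1:40) {
    na <- sample(6:7, 1); nb <- 13 + (rep %% 2) - na
    a <- rnorm(na); b <- rnorm(nb)
    exact <- mann_whitney_u(a, b, exact_max = 14L)$p
    approx <- mann_whitney_u(a, b)$p     # n = 13-14: approximation path
    worst <- max(worst, abs(exact - approx))
  }
  expect_lt(worst, 0.02)
})

test_that("Wilcoxon signed-rank: exact enumeration, symmetry, zero handling", {
  expect_equal(wilcoxon_signed_rank(c(2.5, -2.5))$p, 1)
  r <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6))
  expect_equal(r$p, 2 / 64)            # all-positive sign pattern
  expect_equal(r$method, "exact enumeration")
  expect_equal(wilcoxon_signed_rank(-c(1, 2, 3, 4, 5, 6))$p, 2 / 64)
  expect_error(wilcoxon_signed_rank(c(0, 0, 0)), "zero")
  # zeros dropped before ranking
  expect_equal(wilcoxon_signed_rank(c(0, 1, 2, 3, 4, 5, 6))$n_nonzero, 6L)
  # independent sign-pattern oracle, with ties
  set.seed(9)
  for (rep in 1:6) {
    d <- sample(c(-3, -2, -1, 1, 2, 3), 7, replace = TRUE)
    expect_equal(wilcoxon_signed_rank(d)$p, oracle_wsr_exact(d),
                 tolerance = 1e-12)
  }
  # matches stats::wilcox.test exact p on untied differences
  set.seed(10)
  d <- rnorm(9) + 0.8
  expect_equal(wilcoxon_signed_rank(d)$p,
               stats::wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-9)
})

test_that("Wilcoxon normal approximation tracks exact enumeration", {
  set.seed(11)
  worst <- 0
  for (rep in 1:40) {
    n <- 16 + (rep %% 2)                 # just above the enumeration window
    d <- rnorm(n, 0.3)
    exact <- wilcoxon_signed_rank(d, exact_max = 20L)$p
    approx <- wilcoxon_signed_rank(d)$p
    worst <- max(worst, abs(exact - approx))
  }
  expect_lt(worst, 0.02)
})

test_that("class score summaries report per-class moments and MW p", {
  lib <- ranked_library(1:6, c(-9, -9, -9, -8, -8, -8),
                        c(rep("active", 3), rep("decoy", 3)))
  s <- score_class_summary(lib)
  expect_equal(s$abs_diff, 1)
  expect_equal(s$mean_active, -9)
  expect_equal(s$sd_decoy, 0)
  # swapping labels swaps the class summaries
  swapped <- ranked_library(1:6, c(-9, -9, -9, -8, -8, -8),
                            c(rep("decoy", 3), rep("active", 3)))
  s2 <- score_class_summary(swapped)
  expect_equal(s2$mean_active, s$mean_decoy)
  expect_equal(s2$mean_decoy, s$mean_active)
  expect_equal(s2$abs_diff, s$abs_diff)
  expect_error(score_class_summary(mk_lib(rep("active", 4))), "no decoys")
})

test_that("metric_report bundles the five ranking metrics coherently", {
  lib <- synth_ranked_library(40, 1960, seed = 31)
  rep_ <- metric_report(lib)
  expect_named(rep_, c("ef_1pct", "ef_10pct", "bedroc20", "auc", "act50"))
  expect_equal(rep_$ef_1pct, enrichment_factor(lib, 0.01))
  expect_equal(rep_$auc, enrichment_auc(lib))
  expect_true(rep_$act50 > 0 && rep_$act50 <= 1)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_metric_report(rep_, p)
  back <- read.delim(p)
  expect_equal(back$bedroc20, rep_$bedroc20, tolerance = 1e-12)
})
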