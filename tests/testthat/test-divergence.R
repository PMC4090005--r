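pair_map <- function(n) data.frame(gene_id_a = sprintf("a%04d", 1:n),
                                   gene_id_b = sprintf("b%04d", 1:n),
                                   stringsAsFactors = FALSE)

sig_tab <- function(ids, values, valid = TRUE)
  data.frame(gene_id = ids, value = values, valid = valid,
             stringsAsFactors = FALSE)

test_that("paired signals keep doubly-valid orthologs and subtract A - B", {
  om <- pair_map(4)
  sa <- sig_tab(om$gene_id_a, c(1, 2, 3, NA))
  sb <- sig_tab(om$gene_id_b, c(1, 1, 2, 5), valid = c(TRUE, TRUE, FALSE, TRUE))
  p <- paired_region_signals(sa, sb, om)
  expect_equal(p$gene_id_a, om$gene_id_a[1:2])
  expect_equal(p$d, c(0, 1))
  expect_error(paired_region_signals(sig_tab(om$gene_id_a, rep(NA_real_, 4)),
                                     sb, om), "no ortholog")
})

test_that("interspecies profile correlation handles identity and antithesis", {
  set.seed(71)
  m <- matrix(rnorm(500 * 8), 500, 8)
  r <- interspecies_profile_correlation(m, m)
  expect_equal(unname(r$per_bin), rep(1, 8))
  expect_equal(r$overall, 1)
  r2 <- interspecies_profile_correlation(m, -m)
  expect_equal(unname(r2$per_bin), rep(-1, 8))
  m2 <- matrix(rnorm(500 * 8), 500, 8)
  r3 <- interspecies_profile_correlation(m, m2)
  expect_gte(mean(abs(r3$per_bin) < 0.1), 0.9)
  expect_error(interspecies_profile_correlation(m[1:2, ], m2[1:2, ]), "3")
})

test_that("exceedance curves are monotone with the normal closed form", {
  d <- numeric(100)
  exc <- divergence_exceedance(d, c(0.1, 0.5, 1))
  expect_equal(exc$percent, c(0, 0, 0))
  set.seed(81)
  dn <- rnorm(50000, 0, 0.7)
  exc2 <- divergence_exceedance(dn, c(0, 0.7, 1.4))
  expect_equal(exc2$percent[1], 100)
  expect_equal(exc2$percent[2], 100 * 2 * (1 - pnorm(1)), tolerance = 1)
  expect_true(all(diff(exc2$percent) <= 0))
})

test_that("Lowess extraction equals a residual-ranking oracle and is symmetric", {
  set.seed(91)
  n <- 400L
  ids <- sprintf("g%04d", 1:n)
  x <- rnorm(n, 5, 1.5)
  y <- x + rnorm(n, 0, 0.2)
  y[1] <- x[1] + 3  # single strong outlier above the curve
  out <- lowess_divergent_genes(x, y, ids, n_per_side = 20)
  expect_equal(out$set_b_high[1], ids[1])
  expect_length(intersect(out$set_a_high, out$set_b_high), 0)

  # swapping the species swaps the two sets (up to the change of regression
  # direction, which can move a few marginal genes)
  sw <- lowess_divergent_genes(y, x, ids, n_per_side = 20)
  expect_equal(sw$set_a_high[1], out$set_b_high[1])  # the outlier flips sides
  expect_gte(length(intersect(sw$set_a_high, out$set_b_high)) / 20, 0.75)
  expect_gte(length(intersect(sw$set_b_high, out$set_a_high)) / 20, 0.75)

  # residual-ranking oracle on random instances
  for (seed in 1:10) {
    set.seed(seed)
    x <- rnorm(300); y <- 0.5 * x + rnorm(300, 0, 0.5)
    ids <- sprintf("g%03d", 1:300)
    got <- lowess_divergent_genes(x, y, ids, n_per_side = 40)
    fit <- lowess(x, y, f = 0.3, iter = 2)
    resid <- y - approx(fit$x, fit$y, xout = x, ties = mean)$y
    expect_setequal(got$set_b_high, ids[order(-resid)][1:40])
    expect_setequal(got$set_a_high, ids[order(resid)][1:40])
  }
  expect_error(lowess_divergent_genes(x, y, ids, n_per_side = 200), "large")
})

test_that("pairwise change classes follow flags and signs", {
  cc <- classify_change_pair(c(0, 0.5, 0.5, 0.5, -0.5, 0.2),
                             c(0, -0.5, 0.5, 0.1, -0.6, 0.9))
  expect_equal(as.character(cc$labels),
               c("none", "opposite", "consistent", "only_first",
                 "consistent", "only_second"))
  expect_equal(sum(cc$proportions), 1)

  # species swap negates both differences but preserves every category
  set.seed(101)
  d1 <- rnorm(500, 0, 0.5); d2 <- rnorm(500, 0, 0.5)
  a <- classify_change_pair(d1, d2)
  b <- classify_change_pair(-d1, -d2)
  expect_identical(a$labels, b$labels)
  # and is invariant to gene order
  p <- sample(500)
  expect_identical(as.character(classify_change_pair(d1[p], d2[p])$labels),
                   as.character(a$labels)[p])
})

test_that("change-class proportions match normal orthant probabilities", {
  set.seed(111)
  n <- 1e5
  d1 <- rnorm(n, 0, 0.4); d2 <- rnorm(n, 0, 0.4)
  got <- classify_change_pair(d1, d2, 0.4)$proportions
  p_sig <- 2 * (1 - pnorm(1))  # P(|d| > 0.4) at sd 0.4
  expected <- c(none = (1 - p_sig)^2,
                only_first = p_sig * (1 - p_sig),
                only_second = p_sig * (1 - p_sig),
                consistent = 2 * (p_sig / 2)^2,
                opposite = 2 * (p_sig / 2)^2)
  se <- sqrt(expected * (1 - expected) / n)
  expect_true(all(abs(got - expected) < 3 * se + 1e-12))
})

test_that("gated correlation and consistency curves behave at the extremes", {
  set.seed(121)
  d <- rnorm(2000, 0, 0.8)
  expect_equal(threshold_gated_correlation(d, d, 0.4), 1)
  cons <- consistency_vs_threshold(d, d, 0.4, c(0, 0.5, 1))
  expect_equal(cons$percent, c(100, 100, 100))
  cons2 <- consistency_vs_threshold(d, -d, 0.4, c(0, 0.5))
  expect_equal(cons2$percent, c(0, 0))
  # independent signs sit near 50%
  d2 <- rnorm(2000, 0, 0.8)
  cons3 <- consistency_vs_threshold(d, d2, 0.4, 0.4)
  expect_gt(cons3$percent, 40)
  expect_lt(cons3$percent, 60)
  expect_error(threshold_gated_correlation(d, numeric(2000), 0.4), "gate")
})

test_that("divergent-gene enrichment rises only under true coupling", {
  set.seed(131)
  n <- 4000L
  d_expr <- rnorm(n, 0, 0.8)
  fold0 <- divergent_enrichment_curve(d_expr, rnorm(n, 0, 0.8), 500,
                                      c(0.4, 0.8))
  expect_true(all(abs(fold0$fold - 1) < 0.35))
  # full coupling: every divergent gene passes while non-divergent genes
  # thin out, so the fold rises monotonically until the denominator empties
  fold1 <- divergent_enrichment_curve(d_expr, d_expr, 2000, c(0.1, 0.3, 0.5))
  expect_true(all(diff(fold1$fold) >= 0))
  expect_gt(fold1$fold[3], 3)
  # an emptied denominator is masked, not infinite
  fold2 <- divergent_enrichment_curve(d_expr, d_expr, 500, 1.0)
  expect_true(is.na(fold2$fold))
})

test_that("triple classification matches the enumeration oracle", {
  grid <- expand.grid(a = c(-1, 0, 1), m = c(-1, 0, 1), e = c(-1, 0, 1))
  got <- triple_classification(grid$a, grid$m, grid$e, 0.4)
  want <- mapply(oracle_triple_label, grid$a, grid$m, grid$e, 0.4)
  expect_equal(as.character(got), unname(want))
  # the labels partition: exactly one label each, all levels meaningful
  expect_false(any(is.na(got)))
  # trivial archetypes
  expect_equal(as.character(triple_classification(1, 1, 1)), "all_consistent")
  expect_equal(as.character(triple_classification(0, 0.8, 0.8)),
               "me_expr_not_ac")
})
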