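fake_signals <- function(ids, values, valid = TRUE) {
  data.frame(gene_id = ids, region = "peak", value = values,
             valid = valid & !is.na(values), stringsAsFactors = FALSE)
}

fake_genes <- function(ids, lengths) {
  data.frame(gene_id = ids, chrom = "chr1", strand = "+",
             tss = seq_along(ids) * 4000L,
             tts = seq_along(ids) * 4000L + lengths,
             length = lengths, stringsAsFactors = FALSE)
}

test_that("disparity ratios are ac minus me with the length gate", {
  ids <- c("a", "b", "c")
  g <- fake_genes(ids, c(1000L, 699L, 1000L))
  r <- disparity_ratios(fake_signals(ids, c(5, 5, 3)),
                        fake_signals(ids, c(5, 1, 1)), g)
  expect_equal(r$ratio, c(0, NA, 2))  # 699 bp gene stays unassigned
  expect_equal(r$sector, rep("unassigned", 3))

  # an invalid signal propagates to an undefined ratio
  r2 <- disparity_ratios(fake_signals(ids, c(5, 5, NA)),
                         fake_signals(ids, c(5, 1, 1)), g)
  expect_true(is.na(r2$ratio[3]))
})

test_that("sector assignment partitions ranked genes deterministically", {
  set.seed(41)
  n <- 3600L
  ids <- sprintf("g%04d", 1:n)
  g <- fake_genes(ids, rep(1000L, n))
  ratios <- rnorm(n)
  rec <- disparity_ratios(fake_signals(ids, ratios),
                          fake_signals(ids, numeric(n)), g)
  out <- assign_sectors(rec, 1200L)
  expect_equal(unname(table(out$sector)[c("high_ac", "mid", "high_me")]),
               rep(1200L, 3), ignore_attr = TRUE)
  expect_true(min(out$ratio[out$sector == "high_ac"]) >
                max(out$ratio[out$sector == "mid"]))
  expect_true(min(out$ratio[out$sector == "mid"]) >
                max(out$ratio[out$sector == "high_me"]))

  # invariant to input order
  perm <- sample(n)
  out2 <- assign_sectors(rec[perm, ], 1200L)
  expect_equal(out2$sector[order(perm)], out$sector)

  # all-equal ratios: the tie-break still yields exact sizes
  rec3 <- disparity_ratios(fake_signals(ids, rep(1, n)),
                           fake_signals(ids, numeric(n)), g)
  out3 <- assign_sectors(rec3, 1200L)
  expect_equal(sum(out3$sector == "high_ac"), 1200L)
  out3b <- assign_sectors(rec3[sample(n), ], 1200L)
  expect_equal(out3b$sector[match(out3$gene_id, out3b$gene_id)], out3$sector)

  # adding a constant to ac shifts ratios but not membership
  rec4 <- rec
  rec4$ratio <- rec4$ratio + 5
  out4 <- assign_sectors(rec4, 1200L)
  expect_equal(out4$sector, out$sector)

  expect_error(assign_sectors(rec[1:100, ], 1200L), "too few")
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  # N=10, K=4, n=5, k=4: 6 of the choose(10,5)=252 draws contain all 4
  uni <- sprintf("u%02d", 1:10)
  res <- hypergeom_enrichment(uni[1:5], uni[2:5], uni)
  expect_equal(res$p_enrich, 1 / 42, tolerance = 1e-12)

  # class == universe: expected overlap, fe 0, p_enrich 1
  res2 <- hypergeom_enrichment(uni[1:5], uni, uni)
  expect_equal(res2$fe, 0)
  expect_equal(res2$p_enrich, 1)

  # enumeration oracle over a grid of small problems
  for (N in c(6L, 9L)) {
    uni <- sprintf("u%02d", 1:N)
    for (K in 1:(N - 1)) for (n in 1:(N - 1)) {
      cls <- uni[1:K]
      sec <- uni[1:n]
      k <- length(intersect(sec, cls))
      got <- hypergeom_enrichment(sec, cls, uni)
      ora <- oracle_hypergeom_enum(N, K, n, k)
      expect_equal(got$p_enrich, unname(ora["p_enrich"]), tolerance = 1e-12)
      expect_equal(got$p_deplete, unname(ora["p_deplete"]), tolerance = 1e-12)
    }
  }
  expect_error(hypergeom_enrichment(character(0), uni[1:2], uni), "empty")
})

test_that("concordance fraction counts genes near the median ratio", {
  ids <- sprintf("g%d", 1:4)
  g <- fake_genes(ids, rep(1000L, 4))
  rec <- disparity_ratios(fake_signals(ids, c(0, 0, 0, 10)),
                          fake_signals(ids, numeric(4)), g)
  expect_equal(concordance_fraction(rec, 0.5), 75)
  rec2 <- disparity_ratios(fake_signals(ids, rep(2, 4)),
                           fake_signals(ids, numeric(4)), g)
  expect_equal(concordance_fraction(rec2, 0.5), 100)

  # normal ratios: closed form 2*Phi(0.5) - 1 at sd 1
  set.seed(51)
  n <- 20000L
  idsn <- sprintf("g%05d", 1:n)
  gn <- fake_genes(idsn, rep(1000L, n))
  recn <- disparity_ratios(fake_signals(idsn, rnorm(n)),
                           fake_signals(idsn, numeric(n)), gn)
  expect_equal(concordance_fraction(recn, 0.5),
               100 * (2 * pnorm(0.5) - 1), tolerance = 0.05)
})

test_that("class means separate along the planted disparity axis", {
  set.seed(61)
  n <- 400L
  ids <- sprintf("g%04d", 1:n)
  g <- fake_genes(ids, rep(1000L, n))
  base <- rnorm(n, 5, 1)
  opn <- ids[1:100]
  ac <- base + ifelse(ids %in% opn, 1, 0) + rnorm(n, 0, 0.2)
  me <- base + rnorm(n, 0, 0.2)
  rec <- disparity_ratios(fake_signals(ids, ac), fake_signals(ids, me), g)
  classes <- data.frame(gene_id = c(opn, ids[101:200]),
                        class_name = rep(c("OPN", "other"), each = 100))
  gm <- group_mean_disparity(rec, classes)
  d <- gm$means$mean_ac - gm$means$mean_me
  expect_gt(d[gm$means$class_name == "OPN"],
            d[gm$means$class_name == "other"] + 0.5)

  # classes sharing all genes have identical means
  cls2 <- data.frame(gene_id = rep(ids[1:50], 2),
                     class_name = rep(c("x", "y"), each = 50))
  gm2 <- group_mean_disparity(rec, cls2)
  expect_equal(gm2$means$mean_ac[1], gm2$means$mean_ac[2])
})
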