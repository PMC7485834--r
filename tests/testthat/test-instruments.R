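test_that("significance filtering is strict at the threshold", {
  tab <- make_tab(c("rs1", "rs2", "rs3"), 0.1, 0.01,
                  pval = c(1e-9, 5e-8, 1e-3))
  kept <- select_significant(tab)
  expect_equal(kept$snp_id, "rs1")
  all_null <- make_tab(c("rs1", "rs2"), 0.1, 0.01, pval = 0.5)
  expect_equal(nrow(select_significant(all_null)), 0)
  # in a simulated study the filter keeps strongly-driven causal SNPs and
  # almost nothing else (the spike-and-slab leaves some causal effects too
  # small to detect; those are not expected to pass)
  s <- sim_h(fast_config(seed = 5))
  tm <- s$truth
  het <- 2 * tm$maf * (1 - tm$maf)
  ncp <- het * tm$beta[, 1]^2 * 2e5  # expected chi-square noncentrality
  strong <- tm$snp_id[ncp > 60]
  expect_true(all(strong %in% s$h$snp$snp_id))
  expect_gt(mean(s$h$snp$snp_id %in% tm$snp_id[tm$causal]), 0.95)
})

test_that("LD clumping keeps the best p-value SNP within a block", {
  tab <- make_tab(c("rs1", "rs2"), 0.1, 0.01, pval = c(1e-10, 1e-9))
  r2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  res <- ld_clump(tab, ld_matrix(c("rs1", "rs2"), r2))
  expect_equal(res$table$snp_id, "rs1")
  expect_equal(res$log$snp_id, "rs2")
  # identity matrix keeps everything
  ids <- paste0("rs", 1:4)
  tab4 <- make_tab(ids, 0.1, 0.01, pval = c(1e-9, 1e-8, 1e-10, 1e-7))
  res4 <- ld_clump(tab4, ld_matrix(ids, diag(4)))
  expect_setequal(res4$table$snp_id, ids)
  # SNPs absent from the matrix are dropped, not assumed independent
  res3 <- ld_clump(tab4, ld_matrix(ids[1:3], diag(3)))
  expect_setequal(res3$table$snp_id, ids[1:3])
  expect_equal(res3$log$reason[res3$log$snp_id == "rs4"], "absent_from_ld")
})

test_that("greedy clumping matches the brute-force subset oracle on a 6-SNP toy", {
  # two LD blocks ({rs1,rs2,rs3} and {rs4,rs5}) plus one free SNP
  ids <- paste0("rs", 1:6)
  r2 <- diag(6)
  r2[1, 2] <- r2[2, 1] <- 0.8
  r2[1, 3] <- r2[3, 1] <- 0.4
  r2[2, 3] <- r2[3, 2] <- 0.9
  r2[4, 5] <- r2[5, 4] <- 0.6
  pv <- c(1e-8, 1e-12, 1e-10, 1e-9, 1e-11, 1e-7)
  tab <- make_tab(ids, 0.1, 0.01, pval = pv)
  got <- sort(ld_clump(tab, ld_matrix(ids, r2), r2_threshold = 0.001)$table$snp_id)

  # oracle: enumerate all 2^6 subsets; among maximal pairwise-independent
  # sets, the greedy-by-p solution has the lexicographically smallest
  # member-rank sequence
  rank_of <- order(order(pv, ids))
  best <- NULL
  for (mask in 0:(2^6 - 1)) {
    s <- which(bitwAnd(mask, 2^(0:5)) > 0)
    if (length(s) == 0) next
    pairs_ok <- all(r2[s, s][upper.tri(diag(length(s)))] < 0.001)
    if (!pairs_ok) next
    maximal <- all(vapply(setdiff(1:6, s), function(j) {
      any(r2[j, s] >= 0.001)
    }, logical(1)))
    if (!maximal) next
    key <- sort(rank_of[s])
    if (is.null(best) ||
        paste(formatC(key, width = 2, flag = "0"), collapse = "") <
        paste(formatC(best, width = 2, flag = "0"), collapse = "")) {
      best <- key
      best_set <- s
    }
  }
  expect_equal(got, sort(ids[best_set]))
  # pairwise independence of the returned set
  idx <- match(got, ids)
  expect_true(all(r2[idx, idx][upper.tri(diag(length(idx)))] < 0.001))
})

test_that("clumping ties on p are broken lexicographically by rsID", {
  ids <- c("rsB", "rsA")
  tab <- make_tab(ids, 0.1, 0.01, pval = c(1e-9, 1e-9))
  r2 <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(ids, ids))
  res <- ld_clump(tab, ld_matrix(ids, r2))
  expect_equal(res$table$snp_id, "rsA")
})

test_that("malformed LD matrices are rejected", {
  expect_error(ld_matrix("rs1", matrix(0.5)), "diagonal")
  expect_error(ld_matrix("rs1", matrix(2)), "\\[0, 1\\]")
  expect_error(ld_matrix(c("rs1", "rs2"), matrix(c(1, 0.2, 0.4, 1), 2)),
               "symmetric")
  expect_error(ld_matrix(c("rs1", "rs2"), matrix(c(1, 1.5, 1.5, 1), 2)),
               "\\[0, 1\\]")
})

test_that("LD matrices read from square and long TSV agree", {
  sq <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp\trs1\trs2\trs3",
               "rs1\t1\t0.5\t0",
               "rs2\t0.5\t1\t0.2",
               "rs3\t0\t0.2\t1"), sq)
  lg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp_a\tsnp_b\tr2", "rs1\trs2\t0.5", "rs2\trs3\t0.2"), lg)
  a <- read_ld_matrix(sq)
  b <- read_ld_matrix(lg)
  expect_equal(a$r2[a$snp_ids, a$snp_ids], b$r2[a$snp_ids, a$snp_ids])
})

test_that("cross-trait pruning removes instruments associated elsewhere", {
  target <- make_tab(paste0("rs", 1:4), 0.1, 0.01, pval = 1e-10, trait = "ldl")
  other1 <- make_tab(paste0("rs", 1:3), 0.1, 0.01,
                     pval = c(0.5, 1e-4, 0.002), trait = "hdl")
  other2 <- make_tab(paste0("rs", c(1, 3)), 0.1, 0.01,
                     pval = c(0.9, 5e-5), trait = "tg")
  res <- cross_trait_prune(target, list(other1, other2))
  # rs2 hits in hdl, rs3 in tg; rs4 absent everywhere is kept
  expect_setequal(res$table$snp_id, c("rs1", "rs4"))
  expect_setequal(res$log$snp_id, c("rs2", "rs3"))
  expect_equal(res$log$reason[res$log$snp_id == "rs2"], "associated_with_hdl")
})

test_that("heterogeneity pruning removes the dominant Q outlier first", {
  # 4 instruments with ratio 0.5 and one gross outlier at ratio 5 with a
  # small SE: its Q contribution dominates by hand computation
  h <- make_h(bx = rep(1, 5), sx = 0.01,
              by = c(0.5, 0.51, 0.49, 0.5, 5), sy = c(rep(0.05, 4), 0.05))
  pr <- heterogeneity_prune(h, q_alpha = 0.05)
  expect_equal(pr$log$snp_id[1], "rs005")
  expect_false("rs005" %in% pr$set$snp$snp_id)
  # a homogeneous set is untouched (Q = 0)
  h0 <- make_h(bx = rep(1, 4), sx = 0.01, by = rep(0.5, 4), sy = 0.05)
  pr0 <- heterogeneity_prune(h0)
  expect_equal(nrow(pr0$log), 0)
  expect_equal(n_instruments(pr0$set), 4)
})

test_that("heterogeneity pruning decreases Q monotonically and respects min_k", {
  set.seed(9)
  k <- 12
  h <- make_h(bx = runif(k, 0.5, 1.5), sx = 0.01,
              by = 0.3 * runif(k, 0.5, 1.5) + rnorm(k, 0, 0.1), sy = 0.02)
  qs <- c()
  hh <- h
  repeat {
    re <- ratio_estimates(hh)
    fit <- lipidmr:::ivw_kernel(re$r, re$w)
    qs <- c(qs, fit$Q)
    p <- pchisq(fit$Q, nrow(re) - 1, lower.tail = FALSE)
    if (p >= 0.05 || nrow(re) <= 3) break
    hh <- lipidmr:::subset_harmonized(hh, -which.max(fit$contrib))
  }
  expect_true(all(diff(qs) < 0))
  pr <- heterogeneity_prune(h, min_k = 10)
  expect_gte(n_instruments(pr$set), 10)
  expect_error(heterogeneity_prune(make_h(1, 0.01, 0.5, 0.05), min_k = 3),
               "min_k")
  # pruning restores homogeneity on a contaminated synthetic set
  pr2 <- heterogeneity_prune(h, q_alpha = 0.05)
  re2 <- ratio_estimates(pr2$set)
  fit2 <- lipidmr:::ivw_kernel(re2$r, re2$w)
  expect_gte(pchisq(fit2$Q, nrow(re2) - 1, lower.tail = FALSE), 0.05)
})
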