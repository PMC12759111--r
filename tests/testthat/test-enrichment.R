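test_that("Fisher exact 2x2: identities and an enumeration-verified case", {
  r0 <- fisher_exact_2x2(5, 5, 5, 5)
  expect_equal(r0$odds_ratio, 1)
  expect_equal(r0$p_value, 1)

  r1 <- fisher_exact_2x2(5, 1, 2, 10)
  expect_equal(r1$odds_ratio, 25)
  expect_equal(r1$p_value, fisher_p_oracle(5, 1, 2, 10), tolerance = 1e-10)
  expect_equal(r1$p_value, fisher.test(matrix(c(5, 2, 1, 10), 2))$p.value,
               tolerance = 1e-10)
  expect_true(r1$conf_int[1] <= r1$odds_ratio && r1$odds_ratio <= r1$conf_int[2])

  # swapping rows inverts the OR and leaves p unchanged
  r1s <- fisher_exact_2x2(2, 10, 5, 1)
  expect_equal(r1s$odds_ratio, 1 / r1$odds_ratio, tolerance = 1e-12)
  expect_equal(r1s$p_value, r1$p_value, tolerance = 1e-12)

  # simultaneous row+column swap leaves both invariant
  r1rc <- fisher_exact_2x2(10, 2, 1, 5)
  expect_equal(r1rc$odds_ratio, r1$odds_ratio, tolerance = 1e-12)
  expect_equal(r1rc$p_value, r1$p_value, tolerance = 1e-12)

  # zero cells: Haldane correction for OR only, p on raw counts
  rz <- fisher_exact_2x2(0, 5, 5, 5)
  expect_true(rz$haldane)
  expect_equal(rz$odds_ratio, 0.5 * 5.5 / (5.5 * 5.5))
  expect_equal(rz$p_value, fisher.test(matrix(c(0, 5, 5, 5), 2))$p.value,
               tolerance = 1e-10)

  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "empty")
})

test_that("Fisher p equals independent enumeration over a table sweep", {
  # exhaustive for small totals; the full <= 60 sweep runs in the
  # acceptance suite
  max_diff <- 0
  for (t in 1:20) {
    for (a in 0:t) for (b in 0:(t - a)) for (c in 0:(t - a - b)) {
      d <- t - a - b - c
      diff <- abs(fisher_exact_2x2(a, b, c, d)$p_value -
                    fisher_p_oracle(a, b, c, d))
      max_diff <- max(max_diff, diff)
    }
  }
  expect_lt(max_diff, 1e-10)

  # spot-check against stats::fisher.test on random larger tables
  set.seed(50)
  for (i in 1:200) {
    cells <- rpois(4, sample(c(3, 10, 40), 1))
    if (sum(cells) == 0) next
    expect_equal(fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])$p_value,
                 fisher.test(matrix(cells, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-8)
  }
})

mk_calls <- function(cpgs, category) {
  structure(data.frame(cpg = cpgs, category = category,
                       stringsAsFactors = FALSE),
            class = c("cpg_calls", "data.frame"))
}

test_that("clock enrichment: universe restriction, planting, BH monotonicity", {
  set.seed(51)
  universe <- paste0("cg", 1:2000)
  category <- rep("neither", 2000)
  category[1:400] <- "age_associated"
  category[401:460] <- "age_varying"
  calls <- mk_calls(universe, category)

  # planted clock: mostly a subset of the age-associated category
  clock_planted <- c(sample(universe[1:400], 60), sample(universe[500:2000], 15))
  clock_null <- sample(universe, 80)
  clock_outside <- paste0("cgX", 1:50)  # entirely absent from the universe
  res <- clock_enrichment(calls, list(planted = clock_planted,
                                      null = clock_null,
                                      outside = clock_outside))
  planted_aa <- res[res$clock == "planted" & res$category == "age_associated", ]
  expect_gt(planted_aa$odds_ratio, 1)
  expect_lt(planted_aa$p, 0.05)

  outside <- res[res$clock == "outside", ]
  expect_true(all(outside$empty))
  expect_true(all(is.na(outside$p)))

  # universe restriction: counts only cover in-universe CpGs
  expect_equal(res$n_clock[res$clock == "planted"][1], 75L)
  expect_equal(planted_aa$a + planted_aa$b + planted_aa$c + planted_aa$d, 2000)

  # BH adjustment is monotone and order-preserving
  ok <- !is.na(res$p)
  expect_true(all(res$adj_p[ok] >= res$p[ok]))
  expect_true(!is.unsorted(res$adj_p[ok][order(res$p[ok])]))
})

test_that("DHS enrichment contrasts the two exclusive categories", {
  set.seed(52)
  n_av <- 3000
  n_aa <- 120000
  cpgs <- paste0("cg", seq_len(n_av + n_aa))
  calls <- mk_calls(cpgs, rep(c("age_varying", "age_associated"), c(n_av, n_aa)))
  dhs <- setNames(c(rbinom(n_av, 1, 0.6), rbinom(n_aa, 1, 0.5)), cpgs)
  res <- dhs_enrichment(calls, dhs)
  # expected OR = (0.6/0.4)/(0.5/0.5) = 1.5
  expect_equal(res$odds_ratio, 1.5, tolerance = 0.1)
  expect_lt(res$p_value, 1e-3)

  flipped <- dhs_enrichment(calls, 1 - dhs)
  expect_equal(flipped$odds_ratio, 1 / res$odds_ratio, tolerance = 1e-10)

  # identical DHS proportions in both categories: OR = 1, no signal
  dhs_eq <- setNames(c(rep_len(c(0, 1), n_av), rep_len(c(0, 1), n_aa)), cpgs)
  res_eq <- dhs_enrichment(calls, dhs_eq)
  expect_equal(res_eq$odds_ratio, 1, tolerance = 0.01)
  expect_gt(res_eq$p_value, 0.05)

  expect_error(dhs_enrichment(calls, dhs[-1]), "missing")
})

test_that("feature distribution: normalization, planting, unknown labels", {
  set.seed(53)
  feats <- c("First Exon", "5'UTR", "Exon Boundary",
             "TSS1500", "3'UTR", "Body", "IGR", "TSS200")
  n <- 10000
  cpgs <- paste0("cg", 1:n)
  calls <- mk_calls(cpgs, rep(c("age_associated", "age_varying"), c(8000, 2000)))

  # independent features: proportions rows sum to 1
  ann <- setNames(sample(feats, n, replace = TRUE), cpgs)
  fd <- feature_distribution(calls, ann)
  expect_equal(unname(rowSums(fd$proportions)), c(1, 1), tolerance = 1e-12)
  expect_gt(fd$p_value, 1e-4)

  # one category concentrated in TSS200
  ann2 <- ann
  ann2[8001:10000] <- sample(c("TSS200", feats), 2000, replace = TRUE,
                             prob = c(20, rep(1, 8)))
  fd2 <- feature_distribution(calls, ann2)
  expect_lt(fd2$p_value, 1e-6)

  ann_bad <- ann
  ann_bad[1] <- "Promoter"
  expect_error(feature_distribution(calls, ann_bad), "Promoter")
})
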