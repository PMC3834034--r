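test_that("amplicon rows parse with both minus conventions", {
  tsv <- paste(
    "amplicon\tdirection\tchromosome\tstart_rel\tend_rel\tlength\tcpg_count\tleft\tright",
    "PTPRS_amp03\tF\t2\t−2509\t−2162\t348\t9\tAAA\tTTT",
    "FABP5_amp09\tF\t4\t217\t701\t485\t28\tCCC\tGGG",
    sep = "\n"
  )
  amp <- parse_amplicon_table(text = tsv)
  expect_equal(amp$start_rel, c(-2509L, 217L))
  expect_equal(amp$end_rel, c(-2162L, 701L))
  v <- validate_amplicons(amp)
  expect_true(all(v$span_ok))
  expect_equal(v$computed_span, c(348L, 485L))

  expect_error(
    parse_amplicon_table(text = "X_amp01\tF\t1\tabc\t10\t10\t1\tA\tT"),
    "X_amp01")
})

test_that("span convention: no position 0, inclusive ends", {
  expect_equal(amplicon_span(1L, 1L), 1L)                  # start == end
  expect_equal(amplicon_span(-10L, -1L), 10L)              # both negative
  expect_equal(amplicon_span(-322L, 122L), 444L)           # crossing zero
  expect_equal(amplicon_span(217L, 701L), 485L)            # both positive
  expect_error(amplicon_span(0L, 5L))
})

test_that("the bundled amplicon table audit flags the inconsistent rows", {
  amp <- parse_amplicon_table(amplicon_table_path())
  expect_equal(nrow(amp), 38)
  expect_warning(v <- validate_amplicons(amp), "PPP1R3E_amp07")
  expect_equal(v$computed_span[v$amplicon == "PTPRS_amp03"], 348L)
  expect_true(v$span_ok[v$amplicon == "PTPRS_amp03"])
  expect_true(v$span_ok[v$amplicon == "PTPRS_amp25"])
  expect_false(v$span_ok[v$amplicon == "PPP1R3E_amp07"])
  expect_equal(v$computed_span[v$amplicon == "PPP1R3E_amp07"], 147L)
  expect_setequal(v$amplicon[!v$span_ok],
                  c("PPP1R3E_amp07", "FGFR4_amp26"))
})

test_that("observed differences are plain two-group mean differences", {
  mk <- function(rows) {
    methylation_matrix(matrix(rows, ncol = 6, byrow = TRUE),
                       c(rep("experimental", 3), rep("control", 3)))
  }
  expect_equal(unname(observed_difference(mk(rep(0.5, 6)))), 0)
  expect_equal(unname(observed_difference(mk(c(0.8, 0.7, 0.9, 0.4, 0.5, 0.3)))),
               0.4)
  # random table vs direct two-mean oracle at every site
  tab <- generate_methylation_table(50, 3, effect_sites = 1:10, seed = 8)
  d <- observed_difference(tab)
  oracle <- apply(tab$values, 1,
                  function(v) mean(v[1:3]) - mean(v[4:6]))
  expect_equal(unname(d), unname(oracle))
  # one group fully missing at a site: NA with warning
  vals <- matrix(0.5, 2, 6); vals[2, 1:3] <- NA
  mm2 <- methylation_matrix(vals, c(rep("experimental", 3),
                                    rep("control", 3)))
  expect_warning(d2 <- observed_difference(mm2), "skipped")
  expect_true(is.na(d2[2]))
})

test_that("exhaustive permutation p-values match the enumeration oracle", {
  mm <- methylation_matrix(
    matrix(c(0.1, 0.2, 0.3, 0.95, 0.96, 0.97,   # fully separated
             0.50, 0.55, 0.45, 0.52, 0.48, 0.50, # null-ish
             rep(0.4, 6)),                        # constant
           nrow = 3, byrow = TRUE),
    c(rep("experimental", 3), rep("control", 3)))
  res <- permutation_test(mm, alpha = 0.1)
  expect_equal(res$mode, "exhaustive")
  expect_equal(res$n_relabelings, 20)
  # separated fixture: only the true split and its mirror reach |diff|
  expect_equal(res$sites$p[1], 2 / 20)
  expect_true(res$sites$significant[1])
  # constant site: p = 1
  expect_equal(res$sites$p[3], 1)
  # every site agrees with the brute-force oracle
  for (i in 1:3) {
    expect_equal(res$sites$p[i], perm_oracle_p(mm$values[i, ], 3))
  }
  # exhaustive results are seed-invariant
  res2 <- permutation_test(mm, alpha = 0.1, seed = 999)
  expect_identical(res$sites, res2$sites)
  expect_equal(res$min_attainable_p, 0.1)
})

test_that("Monte-Carlo p converges to the exhaustive value", {
  tab <- generate_methylation_table(5, 3, effect_sites = 1:2,
                                    effect_size = 0.15, noise_sd = 0.08,
                                    seed = 4)
  ex <- permutation_test(tab)
  mc <- permutation_test(tab, n_perm = 2000L, seed = 2, exhaustive_cap = 1L)
  expect_equal(mc$mode, "monte-carlo")
  expect_true(all(mc$sites$p >= 1 / 2001 & mc$sites$p <= 1))
  tol <- 3 * sqrt(ex$sites$p * (1 - ex$sites$p) / 2000) + 1e-3
  expect_true(all(abs(mc$sites$p - ex$sites$p) <= tol))
})

test_that("type-I error sits at the attainable level on null tables", {
  tab <- generate_methylation_table(1000, 3, noise_sd = 0.05, seed = 10)
  res <- permutation_test(tab, alpha = 0.1)
  rate <- mean(res$sites$p <= 0.1)
  # binomial 99% band around the attainable level 0.1
  half <- 2.576 * sqrt(0.1 * 0.9 / 1000)
  expect_gt(rate, 0.1 - half)
  expect_lt(rate, 0.1 + half)
})

test_that("the exhaustive test attains its minimal p on strong effects", {
  hits <- 0L; total <- 0L
  for (s in 1:200) {
    tab <- generate_methylation_table(4, 3, effect_sites = 1:2,
                                      effect_size = 0.3, noise_sd = 0.05,
                                      seed = s)
    res <- permutation_test(tab)
    hits <- hits + sum(res$sites$p[1:2] == 2 / 20)
    total <- total + 2L
  }
  expect_gte(hits / total, 0.95)
})

test_that("promoter reports list significant sites by amplicon", {
  amp <- parse_amplicon_table(amplicon_table_path())
  ids <- c(sprintf("PTPRS_amp03_CpG_%d", 1:3),
           sprintf("FGFR4_amp04_CpG_%d", 1:3))
  # effect confined to the PTPRS amplicon sites; FGFR4 sites are constant
  # (p = 1 there), so the report is fully determined by construction
  vals <- rbind(
    matrix(rep(c(0.75, 0.78, 0.81, 0.40, 0.42, 0.44), 3), 3, byrow = TRUE),
    matrix(0.5, 3, 6))
  rownames(vals) <- ids
  tab <- methylation_matrix(vals, c(rep("experimental", 3),
                                    rep("control", 3)))
  res <- permutation_test(tab, alpha = 0.1)
  rep <- summarize_promoter(res, amp)
  expect_true(all(rep$amplicon == "PTPRS_amp03"))
  expect_setequal(rep$site, ids[1:3])
  expect_equal(unique(rep$start_rel), -2509L)

  # no significant sites: empty report
  null_tab <- generate_methylation_table(4, 3, noise_sd = 0.05, seed = 3,
                                         site_ids = sprintf("PTPRS_amp03_CpG_%d", 1:4))
  null_res <- permutation_test(null_tab, alpha = 0.01)  # below attainable
  expect_equal(nrow(summarize_promoter(null_res, amp)), 0)

  # unmapped ids warn
  bad <- generate_methylation_table(2, 3, effect_sites = 1:2,
                                    effect_size = 0.4, noise_sd = 0.01,
                                    seed = 4, site_ids = c("XX_1", "YY_2"))
  expect_warning(summarize_promoter(permutation_test(bad), amp), "unmapped")
})

test_that("degenerate designs are rejected", {
  expect_error(methylation_matrix(matrix(0.5, 2, 3),
                                  c("experimental", "experimental", "control")),
               "at least 2")
  expect_error(methylation_matrix(matrix(2, 2, 4),
                                  rep(c("experimental", "control"), each = 2)),
               "\\[0, 1\\]")
})
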