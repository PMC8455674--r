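toy_table <- function(p) {
  gwas_table(tibble::tibble(
    rsid = sprintf("rs%d", seq_along(p)),
    effect_allele = "A", other_allele = "G",
    beta = qnorm(p / 2, lower.tail = FALSE) * 0.01, se = 0.01, pvalue = p
  ), "toy", "binary")
}

test_that("select_instruments applies the significance threshold and sorts by p", {
  tbl <- toy_table(c(6e-8, 1e-9, 4e-8))
  sel <- select_instruments(tbl, mr_config(p_threshold = 5e-8))
  expect_equal(sel$rsid, c("rs2", "rs3"))          # ascending p
  sel6 <- select_instruments(tbl, mr_config(p_threshold = 5e-6))
  expect_equal(nrow(sel6), 3)                      # relaxed threshold keeps all
  expect_error(select_instruments(toy_table(c(0.1, 0.5)), mr_config()),
               "5e-08", class = "mrkit_selection_error")
})

test_that("greedy_clump keeps the best variant per LD block", {
  ld <- ld_table(tibble::tibble(rsid_a = "rs1", rsid_b = "rs2", r2 = 0.5))
  expect_equal(greedy_clump(c("rs1", "rs2"), ld, 0.001), "rs1")
  ld2 <- ld_table(tibble::tibble(rsid_a = "rs1", rsid_b = "rs2", r2 = 0.0005))
  expect_equal(greedy_clump(c("rs1", "rs2"), ld2, 0.001), c("rs1", "rs2"))
  # mutually unlinked: all kept
  expect_equal(greedy_clump(sprintf("rs%d", 1:7), NULL, 0.001),
               sprintf("rs%d", 1:7))
})

test_that("greedy_clump output is pairwise independent and greedily maximal", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      n <- 10
      rs <- sprintf("rs%d", 1:n)
      pairs <- t(combn(n, 2))
      keep <- runif(nrow(pairs)) < 0.3
      ld <- ld_table(tibble::tibble(rsid_a = rs[pairs[keep, 1]],
                                    rsid_b = rs[pairs[keep, 2]],
                                    r2 = runif(sum(keep), 0.1, 1)))
      out <- greedy_clump(rs, ld, 0.1)
      # pairwise independence
      if (length(out) > 1) {
        cmb <- t(combn(out, 2))
        expect_true(all(ld_r2(ld, cmb[, 1], cmb[, 2]) < 0.1))
      }
      # every dropped candidate conflicts with an earlier-kept one (the
      # dominance-order solution, checked exhaustively)
      for (rsd in setdiff(rs, out)) {
        earlier <- out[match(out, rs) < match(rsd, rs)]
        expect_true(any(ld_r2(ld, rsd, earlier) >= 0.1))
      }
    })
  }
})

test_that("substitute_proxies picks the highest-r2 qualifying proxy with stated tie-breaks", {
  p_out <- c(1e-10, 1e-20, 1e-5)
  outcome <- gwas_table(tibble::tibble(
    rsid = c("rs10", "rs11", "rs12"),
    effect_allele = "A", other_allele = "G",
    beta = qnorm(p_out / 2, lower.tail = FALSE) * 0.01, se = 0.01,
    pvalue = p_out
  ), "out", "binary")
  ld <- ld_table(tibble::tibble(
    rsid_a = c("rs1", "rs1", "rs2", "rs3", "rs3"),
    rsid_b = c("rs10", "rs11", "rs12", "rs10", "rs11"),
    r2 = c(0.85, 0.9, 0.6, 0.9, 0.9)
  ))
  res <- substitute_proxies(c("rs1", "rs2", "rs3", "rs4"), outcome, ld, 0.8)
  expect_equal(res$proxy[res$rsid == "rs1"], "rs11")  # highest r2 wins
  expect_true(is.na(res$proxy[res$rsid == "rs2"]))    # best available r2 0.6 < 0.8
  expect_equal(res$proxy[res$rsid == "rs3"], "rs11")  # tie on r2 -> smaller outcome p
  expect_true(is.na(res$proxy[res$rsid == "rs4"]))    # no LD information at all
})

test_that("palindromic allele pairs are exactly A/T and C/G", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("C", "G"))
  expect_true(is_palindromic("g", "c"))
  expect_false(is_palindromic("A", "G"))
  expect_false(is_palindromic("T", "C"))
})

test_that("flag_overlap catches identical and highly correlated instruments", {
  ld <- ld_table(tibble::tibble(rsid_a = "rs2", rsid_b = "rs20", r2 = 0.9))
  expect_equal(flag_overlap(c("rs1", "rs2", "rs3"), c("rs1", "rs20"), ld, 0.8),
               c("rs1", "rs2"))
  expect_equal(flag_overlap(c("rs1", "rs2"), c("rs8", "rs9"), NULL, 0.8),
               character(0))
  expect_error(flag_overlap(character(0), "rs1"), class = "mrkit_input_error")
})

test_that("mean F-statistic matches its per-variant definition and bounds", {
  one <- make_hset(0.1, 0.01, 0.2, 0.05)
  expect_equal(mean_f_statistic(one)$mean_f, 100)
  two <- make_hset(c(sqrt(50) * 0.01, sqrt(150) * 0.01), c(0.01, 0.01), c(0, 0), c(1, 1))
  expect_equal(mean_f_statistic(two)$mean_f, 100)
  rnd <- random_hset(25, seed = 5)
  fs <- mean_f_statistic(rnd)
  expect_gte(fs$mean_f, min(fs$per_snp$f))
  expect_lte(fs$mean_f, max(fs$per_snp$f))
})

test_that("configuration validates thresholds and reads from YAML", {
  expect_error(mr_config(proxy_r2 = 0.001, clump_r2 = 0.01), class = "mrkit_config_error")
  expect_error(mr_config(p_threshold = 0), class = "mrkit_config_error")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("p_threshold: 5.0e-6", "clump_r2: 0.001", "proxy_r2: 0.8",
               "palindrome_maf_max: 0.42"), path)
  cfg <- read_mr_config(path)
  expect_equal(cfg$p_threshold, 5e-6)
  writeLines("not_a_key: 1", path)
  expect_error(read_mr_config(path), "not_a_key", class = "mrkit_config_error")
})
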