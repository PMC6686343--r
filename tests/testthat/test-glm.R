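test_that("binomial fit recovers closed-form solutions", {
  # intercept-only, pooled 30 methylated of 60 scored -> logit(0.5) = 0
  d0 <- data.frame(methylated = c(10L, 10L, 10L), scored = c(20L, 20L, 20L))
  f0 <- fit_binomial(character(0), d0)
  expect_equal(unname(f0$coefficients$estimate[1]), 0, tolerance = 1e-10)
  expect_equal(f0$k, 1L)

  # two groups: slope equals the logit difference of group proportions
  d <- data.frame(methylated = c(10L, 14L, 20L, 28L),
                  scored = rep(40L, 4),
                  grp = factor(rep(c("a", "b"), each = 2)))
  f <- fit_binomial("grp", d)
  p1 <- 24 / 80; p2 <- 48 / 80
  est <- f$coefficients$estimate
  expect_equal(unname(est[1]), qlogis(p1), tolerance = 1e-8)
  expect_equal(unname(est[2]), qlogis(p2) - qlogis(p1), tolerance = 1e-8)
  # log-likelihood includes the combinatorial constant
  ll_manual <- sum(dbinom(d$methylated, d$scored,
                          rep(c(p1, p2), each = 2), log = TRUE))
  expect_equal(f$loglik, ll_manual, tolerance = 1e-8)
})

test_that("rank-deficient designs fail with the aliased column named", {
  d <- data.frame(methylated = c(5L, 6L, 7L, 8L), scored = rep(20L, 4),
                  x = factor(c("a", "a", "b", "b")),
                  y = factor(c("u", "u", "v", "v")))   # y aliased with x
  expect_error(fit_binomial(c("x", "y"), d), "aliased.*y", ignore.case = TRUE)
})

test_that("AICc applies the small-sample correction and its limits", {
  expect_equal(aicc(-10, 2, 30), 24 + 12 / 27)
  expect_equal(aicc(-10, 3, 1e5), -2 * -10 + 6, tolerance = 1e-3)
  expect_warning(v <- aicc(-10, 5, 6), "undefined")
  expect_true(is.na(v))
  # AICc >= AIC always (n > k + 1)
  expect_gte(aicc(-10, 4, 20), -2 * -10 + 8)
})

test_that("model enumeration respects marginality and is deterministic", {
  m5 <- enumerate_models(c("A", "B"), marginality = TRUE)
  expect_length(m5, 5)     # {}, {A}, {B}, {A,B}, {A,B,A:B}
  expect_identical(m5[[1]], character(0))
  m8 <- enumerate_models(c("A", "B"), marginality = FALSE)
  expect_length(m8, 8)
  expect_length(enumerate_models("A"), 2)
  expect_identical(enumerate_models(c("A", "B")),
                   enumerate_models(c("A", "B")))
  expect_error(enumerate_models(letters[1:7]), "6")
  # counts match brute force up to 3 mains with all pairwise interactions
  for (nm in 1:3) {
    mains <- LETTERS[seq_len(nm)]
    ints <- if (nm >= 2) apply(combn(mains, 2), 2, paste, collapse = ":")
            else character(0)
    for (marg in c(TRUE, FALSE)) {
      expect_length(enumerate_models(mains, marginality = marg),
                    oracle_enumerate_count(mains, ints, marg))
    }
  }
})

test_that("model table weights, deltas and evidence ratios are coherent", {
  d <- data.frame(methylated = rbinom(30, 50, 0.4), scored = rep(50L, 30),
                  x = rnorm(30))
  f1 <- fit_binomial(character(0), d)
  f2 <- fit_binomial("x", d)
  tab <- model_table(list(f1, f2))
  expect_equal(sum(tab$weight), 1)
  expect_equal(tab$delta_aicc[1], 0)
  expect_true(all(diff(tab$aicc) >= 0))
  expect_true(all(diff(tab$weight) <= 0))    # ranking by AICc = by weight
  expect_equal(tab$evidence_ratio,
               exp(tab$delta_aicc / 2))
  # two equal-AICc models split the weight; delta = 2 -> e; delta = 1 -> 1.6487
  fake <- function(a) structure(list(terms = "m", loglik = -a / 2, k = 1L,
                                     n = 100L, aicc = a), class = "binom_fit")
  t2 <- model_table(list(fake(10), fake(10)))
  expect_equal(t2$weight, c(0.5, 0.5))
  t3 <- model_table(list(fake(10), fake(12)))
  expect_equal(t3$evidence_ratio[2], exp(1))
  t4 <- model_table(list(fake(10), fake(11)))
  expect_equal(t4$evidence_ratio[2], exp(0.5), tolerance = 1e-4)
})

test_that("methylation analysis assembles the frame per scope and predictor", {
  ds <- simulate_dataset(default_study_config(), seed = 42)
  ma <- run_methylation_analysis(ds, "all_sites", "scaled_load")
  expect_s3_class(ma$table, "model_table")
  expect_true(all(c("lineage", "parasite", "inbreeding", "site") %in%
                    colnames(ma$data)))
  expect_gt(nrow(ma$table), 5)
  # restricting to one site drops every site column from the design
  ma1 <- run_methylation_analysis(ds, "site1_only", "scaled_load")
  expect_equal(nlevels(ma1$data$site), 1)
  full <- attr(ma1$table, "fits")[[which.max(
    vapply(attr(ma1$table, "fits"), function(f) f$k, 0L))]]
  expect_false(any(grepl("^site", colnames(model.matrix(full$fit)))))
  expect_lt(nrow(ma1$data), nrow(ma$data))
  # single-morphotype predictor uses the raw counts
  mac <- run_methylation_analysis(ds, "all_sites", "bacterial_cysts")
  expect_equal(mac$data$parasite,
               as.numeric(ds$parasites$counts[mac$data$id, "bacterial_cysts"]))
})
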