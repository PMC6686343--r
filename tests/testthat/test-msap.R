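test_that("band patterns map onto the four methylation states", {
  b <- make_bands(matrix(c("U", "H", "I", "A"), 1, 4))
  st <- encode_states(b)
  expect_equal(unname(st$states[1, ]),
               c("UNMETHYLATED", "HEMI", "INTERNAL", "AMBIGUOUS"))
  b2 <- make_bands(matrix(NA_character_, 2, 1))
  expect_true(all(is.na(encode_states(b2)$states)))
})

test_that("MSL classification uses a strict 5% exceedance rule", {
  mk <- function(n_hemi, n_total) {
    make_states(matrix(c(rep("HEMI", n_hemi),
                         rep("UNMETHYLATED", n_total - n_hemi)),
                       ncol = 1))
  }
  expect_equal(classify_loci(mk(0, 100))$class, "NML")
  expect_equal(classify_loci(mk(10, 100))$class, "MSL")     # 0.10 > 0.05
  expect_equal(classify_loci(mk(5, 100))$class, "NML")      # 0.05 not > 0.05
  expect_equal(classify_loci(mk(6, 100))$class, "MSL")
  # AMBIGUOUS counts in the scored denominator
  st <- make_states(matrix(c("HEMI", rep("AMBIGUOUS", 9),
                             rep("UNMETHYLATED", 10)), ncol = 1))
  expect_equal(classify_loci(st)$meth_freq, 0.05)
  expect_equal(classify_loci(st)$class, "NML")
  # all-missing locus dropped with warning
  st2 <- make_states(cbind(matrix("HEMI", 3, 1), matrix(NA_character_, 3, 1)))
  expect_warning(cl <- classify_loci(st2), "dropped")
  expect_equal(nrow(cl), 1)
  expect_equal(attr(cl, "dropped"), "l2")
})

test_that("polymorphism flags require two distinct observed states", {
  st <- make_states(cbind(rep("HEMI", 4),
                          c("HEMI", "HEMI", "HEMI", "UNMETHYLATED")))
  cl <- classify_loci(st)
  expect_equal(cl$polymorphic, c(FALSE, TRUE))
})

test_that("per-individual methylation proportion excludes ambiguous and missing", {
  st <- make_states(rbind(c("HEMI", "INTERNAL", "UNMETHYLATED", "UNMETHYLATED"),
                          rep("UNMETHYLATED", 4),
                          c("HEMI", "AMBIGUOUS", NA, "UNMETHYLATED")))
  pr <- methylation_proportion(st)
  expect_equal(pr$proportion, c(0.5, 0, 0.5))
  expect_equal(pr$scored, c(4L, 4L, 2L))
  # behind the flag, AMBIGUOUS counts as unmethylated in the denominator
  pr2 <- methylation_proportion(st, include_ambiguous = TRUE)
  expect_equal(pr2$proportion[3], 1 / 3)
  # invariant to locus and individual order
  perm_l <- c(3, 1, 4, 2); perm_i <- c(2, 3, 1)
  st_p <- make_states(st$states[perm_i, perm_l])
  pr3 <- methylation_proportion(st_p)
  expect_equal(pr3$proportion, pr$proportion[perm_i])
})

test_that("group methylation percentage supports both readings of the formula", {
  # 10 methylated-pattern cells, 20 cells in the unmeth + ambiguous classes
  st <- make_states(matrix(c(rep("HEMI", 6), rep("INTERNAL", 4),
                             rep("UNMETHYLATED", 15), rep("AMBIGUOUS", 5)),
                           nrow = 1))
  ratio <- group_methylation_percentage(st, "g1")
  expect_equal(ratio$percent, 50)
  prop <- group_methylation_percentage(st, "g1", reading = "proportion")
  expect_equal(prop$percent, 100 * 10 / 30)
  expect_false(isTRUE(all.equal(ratio$percent, prop$percent)))
  # no methylated patterns -> 0 under either reading
  st0 <- make_states(matrix(rep("UNMETHYLATED", 8), 2, 4))
  expect_equal(group_methylation_percentage(st0, rep("g", 2))$percent, 0)
})

test_that("replicate error rate counts mismatching band patterns per cell", {
  set.seed(12)
  pat <- matrix(sample(c("U", "H", "I", "A"), 200, TRUE), 2, 100)
  orig <- make_bands(pat)
  expect_equal(replicate_error_rate(orig, orig)$rate, 0)
  # one flipped pattern among 2 individuals x 100 loci
  pat2 <- pat
  pat2[1, 1] <- if (pat[1, 1] == "U") "H" else "U"
  expect_equal(replicate_error_rate(orig, make_bands(pat2))$rate,
               1 / (100 * 2))
  # every pattern complemented -> maximal rate 1
  flip <- matrix(c(U = "A", H = "I", I = "H", A = "U")[pat], 2, 100,
                 dimnames = dimnames(pat))
  expect_equal(replicate_error_rate(orig, make_bands(flip))$rate, 1)
  expect_error(replicate_error_rate(orig, make_bands(
    matrix("U", 1, 1, dimnames = list("zz", "l1")))), "subset")
})

test_that("locus classification on simulated data recovers the true partition", {
  cfg <- default_study_config()
  cfg$occupancy <- cfg$occupancy * 4L    # ~500 individuals
  ds <- simulate_dataset(cfg, seed = 3)
  cl <- classify_loci(encode_states(ds$bands))
  called_msl <- cl$locus[cl$class == "MSL"]
  mis <- length(setdiff(ds$truth$msl_loci, called_msl)) +
    length(setdiff(called_msl, ds$truth$msl_loci))
  expect_lte(mis / length(ds$bands$loci), 0.02)
})
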