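test_that("genotype CSV parsing handles calls, missing sentinel and errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,site,L1_1,L1_2,L2_1,L2_2",
               "A,s1,101,101,7,7",
               "B,s1,103,101,7,7",
               "C,s1,0,0,7,8"), f)
  g <- read_genotypes(f)
  expect_equal(g$loci, c("L1", "L2"))
  expect_equal(unname(g$a1[, 1]), c(101L, 101L, NA))   # 0,0 -> missing call
  expect_equal(unname(g$a2[, 1]), c(101L, 103L, NA))   # canonicalized (min,max)
  expect_equal(g$sites, rep("s1", 3))

  writeLines(c("id,site,L1_1,L1_2", "A,s1,101,101", "A,s1,101,101"), f)
  expect_error(read_genotypes(f), "duplicate individual")
  writeLines(c("id,site,L1_1,L1_2,L2_1", "A,s1,1,1,2"), f)
  expect_error(read_genotypes(f), "odd number")
  writeLines(c("id,site,L1_1,L1_2", "A,s1,-3,1"), f)
  expect_error(read_genotypes(f), "negative allele")
  writeLines(c("id,site,L1_1,L1_2", "A,s1,0,5"), f)
  expect_error(read_genotypes(f), "0,0")
})

test_that("genotype write/read round-trips on canonicalized calls", {
  g <- make_geno(list(A = list(c(5, 2), c(1, 1)),
                      B = list(NULL, c(9, 3)),
                      C = list(c(2, 2), NULL)),
                 sites = c("s1", "s1", "s2"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(g, f)
  g2 <- read_genotypes(f)
  expect_identical(g2$a1, g$a1)
  expect_identical(g2$a2, g$a2)
  expect_identical(g2$sites, g$sites)
  expect_identical(g2$loci, g$loci)
})

test_that("band matrix round-trips, rejects non-binary cells, promotes half-missing", {
  pat <- matrix(c("U", "H", "I", "A", NA, "U"), 2, 3)
  b <- make_bands(pat)
  f <- withr::local_tempfile(fileext = ".csv")
  write_band_matrix(b, f)
  b2 <- read_band_matrix(f)
  expect_identical(b2$hpa, b$hpa)
  expect_identical(b2$msp, b$msp)

  writeLines(c("id,digest,l1", "A,HPA,2", "A,MSP,1"), f)
  expect_error(read_band_matrix(f), "non-binary")

  # one digest scored, the other not -> both become missing, with warning
  expect_warning(
    bm <- band_matrix(c("A"), c("l1"), matrix(1L), matrix(NA_integer_)),
    "promoted")
  expect_true(is.na(bm$hpa[1, 1]) && is.na(bm$msp[1, 1]))
})

test_that("q-matrix reader renormalizes small deviations and rejects large ones", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,L1,L2", "A,0.28,0.72", "B,0.9995,0.0002"), f)
  q <- read_qmatrix(f)
  expect_equal(unname(rowSums(q$q)), c(1, 1))
  expect_equal(unname(q$q[1, ]), c(0.28, 0.72))
  writeLines(c("id,L1,L2", "A,0.6,0.6"), f)
  expect_error(read_qmatrix(f), "deviate")
})

test_that("parasite reader rejects negative and missing counts", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,cysts,worms", "A,3,0", "B,0,2"), f)
  p <- read_parasites(f)
  expect_equal(unname(p$counts["A", ]), c(3L, 0L))
  writeLines(c("id,cysts", "A,-1"), f)
  expect_error(read_parasites(f), "negative")
  writeLines(c("id,cysts", "A,"), f)
  expect_error(read_parasites(f), "missing")
})

test_that("peak binarization applies height and sizing filters per bin", {
  bins <- data.frame(label = c("L1", "L2"), low = c(150, 200), high = c(151, 201))
  pk <- function(size, height, dig = "HPA", id = "A")
    data.frame(individual_id = id, digest = dig, size = size, height = height)
  base <- rbind(pk(150.2, 250), pk(150.2, 250, "MSP"))
  b <- binarize_peaks(base, pipeline_config(), bins)
  expect_equal(b$hpa["A", "L1"], 1L)
  expect_equal(b$hpa["A", "L2"], 0L)

  low_height <- rbind(pk(150.2, 99), pk(150.2, 250, "MSP"))
  b2 <- binarize_peaks(low_height, pipeline_config(), bins)
  expect_equal(b2$hpa["A", "L1"], 0L)   # below 100 RFU

  out_of_range <- rbind(pk(99.5, 500), pk(150.2, 250, "MSP"))
  b3 <- binarize_peaks(out_of_range, pipeline_config(), bins)
  expect_equal(b3$hpa["A", "L1"], 0L)   # outside 100-500 bp window

  expect_error(binarize_peaks(base, pipeline_config(),
                              data.frame(label = "X", low = 90, high = 120)),
               "analysis range")
  expect_error(binarize_peaks(base, pipeline_config(),
                              data.frame(label = c("X", "Y"),
                                         low = c(150, 150.5),
                                         high = c(151, 152))),
               "overlapping")
})

test_that("binarization is monotone: adding a peak never turns 1 into 0", {
  set.seed(404)
  bins <- data.frame(label = paste0("L", 1:10),
                     low = seq(100, 145, by = 5), high = seq(101, 146, by = 5))
  for (rep in 1:10) {
    n <- sample(5:20, 1)
    peaks <- data.frame(
      individual_id = sample(c("A", "B"), n, replace = TRUE),
      digest = sample(c("HPA", "MSP"), n, replace = TRUE),
      size = runif(n, 95, 160), height = runif(n, 50, 500))
    b1 <- suppressWarnings(binarize_peaks(peaks, pipeline_config(), bins))
    extra <- peaks[sample(n, 1), ]
    extra$size <- runif(1, 95, 160); extra$height <- runif(1, 50, 500)
    b2 <- suppressWarnings(binarize_peaks(rbind(peaks, extra),
                                          pipeline_config(), bins))
    for (d in c("hpa", "msp")) {
      m1 <- b1[[d]][b2$ids, , drop = FALSE]
      m2 <- b2[[d]]
      was1 <- !is.na(m1) & m1 == 1L
      expect_true(all(m2[was1] == 1L, na.rm = FALSE))
    }
  }
})

test_that("pipeline_config validates its invariants", {
  expect_error(pipeline_config(error_threshold = 0), "error_threshold")
  expect_error(pipeline_config(q_threshold = 1.2), "q_threshold")
  expect_error(pipeline_config(n_permutations = 10), "n_permutations")
})
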