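test_that("jaccard counts intersection over union", {
  expect_equal(jaccard(c("a", "b"), c("b", "c")), 1 / 3)
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(character(), c("a")), 0)
  e <- jaccard(character(), character())
  expect_equal(as.numeric(e), 0)
  expect_true(attr(e, "empty"))
})

test_that("generalized jaccard is sum-min over sum-max", {
  expect_equal(generalized_jaccard(c(1, 0.5, 0), c(0.5, 0.5, 0)), 2 / 3)
  e <- generalized_jaccard(c(0, 0), c(0, 0))
  expect_equal(as.numeric(e), 0)
  expect_true(attr(e, "empty"))
  expect_error(generalized_jaccard(c(a = 1), c(b = 1)), "different metabolite sets")
  expect_error(generalized_jaccard(c(a = 2), c(a = 1)), "\\[0, 1\\]")
})

test_that("both coefficients are symmetric and bounded on random sets", {
  set.seed(7)
  universe <- letters
  for (i in 1:50) {
    A <- sample(universe, sample(0:10, 1))
    B <- sample(universe, sample(0:10, 1))
    j1 <- as.numeric(jaccard(A, B))
    expect_equal(j1, as.numeric(jaccard(B, A)))
    expect_gte(j1, 0)
    expect_lte(j1, 1)
    expect_equal(j1 == 1, setequal(A, B) && length(A) > 0)
    x <- stats::runif(8)
    y <- stats::runif(8)
    g1 <- generalized_jaccard(x, y)
    expect_equal(as.numeric(g1), as.numeric(generalized_jaccard(y, x)))
    expect_gte(as.numeric(g1), 0)
    expect_lte(as.numeric(g1), 1)
    # binary reductions reduce the generalized form to plain jaccard
    bx <- round(x)
    by <- round(y)
    expect_equal(as.numeric(generalized_jaccard(bx, by)),
                 as.numeric(jaccard(which(bx > 0), which(by > 0))))
  }
})

t3_reference <- function(scan, fx) {
  fp <- deficiency_footprint(fx$model, fx$spec$folate_species)
  list(delta = fp$delta, profile = fp$profile)
}

test_that("ranking orders the purine-toy genes as ground truth dictates", {
  fx <- t3()
  scan <- scan_all_genes(fx$model, profiles = TRUE)
  ref <- t3_reference(scan, fx)
  rk <- rank_against_reference(scan, ref$delta, reference_profile = ref$profile,
                               markers = c("SAM", "BH4"))
  lookup <- function(g, col) rk[[col]][rk$gene == g]
  expect_equal(lookup("gGART", "jc"), 1)
  expect_equal(lookup("gATIC", "jc"), 5 / 7)
  expect_equal(lookup("gSIDE", "jc"), 0)
  expect_lt(which(rk$gene == "gGART"), which(rk$gene == "gATIC"))
  expect_lt(which(rk$gene == "gATIC"), which(rk$gene == "gSIDE"))
  # binary toy: generalized coefficient equals the set coefficient
  expect_equal(rk$jcg, rk$jc, tolerance = 1e-9)
  # marker flags: only purine-path knockouts block both SAM and BH4 analogs
  both <- rk$gene[rk$has_SAM & rk$has_BH4]
  expect_setequal(both, c("gPPAT", "gGART", "gMID", "gATIC", "gFTHFS"))
  expect_false(rk$has_SAM[rk$gene == "gBH4"])
})

test_that("ranking rejects candidates from a different model state", {
  fx <- t3()
  scan <- scan_all_genes(fx$model, profiles = TRUE)
  other <- scan_all_genes(knockout_genes(fx$model, "gSIDE"))
  ref <- blocked_metabolites(knockout_genes(fx$model, "gSIDE"))
  expect_error(rank_against_reference(scan, ref), "hash mismatch")
})

test_that("degenerate all-empty candidates rank stably at zero", {
  m <- t1_model()
  scan <- scan_all_genes(m)
  scan$blocked <- purrr::map(scan$blocked, function(x) character())
  scan$n_blocked <- 0L
  ref <- blocked_metabolites(m)  # empty reference
  rk <- rank_against_reference(scan, ref)
  expect_true(all(rk$jc == 0))
  expect_equal(rk$gene, sort(rk$gene))
})

test_that("the jc histogram bins the non-empty footprints", {
  fx <- t3()
  scan <- scan_all_genes(fx$model, profiles = TRUE)
  ref <- t3_reference(scan, fx)
  rk <- rank_against_reference(scan, ref$delta, reference_profile = ref$profile)
  h <- jc_histogram(rk, binwidth = 0.25)
  expect_equal(sum(h$count), sum(rk$n_blocked > 0))
  expect_equal(h$count[h$bin_lo == 0.75], sum(rk$jc > 0.75 & rk$n_blocked > 0))
  p <- ggplot2::autoplot(rk)
  expect_s3_class(p, "ggplot")
})
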