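test_that("the linear generator reproduces the documented chain", {
  fx <- make_linear(3)
  expect_equal(fx$model$reactions$id, c("EX_A1", "R1", "R2"))
  expect_equal(fx$model$reactions$gpr, c("", "g1", "g2 or g3"))
  expect_error(make_linear(1), ">= 2")
  # knockout of step k blocks everything downstream
  fed5 <- apply_medium(make_linear(5)$model, c(EX_A1 = 10))
  expect_setequal(knockout_delta(fed5, "g2")$id, c("A3", "A4", "A5"))
  # branch: knocking out only the branch gene blocks only the branch tip
  fb <- apply_medium(make_linear(5, branch = TRUE)$model, c(EX_A1 = 10))
  expect_setequal(knockout_delta(fb, "gb")$id, "B1")
  # upstream knockouts take the branch with them
  expect_true("B1" %in% knockout_delta(fb, "g1")$id)
  # step 2 sits upstream of the A3 branch point, so the tip goes too
  expect_equal(make_linear(5, branch = TRUE)$spec$knockout_deltas$g2,
               c("A3", "A4", "A5", "B1"))
  expect_setequal(knockout_delta(fb, "g2")$id, c("A3", "A4", "A5", "B1"))
})

test_that("the cofactor cycle has the documented ground truth", {
  fx <- make_cofactor_cycle()
  expect_setequal(blocked_metabolites(fx$model)$id, fx$spec$native_blocked)
  for (met in fx$spec$fluxsum_unblocked) {
    expect_false(is_blocked_fluxsum(fx$model, met))
  }
})

test_that("random fixtures are reproducible from their seed", {
  a <- make_random(8, seed = 11)
  b <- make_random(8, seed = 11)
  expect_identical(model_hash(a$model), model_hash(b$model))
  c <- make_random(8, seed = 12)
  expect_false(identical(model_hash(a$model), model_hash(c$model)))
  expect_error(make_random(13, seed = 1), "<= 12")
  # generation does not disturb the session RNG stream
  set.seed(99)
  before <- stats::runif(1)
  set.seed(99)
  invisible(make_random(8, seed = 5))
  expect_equal(stats::runif(1), before)
})

test_that("oracle handles degenerate inputs exactly", {
  # metabolite with no producing reaction
  mets <- tibble::tibble(id = c("A", "B"))
  rxn <- tibble::tibble(id = c("EX_A", "R1"), stoich = list(c(A = 1), c(A = -1, B = 1)),
                        lb = c(0, 0), ub = c(10, 100), gpr = "")
  m <- metabolic_model(mets, rxn)
  expect_true(oracle_producible(m, "B"))
  dead <- delete_reactions(m, "R1")
  expect_false(oracle_producible(dead, "B"))
  expect_error(oracle_producible(make_purine_toy()$model, "SAM", limit = 5), "limited")
  # no-exchange network: nothing is producible
  closed <- apply_medium(m, medium_spec(data.frame(id = character(), uptake = numeric())))
  expect_false(oracle_producible(closed, "B"))
})

test_that("LP producibility equals exact mode enumeration on random fixtures", {
  sizes <- rep(c(6, 8, 10, 12), length.out = 30)
  for (seed in seq_along(sizes)) {
    fx <- make_random(sizes[seed], seed = seed)
    expect_true(agreement_ok(fx$model), label = paste("native seed", seed))
    if (length(fx$model$genes)) {
      g <- fx$model$genes[1 + seed %% length(fx$model$genes)]
      expect_true(agreement_ok(knockout_genes(fx$model, g)),
                  label = paste("knockout seed", seed))
    }
  }
})

test_that("fixtures survive an SBML round trip with identical analysis", {
  for (fx in list(make_linear(4, branch = TRUE), make_cofactor_cycle(),
                  make_purine_toy(), make_random(8, seed = 3))) {
    f <- withr::local_tempfile(fileext = ".xml")
    write_sbml(fx$model, f)
    back <- read_sbml(f)
    expect_identical(model_hash(back), model_hash(fx$model))
    expect_setequal(blocked_metabolites(back)$id, blocked_metabolites(fx$model)$id)
  }
})
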