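test_that("gene knockouts disable reactions per their GPR rules", {
  m <- t1_model()
  ko <- knockout_genes(m, "g1")
  expect_equal(unlist(ko$reactions[ko$reactions$id == "R1", c("lb", "ub")],
                      use.names = FALSE), c(0, 0))
  expect_equal(ko$reactions$ub[ko$reactions$id == "R2"], 1000)

  # single isozyme knockout leaves the OR-ruled step alive
  ko2 <- knockout_genes(m, "g2")
  expect_equal(ko2$reactions$ub[ko2$reactions$id == "R2"], 1000)
  # both isozymes gone disables it
  ko23 <- knockout_genes(m, c("g2", "g3"))
  expect_equal(ko23$reactions$ub[ko23$reactions$id == "R2"], 0)

  expect_error(knockout_genes(m, "gX"), "unknown gene")
})

test_that("empty perturbations are the identity and application is pure", {
  m <- t3()$model
  expect_identical(model_hash(knockout_genes(m, character())), model_hash(m))
  h <- model_hash(m)
  k1 <- knockout_genes(m, "gGART")
  k2 <- knockout_genes(m, "gGART")
  expect_identical(model_hash(k1), model_hash(k2))
  expect_identical(model_hash(m), h)  # input untouched
})

test_that("consumer blockade hits exactly the admissible consumers", {
  fx <- t3()
  m <- fx$model
  blocked <- block_consumers(m, c("THF", "fTHF"))
  off <- blocked$reactions$id[blocked$reactions$ub == 0 & blocked$reactions$lb == 0]
  expect_setequal(off, c("R_GART", "R_ATIC", "R_FTHFS"))

  # a reversible reaction consuming the target in reverse counts as consumer
  mets <- tibble::tibble(id = c("A", "B"))
  rxn <- tibble::tibble(id = "Rrev", stoich = list(c(A = -1, B = 1)),
                        lb = -1000, ub = 1000, gpr = "")
  mm <- metabolic_model(mets, rxn)
  bb <- block_consumers(mm, "B")
  expect_equal(bb$reactions$ub, 0)

  # no-consumer target: unchanged model plus a warning
  expect_warning(out <- block_consumers(m, "SAM"), "no consuming reaction")
  expect_identical(model_hash(out), model_hash(m))

  expect_error(block_consumers(m, "NOPE"), "unknown metabolite")
})

test_that("sinks are excluded from consumer blockade", {
  s <- add_sinks(t3()$model)
  blocked <- block_consumers(s, c("THF", "fTHF"))
  sk <- blocked$reactions[blocked$reactions$sink, ]
  expect_true(all(sk$ub > 0))
})

test_that("transporter exemption spares pure relocation steps", {
  mets <- tibble::tibble(id = c("thf_c", "thf_m", "x_c"),
                         compartment = c("c", "m", "c"))
  rxn <- tibble::tibble(
    id = c("T1", "R1"),
    stoich = list(c(thf_c = -1, thf_m = 1), c(thf_c = -1, x_c = 1)),
    lb = 0, ub = 1000, gpr = "")
  m <- metabolic_model(mets, rxn)
  both <- block_consumers(m, "thf_c")
  expect_true(all(both$reactions$ub == 0))
  spared <- block_consumers(m, "thf_c", exclude_transporters = TRUE)
  expect_equal(spared$reactions$ub[spared$reactions$id == "T1"], 1000)
  expect_equal(spared$reactions$ub[spared$reactions$id == "R1"], 0)
})

test_that("cofactor stripping removes the pair and only the pair", {
  m <- t3()$model
  st <- strip_cofactor(m, "R_GART", list(c("fTHF", "THF")))
  s <- st$reactions$stoich[[which(st$reactions$id == "R_GART")]]
  expect_setequal(names(s), c("PRA", "FGAR"))
  expect_equal(unname(s["PRA"]), -1)

  # stripped reaction is no longer a folate consumer
  after <- block_consumers(st, c("THF", "fTHF"))
  expect_equal(after$reactions$ub[after$reactions$id == "R_GART"], 1000)

  # reaction lacking the pair errors, naming reaction and pair
  expect_error(strip_cofactor(m, "R_MID", list(c("fTHF", "THF"))),
               "R_MID.*fTHF/THF")
})

test_that("sink augmentation counts and contracts hold", {
  m <- t1_model()
  s <- add_sinks(m)
  expect_equal(nrow(s$reactions), nrow(m$reactions) + nrow(m$metabolites))
  expect_true(all(startsWith(s$reactions$id[s$reactions$sink], "SK_")))
  expect_error(add_sinks(s), "collision")
})

test_that("sink drains are independent: one sink vs all sinks agree", {
  m <- t2_model()
  all_s <- add_sinks(m)
  for (met in c("B", "Fred")) {
    one <- m
    one$reactions <- dplyr::bind_rows(one$reactions, tibble::tibble(
      id = paste0("SK_", met), stoich = list(stats::setNames(-1, met)),
      lb = 0, ub = 1e6, gpr = "", exchange = FALSE, sink = TRUE))
    expect_equal(max_production(all_s, met), max_production(one, met))
  }
})

test_that("perturbation records apply and round-trip through JSON", {
  m <- t3()$model
  p <- perturbation("gene_knockout", "gGART")
  expect_identical(model_hash(apply_perturbation(m, p)),
                   model_hash(knockout_genes(m, "gGART")))
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(kind = "gene_knockout", payload = "gGART", label = p$label),
                       f, auto_unbox = TRUE)
  expect_identical(model_hash(apply_perturbation(m, read_perturbation(f))),
                   model_hash(knockout_genes(m, "gGART")))

  ps <- perturbation("cofactor_strip",
                     list(reactions = c("R_GART", "R_ATIC"), pairs = list(c("fTHF", "THF"))))
  expect_identical(model_hash(apply_perturbation(m, ps)),
                   model_hash(strip_cofactor(m, c("R_GART", "R_ATIC"),
                                             list(c("fTHF", "THF")))))
  expect_error(perturbation("gene_knockout", character()), "empty")
})
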