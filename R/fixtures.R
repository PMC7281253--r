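# Synthetic fixture networks with ground-truth blocked structure, and the
# exact producibility oracle. These are first-class test surfaces for the
# blocked-metabolite semantics: a linear chain (with optional branch), a
# conserved cofactor cycle, a folate-dependent purine-synthesis toy, and
# random sparse networks small enough for exact mode enumeration.

#' Linear pathway fixture
#'
#' A chain `A1 -> A2 -> ... -> An` fed by an exchange for `A1` (uptake 10).
#' Step `k` carries gene `g<k>`, except the terminal step which carries two
#' isozyme genes (`g<n-1> or g<n>`) so that OR semantics are exercised: with
#' `n = 3` this is the three-gene, two-step toy used throughout the package
#' tests (`R2` rule `"g2 or g3"`). Optionally a branch
#' `A<mid> -> B1` (gene `gb`) hangs off the midpoint.
#'
#' @param n chain length (>= 2).
#' @param branch add the midpoint branch?
#' @return List with elements `model` and `spec` (ground truth: native
#'   blocked set and per-gene knockout deltas).
#' @export
make_linear <- function(n = 3, branch = FALSE) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  mets <- paste0("A", seq_len(n))
  steps <- n - 1L
  gpr <- c(if (steps > 1) paste0("g", seq_len(steps - 1L)),
           paste0("g", steps, " or g", steps + 1L))
  rxn <- tibble::tibble(
    id = c("EX_A1", paste0("R", seq_len(steps))),
    stoich = c(list(c(A1 = 1)),
               purrr::map(seq_len(steps), function(k) {
                 stats::setNames(c(-1, 1), c(mets[k], mets[k + 1L]))
               })),
    lb = 0,
    ub = c(10, rep(1000, steps)),
    gpr = c("", gpr)
  )
  deltas <- c(
    purrr::map(seq_len(steps - 1L), function(k) mets[seq(k + 1L, n)]) |>
      stats::setNames(paste0("g", seq_len(max(steps - 1L, 0L)))),
    stats::setNames(list(character(), character()), paste0("g", steps + c(0L, 1L)))
  )
  mid <- ceiling(n / 2)
  if (branch) {
    mets <- c(mets, "B1")
    rxn <- dplyr::bind_rows(rxn, tibble::tibble(
      id = "Rb", stoich = list(stats::setNames(c(-1, 1), c(paste0("A", mid), "B1"))),
      lb = 0, ub = 1000, gpr = "gb"
    ))
    deltas <- purrr::map(seq_along(deltas), function(k) {
      if (k < mid) c(deltas[[k]], "B1") else deltas[[k]]
    }) |> stats::setNames(names(deltas))
    deltas$gb <- "B1"
  }
  model <- metabolic_model(tibble::tibble(id = mets), rxn, id = if (branch) "linear_branched" else "linear")
  list(model = model, spec = list(topology = "linear", n = n, branch = branch,
                                  native_blocked = character(), knockout_deltas = deltas))
}

#' Conserved cofactor-cycle fixture
#'
#' Two reactions exchange a cofactor couple with no de-novo source:
#' `R1: A + Fred -> B + Fox` and `R2: X + Fox -> Y + Fred`, with exchanges
#' for `A` and `X` (uptake 10 each) and exports for `B` and `Y`. The cycle
#' can spin (every reaction can carry flux), yet `Fred`/`Fox` cannot be
#' synthesized de novo: they are blocked under the sink definition while the
#' flux-sum definition says otherwise — the package's definitional contrast.
#'
#' @return List with `model` and `spec` (ground truth).
#' @export
make_cofactor_cycle <- function() {
  mets <- c("A", "X", "B", "Y", "Fred", "Fox")
  rxn <- tibble::tibble(
    id = c("EX_A", "EX_X", "EX_B", "EX_Y", "R1", "R2"),
    stoich = list(
      c(A = 1), c(X = 1), c(B = -1), c(Y = -1),
      c(A = -1, Fred = -1, B = 1, Fox = 1),
      c(X = -1, Fox = -1, Y = 1, Fred = 1)
    ),
    lb = 0,
    ub = c(10, 10, 1000, 1000, 1000, 1000),
    gpr = c("", "", "", "", "g1", "g2")
  )
  model <- metabolic_model(tibble::tibble(id = mets), rxn, id = "cofactor_cycle")
  list(model = model,
       spec = list(topology = "cofactor_cycle",
                   native_blocked = c("Fred", "Fox"),
                   fluxsum_unblocked = c("Fred", "Fox")))
}

#' Folate-dependent purine-synthesis toy
#'
#' A miniature of de-novo purine biosynthesis with a conserved folate-analog
#' couple `THF`/`fTHF`: two pathway steps (the GART and ATIC analogs) consume
#' `fTHF` and return `THF`, which is re-formylated from formate. Downstream,
#' IMP yields ATP and GTP, GTP yields the BH4 analog, and Met + ATP yields
#' the SAM analog. A side branch (`Gln -> Orn`) provides a knockout whose
#' footprint is disjoint from the folate-deficiency footprint. Exchanges
#' (uptake 10): PRPP, Gln, Formate, Met.
#'
#' Ground truth: native blocked = \{THF, fTHF\}; blocking all folate
#' consumers newly blocks the 7 species \{FGAR, AICAR, IMP, ATP, GTP, BH4,
#' SAM\}; knocking out `gGART` blocks the same 7 (Jaccard 1 against the
#' deficiency), `gATIC` blocks 5 of them (Jaccard 5/7), `gSIDE` blocks only
#' `Orn` (Jaccard 0).
#'
#' @return List with `model` and `spec` (ground truth).
#' @export
make_purine_toy <- function() {
  mets <- c("PRPP", "Gln", "Formate", "Met", "PRA", "FGAR", "AICAR", "IMP",
            "ATP", "GTP", "BH4", "SAM", "Orn", "THF", "fTHF")
  rxn <- tibble::tibble(
    id = c("EX_PRPP", "EX_Gln", "EX_For", "EX_Met",
           "R_PPAT", "R_GART", "R_MID", "R_ATIC", "R_FTHFS",
           "R_ADE", "R_GUA", "R_BH4", "R_SAM", "R_SIDE"),
    stoich = list(
      c(PRPP = 1), c(Gln = 1), c(Formate = 1), c(Met = 1),
      c(PRPP = -1, Gln = -1, PRA = 1),
      c(PRA = -1, fTHF = -1, FGAR = 1, THF = 1),
      c(FGAR = -1, AICAR = 1),
      c(AICAR = -1, fTHF = -1, IMP = 1, THF = 1),
      c(THF = -1, Formate = -1, fTHF = 1),
      c(IMP = -1, ATP = 1),
      c(IMP = -1, GTP = 1),
      c(GTP = -1, BH4 = 1),
      c(Met = -1, ATP = -1, SAM = 1),
      c(Gln = -1, Orn = 1)
    ),
    lb = 0,
    ub = c(rep(10, 4), rep(1000, 10)),
    gpr = c("", "", "", "",
            "gPPAT", "gGART", "gMID", "gATIC", "gFTHFS",
            "gADE", "gGUA", "gBH4", "gSAM", "gSIDE")
  )
  model <- metabolic_model(tibble::tibble(id = mets), rxn, id = "purine_toy")
  purine_block <- c("FGAR", "AICAR", "IMP", "ATP", "GTP", "BH4", "SAM")
  list(model = model,
       spec = list(
         topology = "purine_toy",
         folate_species = c("THF", "fTHF"),
         folate_steps = c("R_GART", "R_ATIC"),
         native_blocked = c("THF", "fTHF"),
         deficiency_delta = purine_block,
         knockout_deltas = list(
           gGART = purine_block,
           gATIC = c("IMP", "ATP", "GTP", "BH4", "SAM"),
           gSIDE = "Orn"
         )
       ))
}

#' Random sparse fixture network
#'
#' Reproducible random networks small enough for the exact mode-enumeration
#' oracle: integer stoichiometric coefficients in \{-2, -1, 1, 2\}, each
#' reaction irreversible with probability 0.7, at least one exchange
#' (uptake 10).
#'
#' @param n_reactions total reaction count (<= 12, oracle tractability).
#' @param seed integer seed; the same seed reproduces the same network.
#' @return List with `model` and `spec`.
#' @export
make_random <- function(n_reactions = 8, seed = 1) {
  if (n_reactions > 12) stop("n_reactions must be <= 12 (oracle limit)", call. = FALSE)
  if (n_reactions < 2) stop("n_reactions must be >= 2", call. = FALSE)
  rng <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    n_ex <- sample(1:min(3, n_reactions - 1L), 1)
    n_int <- n_reactions - n_ex
    n_met <- max(3L, min(10L, n_int + sample(0:2, 1)))
    mets <- paste0("M", seq_len(n_met))
    stoich <- vector("list", n_reactions)
    lb <- numeric(n_reactions)
    ub <- numeric(n_reactions)
    ids <- character(n_reactions)
    for (k in seq_len(n_ex)) {
      m <- mets[k]
      stoich[[k]] <- stats::setNames(1, m)
      ids[k] <- paste0("EX_", m)
      lb[k] <- 0
      ub[k] <- 10
    }
    pick <- function(x, k) x[sample.int(length(x), k)]
    for (k in seq(n_ex + 1L, n_reactions)) {
      ns <- sample(1:2, 1)
      subs <- pick(mets, ns)
      avail <- setdiff(mets, subs)
      np <- sample(1:min(2, length(avail)), 1)
      prods <- pick(avail, np)
      s <- c(stats::setNames(-sample(1:2, ns, replace = TRUE), subs),
             stats::setNames(sample(1:2, np, replace = TRUE), prods))
      stoich[[k]] <- s
      ids[k] <- paste0("R", k - n_ex)
      rev <- stats::runif(1) > 0.7
      lb[k] <- if (rev) -1000 else 0
      ub[k] <- 1000
    }
    list(mets = mets, rxn = tibble::tibble(
      id = ids, stoich = stoich, lb = lb, ub = ub,
      gpr = c(rep("", n_ex), paste0("g", seq_len(n_int)))
    ))
  })
  model <- metabolic_model(tibble::tibble(id = rng$mets), rng$rxn,
                           id = paste0("random_", seed))
  list(model = model, spec = list(topology = "random", seed = seed,
                                  n_reactions = n_reactions))
}
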