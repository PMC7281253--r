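# Exact producibility oracle: elementary-mode enumeration by the double
# description method, in exact integer arithmetic. Completely independent of
# the LP engine — used to verify it on small fixture networks. The network
# is augmented with one sink per metabolite before enumeration, mirroring
# the producibility definition (byproducts may drain freely).
#
# The flux cone {v : Sv = 0, irreversible v_i >= 0} is brought into the
# orthant by splitting reversible reactions into forward/backward columns.
# Starting from the unit rays of the orthant, each steady-state equality is
# imposed in turn: surviving rays are those on the hyperplane plus canonical
# combinations of adjacent (positive, negative) pairs. Integer vectors are
# reduced by their gcd after every combination, which keeps coefficients
# small on the <= 12-reaction fixtures this oracle is restricted to.

gcd2 <- function(a, b) {
  while (b != 0) {
    t <- a %% b
    a <- b
    b <- t
  }
  a
}

gcd_vec <- function(x) {
  g <- 0
  for (v in abs(x)) {
    g <- gcd2(g, v)
    if (g == 1) break
  }
  g
}

# Extreme rays of {x >= 0, A x = 0}; A integer matrix. Columns of the
# returned matrix are the rays (integer, gcd-reduced).
extreme_rays <- function(A) {
  n <- ncol(A)
  rays <- diag(n)
  for (i in seq_len(nrow(A))) {
    d <- as.numeric(A[i, , drop = FALSE] %*% rays)
    zero <- which(d == 0)
    pos <- which(d > 0)
    neg <- which(d < 0)
    new_rays <- rays[, zero, drop = FALSE]
    if (length(pos) && length(neg)) {
      zsets <- lapply(seq_len(ncol(rays)), function(k) which(rays[, k] == 0))
      combos <- list()
      for (p in pos) {
        for (q in neg) {
          z_pq <- intersect(zsets[[p]], zsets[[q]])
          adjacent <- TRUE
          for (r in seq_len(ncol(rays))) {
            if (r == p || r == q) next
            if (all(z_pq %in% zsets[[r]])) {
              adjacent <- FALSE
              break
            }
          }
          if (!adjacent) next
          v <- d[p] * rays[, q] - d[q] * rays[, p]
          g <- gcd_vec(v)
          if (g > 1) v <- v / g
          if (max(abs(v)) > 2^45) stop("oracle: integer overflow in ray combination", call. = FALSE)
          combos[[length(combos) + 1L]] <- v
        }
      }
      if (length(combos)) {
        new_rays <- cbind(new_rays, do.call(cbind, combos))
      }
    }
    if (ncol(new_rays) > 1) {
      key <- apply(new_rays, 2, paste, collapse = ",")
      new_rays <- new_rays[, !duplicated(key), drop = FALSE]
    }
    rays <- new_rays
    if (!ncol(rays)) break
  }
  rays
}

#' Exact de-novo producibility oracle
#'
#' Decides whether a metabolite can be produced at steady state by
#' enumerating the extreme rays of the flux cone of the sink-augmented
#' network in exact integer arithmetic (double description). The metabolite
#' is producible iff some elementary mode carries positive sink flux. The
#' oracle ignores bound magnitudes (it answers the conic question, which is
#' what producibility is: positive bounds only scale flux); reactions with
#' `lb = ub = 0` are removed, reversible reactions are split.
#'
#' @param model a [metabolic_model()]; enumeration is exponential in the
#'   worst case, so the reaction count (sinks and disabled reactions not
#'   counted) is capped.
#' @param metabolite metabolite id to test.
#' @param limit maximum admissible reaction count.
#' @return `TRUE` iff the metabolite is producible de novo.
#' @export
oracle_producible <- function(model, metabolite, limit = 16) {
  met_index(model, metabolite)
  rxn <- model$reactions[!model$reactions$sink, ]
  active <- !(rxn$lb == 0 & rxn$ub == 0)
  rxn <- rxn[active, ]
  if (nrow(rxn) > limit) {
    stop("oracle limited to ", limit, " reactions (got ", nrow(rxn), ")", call. = FALSE)
  }
  mets <- model$metabolites$id
  cols <- list()
  for (i in seq_len(nrow(rxn))) {
    s <- rxn$stoich[[i]]
    col <- numeric(length(mets))
    col[match(names(s), mets)] <- s
    if (any(col != round(col))) stop("oracle requires integer stoichiometry", call. = FALSE)
    if (rxn$ub[i] > 0) cols[[length(cols) + 1L]] <- col
    if (rxn$lb[i] < 0) cols[[length(cols) + 1L]] <- -col
  }
  # one sink per metabolite: byproducts are free to drain, exactly as in the
  # sink-augmented producibility definition
  n_rxn_cols <- length(cols)
  for (k in seq_along(mets)) {
    sink_col <- numeric(length(mets))
    sink_col[k] <- -1
    cols[[length(cols) + 1L]] <- sink_col
  }
  A <- do.call(cbind, cols)
  rays <- extreme_rays(A)
  if (!ncol(rays)) return(FALSE)
  query_row <- n_rxn_cols + match(metabolite, mets)
  any(rays[query_row, ] > 0)
}
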