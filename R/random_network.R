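#' Seeded random toy network generator
#'
#' Emits a small layered network — substrate source, a chain of
#' intermediates, biomass and product sinks, a maintenance drain — plus
#' random extra edges (occasionally with stoichiometric coefficient 2,
#' creating yield-changing bypasses) and an optional fraction of reversible
#' internal reactions. Networks are regenerated (bounded retries under
#' derived seeds) until wild-type growth and achievable product flux are
#' both positive, so every emitted instance poses a meaningful
#' growth-coupling problem. Fully determined by \code{seed}.
#'
#' @param n_intermediates number of internal metabolites (>= 2).
#' @param n_extra_edges random internal conversions added on top of the
#'   backbone chain.
#' @param rev_fraction fraction of internal reactions made reversible.
#' @param seed integer seed.
#' @param max_retries attempts before giving up.
#' @return a \code{metabolic_model} with roles \code{R_s} (source),
#'   \code{R_bio} (objective), \code{R_prod}/\code{R_p} (product formation
#'   and sink) and \code{R_m} (maintenance).
#' @export
random_network <- function(n_intermediates = 4, n_extra_edges = 3,
                           rev_fraction = 0, seed = 1, max_retries = 25) {
  for (attempt in seq_len(max_retries)) {
    model <- .random_network_once(n_intermediates, n_extra_edges,
                                  rev_fraction,
                                  seed * 1000L + attempt - 1L)
    g <- fba(model, "R_bio", "max")
    if (g$status != "optimal" || g$objective_value <= 1e-6) next
    p <- fba(model, "R_p", "max")
    if (p$status != "optimal" || p$objective_value <= 1e-6) next
    return(model)
  }
  stop("random_network: no viable network after ", max_retries, " retries")
}

.random_network_once <- function(k, n_extra, rev_fraction, seed) {
  stopifnot(k >= 2)
  rng <- .with_seed(seed)
  on.exit(rng())
  mets <- c(paste0("M", seq_len(k)), "P")
  rxns <- list(R_s = c(M1 = 1))
  # backbone chain M1 -> ... -> Mk
  for (i in seq_len(k - 1)) {
    nm <- paste0("R_c", i)
    st <- setNames(c(-1, 1), c(paste0("M", i), paste0("M", i + 1)))
    rxns[[nm]] <- st
  }
  # product formation from a random intermediate (sometimes as co-product)
  src <- sample(k, 1)
  st <- setNames(c(-1, 1), c(paste0("M", src), "P"))
  if (runif(1) < 0.4 && src < k) {
    st <- setNames(c(-1, 1, 1), c(paste0("M", src), paste0("M", sample(src:k, 1)), "P"))
    st <- st[!duplicated(names(st))]
  }
  rxns$R_prod <- st
  rxns$R_bio <- setNames(-1, paste0("M", k))
  rxns$R_p <- c(P = -1)
  rxns$R_m <- c(M1 = -1)
  # extra random internal conversions
  for (e in seq_len(n_extra)) {
    ij <- sample(k, 2)
    coef <- if (runif(1) < 0.3) 2 else 1
    rxns[[paste0("R_x", e)]] <-
      setNames(c(-1, coef), paste0("M", ij))
  }
  S <- .stoich_matrix(mets, rxns)
  n <- length(rxns)
  lb <- setNames(rep(0, n), names(rxns))
  ub <- setNames(rep(1000, n), names(rxns))
  ub["R_s"] <- 10
  internal <- setdiff(names(rxns), c("R_s", "R_bio", "R_p", "R_m"))
  nrev <- round(rev_fraction * length(internal))
  if (nrev > 0)
    lb[sample(internal, nrev)] <- -1000
  metabolic_model(S, lb, ub, objective_id = "R_bio", maintenance_id = "R_m")
}

# run code under a temporary RNG state; returns a restore function
.with_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}
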