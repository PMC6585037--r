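#' Packaged toy networks
#'
#' Three small irreversible networks used throughout the test surface.
#' \describe{
#'   \item{TOY-A}{a linear chain: \code{R_s: -> A (ub 10)}, \code{R_1: A -> B},
#'     \code{R_2: B -> P}, \code{R_ex: P ->} (objective). Every flux equals the
#'     uptake, so all optima are unique.}
#'   \item{TOY-B}{a branched network where growth (drain of D) can run either
#'     through a product-free route (\code{R_2: A -> D}) or a co-producing
#'     route (\code{R_1: A -> B}, \code{R_3: B -> D + P}); \code{R_bio: D ->}
#'     is the objective, \code{R_p: P ->} the product sink and
#'     \code{R_m: D ->} a maintenance drain with configurable lower bound.}
#'   \item{TOY-C}{TOY-B plus two product-free bypasses (\code{R_4: A -> 2 D},
#'     \code{R_5: B -> D}) creating a non-trivial knockout landscape.}
#' }
#'
#' @param name one of \code{"TOY-A"}, \code{"TOY-B"}, \code{"TOY-C"}.
#' @param maintenance_lb lower bound of the maintenance drain \code{R_m}
#'   (TOY-B/C only; default 0).
#' @return a \code{metabolic_model}.
#' @export
toy_network <- function(name = c("TOY-A", "TOY-B", "TOY-C"),
                        maintenance_lb = 0) {
  name <- match.arg(name)
  if (name == "TOY-A") {
    mets <- c("A", "B", "P")
    rxns <- list(R_s  = c(A = 1),
                 R_1  = c(A = -1, B = 1),
                 R_2  = c(B = -1, P = 1),
                 R_ex = c(P = -1))
    S <- .stoich_matrix(mets, rxns)
    return(metabolic_model(S, lb = c(0, 0, 0, 0), ub = c(10, 1000, 1000, 1000),
                           objective_id = "R_ex"))
  }
  mets <- c("A", "B", "D", "P")
  rxns <- list(R_s   = c(A = 1),
               R_1   = c(A = -1, B = 1),
               R_2   = c(A = -1, D = 1),
               R_3   = c(B = -1, D = 1, P = 1),
               R_bio = c(D = -1),
               R_p   = c(P = -1),
               R_m   = c(D = -1))
  if (name == "TOY-C")
    rxns <- c(rxns, list(R_4 = c(A = -1, D = 2), R_5 = c(B = -1, D = 1)))
  S <- .stoich_matrix(mets, rxns)
  n <- length(rxns)
  lb <- setNames(rep(0, n), names(rxns))
  lb["R_m"] <- maintenance_lb
  ub <- setNames(rep(1000, n), names(rxns))
  ub["R_s"] <- 10
  metabolic_model(S, lb, ub, objective_id = "R_bio", maintenance_id = "R_m")
}

.stoich_matrix <- function(mets, rxns) {
  S <- matrix(0, length(mets), length(rxns),
              dimnames = list(mets, names(rxns)))
  for (j in seq_along(rxns))
    S[names(rxns[[j]]), j] <- rxns[[j]]
  S
}
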