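#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux of one reaction over the steady-state
#' flux space \code{S v = 0}, \code{l <= v <= u} and returns one optimal
#' vertex. With degenerate optima the vertex is solver-dependent; use
#' \code{\link{pfba}} or \code{\link{fva}} for well-defined quantities.
#'
#' @param model a \code{metabolic_model}.
#' @param objective reaction id to optimize (default: the model objective).
#' @param sense \code{"max"} or \code{"min"}.
#' @return a \code{flux_distribution}: list with \code{fluxes} (named
#'   vector), \code{objective_value} and \code{status}. Infeasible or
#'   unbounded problems are reported through \code{status}, not as errors.
#' @export
fba <- function(model, objective = NULL, sense = c("max", "min")) {
  sense <- match.arg(sense)
  objective <- .resolve_objective(model, objective)
  out <- .model_lp(model, objective, sense)
  structure(list(fluxes = out$x, objective_value = out$objval,
                 objective_id = objective, status = out$status),
            class = "flux_distribution")
}

.resolve_objective <- function(model, objective) {
  if (is.null(objective)) objective <- model$objective_id
  if (is.na(objective)) stop("no objective: model has none and no objective was given")
  if (!objective %in% model$reaction_ids)
    stop("unknown objective reaction '", objective, "'")
  objective
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf("<flux_distribution> %s %s = %s\n", x$status, x$objective_id,
              format(x$objective_value)))
  invisible(x)
}

#' Parsimonious FBA
#'
#' Fixes the FBA optimum of the objective (within relative tolerance
#' \code{tol_opt}) and, among all such flux vectors, returns one minimizing
#' total absolute flux. Implemented as a single LP on the split
#' (irreversible) model, minimizing the sum of forward plus backward
#' fluxes. This is the "predicted phenotype" used by the analysis layer.
#'
#' @inheritParams fba
#' @param tol_opt relative slack allowed when fixing the optimum.
#' @return a \code{flux_distribution}; \code{total_flux} holds the minimal
#'   sum of absolute fluxes.
#' @export
pfba <- function(model, objective = NULL, tol_opt = 1e-8) {
  objective <- .resolve_objective(model, objective)
  opt <- fba(model, objective, "max")
  if (opt$status != "optimal") return(opt)
  sp <- split_reversible(model)
  sm <- sp$model
  nsp <- length(sm$reaction_ids)
  # objective row over split columns: fwd - bwd of the objective reaction
  crow <- numeric(nsp)
  crow[which(sp$fwd_of == objective)] <- 1
  crow[which(sp$bwd_of == objective)] <- -1
  z <- opt$objective_value
  slack <- abs(z) * tol_opt + 1e-9
  extra <- list(T = rbind(crow, -crow), b = c(z - slack, -(z + slack)))
  out <- .model_lp(sm, rep(1, nsp), "min", extra = extra)
  if (out$status != "optimal") # numerically degenerate fixing; fall back
    return(opt)
  v <- recombine_fluxes(sp, out$x)
  structure(list(fluxes = v, objective_value = unname(v[objective]),
                 objective_id = objective, status = "optimal",
                 total_flux = out$objval),
            class = "flux_distribution")
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux subject to the objective being at
#' least \code{fraction} of its maximum.
#'
#' @inheritParams fba
#' @param fraction fraction of the optimal objective in \code{[0, 1]}.
#' @param reactions reaction ids to scan (default: all).
#' @return a \code{flux_range}: data frame with columns \code{reaction},
#'   \code{min}, \code{max}; the attained optimum is in
#'   \code{attr(, "objective_value")}.
#' @export
fva <- function(model, objective = NULL, fraction = 1, reactions = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  objective <- .resolve_objective(model, objective)
  if (is.null(reactions)) reactions <- model$reaction_ids
  bad <- setdiff(reactions, model$reaction_ids)
  if (length(bad)) stop("unknown reaction id(s): ", paste(bad, collapse = ", "))
  opt <- fba(model, objective, "max")
  if (opt$status != "optimal")
    stop("FVA base problem is ", opt$status)
  n <- length(model$reaction_ids)
  crow <- numeric(n); crow[match(objective, model$reaction_ids)] <- 1
  extra <- list(T = matrix(crow, 1), b = fraction * opt$objective_value - 1e-9)
  lo <- hi <- numeric(length(reactions))
  for (k in seq_along(reactions)) {
    lo[k] <- .model_lp(model, reactions[k], "min", extra = extra)$objval
    hi[k] <- .model_lp(model, reactions[k], "max", extra = extra)$objval
  }
  out <- data.frame(reaction = reactions, min = lo, max = hi)
  attr(out, "objective_value") <- opt$objective_value
  class(out) <- c("flux_range", "data.frame")
  out
}

#' Classify growth coupling of a knockout strategy
#'
#' Strong coupling: every admissible flux vector of the mutant carries
#' product flux of at least \code{p_min} (checked by LP minimization of the
#' product over the whole mutant flux space) while growth of at least
#' \code{b_min} stays possible. Weak coupling: product flux of at least
#' \code{p_min} is forced only once growth reaches \code{b_min}. Both
#' thresholds default to the small epsilon used to avoid discarding
#' low-production couplings.
#'
#' @param model a \code{metabolic_model} with the environment already set.
#' @param strategy character vector of knockouts.
#' @param product_id reaction id of the product sink.
#' @param p_min,b_min product/growth thresholds.
#' @return a \code{coupling_class}: list with \code{class} (\code{"strong"},
#'   \code{"weak"} or \code{"none"}) and the supporting LP values.
#' @export
classify_coupling <- function(model, strategy, product_id,
                              p_min = .tol$eps, b_min = .tol$eps) {
  mut <- apply_knockouts(model, strategy)
  biomass <- .resolve_objective(mut, NULL)
  growth <- fba(mut, biomass, "max")
  if (growth$status != "optimal")
    return(structure(list(class = "none", status = growth$status,
                          max_biomass = NA_real_,
                          min_product_free = NA_real_,
                          min_product_at_bmin = NA_real_,
                          p_min = p_min, b_min = b_min),
                     class = "coupling_class"))
  minp_free <- .model_lp(mut, product_id, "min")
  n <- length(mut$reaction_ids)
  brow <- numeric(n); brow[match(biomass, mut$reaction_ids)] <- 1
  minp_b <- .model_lp(mut, product_id, "min",
                      extra = list(T = matrix(brow, 1), b = b_min))
  strong <- minp_free$status == "optimal" &&
    minp_free$objval >= p_min && growth$objective_value >= b_min
  weak <- !strong && minp_b$status == "optimal" && minp_b$objval >= p_min
  structure(list(
    class = if (strong) "strong" else if (weak) "weak" else "none",
    status = "optimal",
    max_biomass = growth$objective_value,
    min_product_free = if (minp_free$status == "optimal") minp_free$objval else NA_real_,
    min_product_at_bmin = if (minp_b$status == "optimal") minp_b$objval else Inf,
    p_min = p_min, b_min = b_min), class = "coupling_class")
}

#' @export
print.coupling_class <- function(x, ...) {
  cat(sprintf("<coupling_class> %s (min p free=%s, min p at b>=%g: %s)\n",
              x$class, format(x$min_product_free), x$b_min,
              format(x$min_product_at_bmin)))
  invisible(x)
}

#' Write a flux distribution or range as TSV
#' @param x a \code{flux_distribution} or \code{flux_range}.
#' @param path output file.
#' @return the written data frame, invisibly.
#' @export
write_fluxes <- function(x, path) {
  df <- if (inherits(x, "flux_distribution"))
    data.frame(reaction = names(x$fluxes), flux = unname(x$fluxes))
  else as.data.frame(x)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
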