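#' Brute-force minimal cut set oracle
#'
#' Ground truth for the MILP enumeration: tests every reaction subset up to
#' \code{max_size} by LP feasibility of the target space under the
#' knockouts and returns exactly the minimal blocking sets. Minimality is
#' by construction (subsets are visited in increasing size and supersets of
#' found sets are skipped). Guarded to stay tractable.
#'
#' @param model a \code{metabolic_model}.
#' @param target a \code{linear_flux_space}.
#' @param max_size largest subset size (<= 4).
#' @param pool candidate reactions (default: all).
#' @return list with \code{cutsets} (list of \code{\link{cut_set}}s,
#'   \code{minimal = TRUE}) and \code{status}: \code{"ok"},
#'   \code{"target already blocked"} (infeasible before any knockout) or
#'   \code{"unblockable"} (origin included; no cut set of any size exists).
#' @export
brute_force_mcs <- function(model, target, max_size = 3,
                            pool = model$reaction_ids) {
  if (length(model$reaction_ids) > 20 || max_size > 4)
    stop("combinatorial guard: n_reactions <= 20 and max_size <= 4")
  if (!flux_space_feasible(model, target))
    return(list(cutsets = list(), status = "target already blocked"))
  if (!validate_target_space(model, target)$valid)
    return(list(cutsets = list(), status = "unblockable"))
  found <- list()
  for (size in seq_len(max_size)) {
    combos <- combn(pool, size, simplify = FALSE)
    for (cand in combos) {
      superset <- any(vapply(found, function(f) all(f %in% cand), FALSE))
      if (superset) next
      if (!flux_space_feasible(model, target, cand))
        found[[length(found) + 1L]] <- cand
    }
  }
  list(cutsets = lapply(seq_along(found), function(i)
    cut_set(found[[i]], formulation = target$label, order = i,
            minimal = TRUE)),
    status = "ok")
}

#' Exhaustive knockout search oracle
#'
#' Evaluates the biomass-product coupled yield of the parsimonious-FBA
#' phenotype for every knockout set up to \code{max_size} drawn from the
#' candidate pool, and returns the argmax. Ties break towards smaller sets,
#' then lexicographic order — deterministic by construction.
#'
#' @param model a \code{metabolic_model}.
#' @param env optional \code{environment_spec} applied first.
#' @param product_id,substrate_id reaction ids used by the metric.
#' @param metric currently \code{"BPCY"}.
#' @param max_size largest knockout set (<= 4).
#' @param pool candidate reactions (default \code{\link{knockout_pool}}).
#' @return list with \code{knockouts}, \code{score} and \code{metric}.
#' @export
exhaustive_best_knockouts <- function(model, env = NULL, product_id,
                                      substrate_id, metric = "BPCY",
                                      max_size = 2,
                                      pool = knockout_pool(model)) {
  metric <- match.arg(metric, "BPCY")
  if (length(pool) > 20 || max_size > 4)
    stop("combinatorial guard: pool <= 20 and max_size <= 4")
  base <- set_environment(model, env)
  candidates <- list(character(0))
  for (size in seq_len(max_size))
    candidates <- c(candidates, combn(sort(pool), size, simplify = FALSE))
  best <- NULL; best_score <- -Inf
  for (cand in candidates) {
    score <- .bpcy_of_strategy(base, cand, product_id, substrate_id)
    if (score > best_score + 1e-9) { best <- cand; best_score <- score }
  }
  list(knockouts = best, score = best_score, metric = metric)
}

.bpcy_of_strategy <- function(model, knockouts, product_id, substrate_id) {
  mut <- apply_knockouts(model, knockouts)
  ph <- pfba(mut)
  if (ph$status != "optimal" || ph$objective_value <= .tol$act) return(0)
  vs <- abs(ph$fluxes[substrate_id])
  if (vs <= .tol$act) return(0)
  unname(ph$objective_value * ph$fluxes[product_id] / vs)
}
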