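#' Configuration for the evolutionary knockout search
#'
#' Two fitness schemes are supported, both maximizing two objectives:
#' \describe{
#'   \item{EAw}{maximum growth \code{Z} and the product flux of the
#'     parsimonious phenotype at that optimum — biomass-product coupling
#'     maximization.}
#'   \item{EAm}{maximum growth \code{Z} and \code{W}, the FVA minimum of
#'     the product flux at \code{v_b = Z}; a candidate is only acceptable
#'     when the product flux is forced positive already at half the maximum
#'     growth — product minimum maximization.}
#' }
#'
#' @param formulation \code{"EAw"} or \code{"EAm"}.
#' @param product_id product sink reaction id.
#' @param max_knockouts deletion cap per candidate (default 20).
#' @param max_evaluations stop after this many objective evaluations
#'   (default 1e5).
#' @param pop_size,archive_size SPEA2 population/archive sizes.
#' @param mutation_rate,crossover_rate per-individual operator rates.
#' @param pool knockout candidate pool; default
#'   \code{\link{knockout_pool}} of the model at run time.
#' @param seed integer seed for a reproducible run.
#' @return an \code{ea_config}.
#' @export
ea_config <- function(formulation = c("EAw", "EAm"), product_id,
                      max_knockouts = 20, max_evaluations = 1e5,
                      pop_size = 100, archive_size = 100,
                      mutation_rate = 0.8, crossover_rate = 0.5,
                      pool = NULL, seed = NULL) {
  formulation <- match.arg(formulation)
  stopifnot(pop_size > 0, archive_size > 0,
            mutation_rate >= 0, mutation_rate <= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            max_knockouts >= 0, max_evaluations >= 0)
  structure(list(formulation = formulation, product_id = product_id,
                 max_knockouts = max_knockouts,
                 max_evaluations = max_evaluations,
                 pop_size = pop_size, archive_size = archive_size,
                 mutation_rate = mutation_rate,
                 crossover_rate = crossover_rate,
                 pool = pool, seed = seed),
            class = "ea_config")
}

#' Evaluate a knockout candidate
#'
#' Applies the environment and knockouts, then scores the mutant under the
#' chosen fitness scheme. Infeasible or non-growing mutants score
#' \code{(0, 0)} with \code{feasible = FALSE}; EAm candidates failing the
#' half-maximum-growth production test are marked \code{accepted = FALSE}
#' (worst fitness) and barred from the final archive.
#'
#' @param model a \code{metabolic_model}.
#' @param env an \code{environment_spec} or \code{NULL}.
#' @param knockouts character vector of reaction ids.
#' @param formulation \code{"EAw"} or \code{"EAm"}.
#' @param product_id product sink reaction id.
#' @return a \code{candidate}: knockouts, \code{objectives} (length 2,
#'   maximization sense), \code{feasible}, \code{accepted}.
#' @export
evaluate_candidate <- function(model, env, knockouts, formulation, product_id) {
  mut <- apply_knockouts(set_environment(model, env), knockouts)
  cand <- list(knockouts = sort(unique(as.character(knockouts))),
               objectives = c(0, 0), feasible = FALSE, accepted = FALSE)
  class(cand) <- "candidate"
  growth <- fba(mut)
  if (growth$status != "optimal" || growth$objective_value <= .tol$act)
    return(cand)
  z <- growth$objective_value
  biomass <- mut$objective_id
  brow <- .unit_row(mut, biomass)
  min_p_at <- function(frac) {
    out <- .model_lp(mut, product_id, "min",
                     extra = list(T = matrix(brow, 1),
                                  b = frac * z * (1 - .tol$opt)))
    if (out$status == "optimal") out$objval else NA_real_
  }
  cand$feasible <- TRUE
  if (formulation == "EAw") {
    ph <- pfba(mut)
    cand$objectives <- c(z, unname(ph$fluxes[product_id]))
    cand$accepted <- TRUE
  } else {
    w <- min_p_at(1)
    half <- min_p_at(0.5)
    cand$objectives <- c(z, w)
    cand$accepted <- is.finite(half) && half > .tol$act
    if (!cand$accepted) cand$objectives <- c(0, 0)
  }
  cand
}

#' SPEA2 fitness assignment
#'
#' Standard strength-Pareto fitness over a maximization objective matrix:
#' strength \code{S(i)} counts individuals dominated by i; raw fitness
#' \code{R(i)} sums the strengths of i's dominators; density
#' \code{D(i) = 1 / (sigma_k + 2)} from the k-th nearest neighbour distance
#' with \code{k = floor(sqrt(N))}. Lower fitness is better; nondominated
#' individuals have fitness < 1.
#'
#' @param objectives numeric matrix, one row per individual (maximization).
#' @return list with \code{strength}, \code{raw}, \code{density},
#'   \code{fitness}.
#' @export
spea2_fitness <- function(objectives) {
  objectives <- as.matrix(objectives)
  N <- nrow(objectives)
  dominates <- matrix(FALSE, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i != j)
      dominates[i, j] <- all(objectives[i, ] >= objectives[j, ]) &&
        any(objectives[i, ] > objectives[j, ])
  }
  strength <- rowSums(dominates)
  raw <- vapply(seq_len(N), function(i) sum(strength[dominates[, i]]), 0)
  if (N > 1) {
    d <- as.matrix(dist(objectives))
    k <- max(1L, min(N - 1L, floor(sqrt(N))))
    sigma <- vapply(seq_len(N), function(i) sort(d[i, -i])[k], 0)
  } else sigma <- 0
  density <- 1 / (sigma + 2)
  list(strength = strength, raw = raw, density = density,
       fitness = raw + density)
}

#' Mutation and crossover on knockout sets
#'
#' Crossover (per-child probability \code{crossover_rate}) draws each
#' element of the parents' union with probability one half; mutation
#' (probability \code{mutation_rate}) adds, removes or replaces one
#' knockout. Children always respect the pool and the deletion cap.
#'
#' @param parents list of knockout character vectors (recycled in pairs).
#' @param config an \code{\link{ea_config}}.
#' @param pool candidate reaction ids.
#' @param n_offspring number of children to produce.
#' @return list of knockout vectors.
#' @export
vary_offspring <- function(parents, config, pool, n_offspring = length(parents)) {
  stopifnot(length(parents) >= 1)
  out <- vector("list", n_offspring)
  for (k in seq_len(n_offspring)) {
    p1 <- parents[[sample.int(length(parents), 1)]]
    p2 <- parents[[sample.int(length(parents), 1)]]
    child <- p1
    if (runif(1) < config$crossover_rate) {
      u <- union(p1, p2)
      child <- u[runif(length(u)) < 0.5]
    }
    if (runif(1) < config$mutation_rate) {
      op <- sample(c("add", "remove", "replace"), 1)
      addable <- setdiff(pool, child)
      if (op == "add" && length(addable) && length(child) < config$max_knockouts)
        child <- c(child, sample(addable, 1))
      else if (op == "remove" && length(child))
        child <- setdiff(child, sample(child, 1))
      else if (op == "replace" && length(child) && length(addable))
        child <- c(setdiff(child, sample(child, 1)), sample(addable, 1))
    }
    if (length(child) > config$max_knockouts)
      child <- sample(child, config$max_knockouts)
    out[[k]] <- sort(unique(child))
  }
  out
}

#' Run the SPEA2 knockout search
#'
#' Evolves a population of knockout candidates under the configured fitness
#' scheme until the evaluation budget is spent, maintaining an archive of
#' nondominated candidates with distance-based truncation. Evaluations are
#' cached per knockout set (each distinct candidate costs its LPs once) but
#' every submitted candidate counts against the budget.
#'
#' @param model a \code{metabolic_model}.
#' @param env an \code{environment_spec} or \code{NULL}.
#' @param config an \code{\link{ea_config}}.
#' @return an \code{ea_result}: list with \code{archive} (accepted,
#'   mutually nondominated candidates), \code{evaluations} and the config.
#' @export
run_ea <- function(model, env, config) {
  stopifnot(inherits(config, "ea_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  pool <- config$pool
  if (is.null(pool)) pool <- knockout_pool(model)
  cache <- new.env(parent = emptyenv())
  evals <- 0L
  evaluate <- function(ko) {
    key <- paste0("k:", paste(ko, collapse = ";"))
    evals <<- evals + 1L
    if (!is.null(cache[[key]])) return(cache[[key]])
    cand <- evaluate_candidate(model, env, ko, config$formulation,
                               config$product_id)
    cache[[key]] <- cand
    cand
  }
  random_candidate <- function() {
    size <- sample.int(min(config$max_knockouts, length(pool)), 1)
    sort(sample(pool, size))
  }

  pop <- lapply(seq_len(config$pop_size), function(i) evaluate(random_candidate()))
  archive <- list()
  repeat {
    union_set <- c(pop, archive)
    objs <- do.call(rbind, lapply(union_set, `[[`, "objectives"))
    fit <- spea2_fitness(objs)
    nd <- fit$raw == 0
    archive <- union_set[nd]
    archive <- .dedupe_candidates(archive)
    if (length(archive) > config$archive_size)
      archive <- .spea2_truncate(archive, config$archive_size)
    if (length(archive) < config$archive_size) {
      dominated <- union_set[!nd]
      if (length(dominated)) {
        ord <- order(fit$fitness[!nd])
        extra <- .dedupe_candidates(dominated[ord])
        archive <- c(archive,
                     head(extra, config$archive_size - length(archive)))
      }
    }
    if (evals >= config$max_evaluations) break
    # binary tournament on the archive, then variation
    afit <- spea2_fitness(do.call(rbind, lapply(archive, `[[`, "objectives")))$fitness
    select <- function() {
      i <- sample.int(length(archive), 1); j <- sample.int(length(archive), 1)
      if (afit[i] <= afit[j]) archive[[i]]$knockouts else archive[[j]]$knockouts
    }
    parents <- lapply(seq_len(config$pop_size), function(k) select())
    children <- vary_offspring(parents, config, pool, config$pop_size)
    budget <- config$max_evaluations - evals
    if (budget < length(children)) children <- head(children, max(budget, 0))
    if (!length(children)) break
    pop <- lapply(children, evaluate)
  }
  final <- Filter(function(c) c$feasible && c$accepted, archive)
  if (length(final)) {
    objs <- do.call(rbind, lapply(final, `[[`, "objectives"))
    keep <- spea2_fitness(objs)$raw == 0
    final <- final[keep]
  }
  structure(list(archive = final, evaluations = evals, config = config),
            class = "ea_result")
}

#' @export
print.ea_result <- function(x, ...) {
  cat(sprintf("<ea_result> %s: %d archived candidate(s), %d evaluations\n",
              x$config$formulation, length(x$archive), x$evaluations))
  for (c in x$archive)
    cat(sprintf("  {%s} -> (%.4g, %.4g)\n",
                paste(c$knockouts, collapse = ", "),
                c$objectives[1], c$objectives[2]))
  invisible(x)
}

.dedupe_candidates <- function(cands) {
  keys <- vapply(cands, function(c) paste(c$knockouts, collapse = ";"), "")
  cands[!duplicated(keys)]
}

# SPEA2 truncation: iteratively drop the candidate closest to its nearest
# neighbour (ties towards fewer knockouts, then lexicographic id order).
.spea2_truncate <- function(archive, size) {
  while (length(archive) > size) {
    objs <- do.call(rbind, lapply(archive, `[[`, "objectives"))
    d <- as.matrix(dist(objs))
    diag(d) <- Inf
    nn <- apply(d, 1, min)
    worst <- which(nn <= min(nn) + 1e-12)
    if (length(worst) > 1) {
      sizes <- vapply(archive[worst], function(c) length(c$knockouts), 0L)
      worst <- worst[sizes == max(sizes)]
      keys <- vapply(archive[worst], function(c) paste(c$knockouts, collapse = ";"), "")
      worst <- worst[order(keys, decreasing = TRUE)]
    }
    archive <- archive[-worst[1]]
  }
  archive
}

#' Run the evolutionary search several times with derived seeds
#'
#' The heuristic nature of the algorithm calls for repeated runs; run
#' \code{i} uses seed \code{seed + i - 1}.
#'
#' @inheritParams run_ea
#' @param runs number of repetitions (default 10).
#' @param seed base seed.
#' @return list of \code{ea_result}s.
#' @export
run_ea_batch <- function(model, env, config, runs = 10, seed = 1) {
  lapply(seq_len(runs), function(i) {
    config$seed <- seed + i - 1
    run_ea(model, env, config)
  })
}
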