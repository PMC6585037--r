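#' Filtering criteria for strategy screening
#'
#' The three-stage screen applied to every strategy set before analysis:
#' (1) the mutant must be feasible under the environmental conditions,
#' (2) its maximum growth must reach a fraction of the wild-type's
#' (default 1 percent), and (3) it must carry non-zero product flux with
#' growth at or above a fraction of the mutant maximum (default 90
#' percent) — the growth-coupling test.
#'
#' @param product_id product sink reaction id.
#' @param env an \code{environment_spec} or \code{NULL}.
#' @param min_growth_fraction_of_wt criterion-2 fraction (default 0.01).
#' @param coupling_growth_fraction criterion-3 fraction (default 0.90).
#' @param tol_act activity threshold for "non-zero" flux.
#' @return a \code{filter_criteria}.
#' @export
filter_criteria <- function(product_id, env = NULL,
                            min_growth_fraction_of_wt = 0.01,
                            coupling_growth_fraction = 0.90,
                            tol_act = .tol$act) {
  stopifnot(min_growth_fraction_of_wt > 0, min_growth_fraction_of_wt <= 1,
            coupling_growth_fraction > 0, coupling_growth_fraction <= 1)
  structure(list(product_id = product_id, env = env,
                 min_growth_fraction_of_wt = min_growth_fraction_of_wt,
                 coupling_growth_fraction = coupling_growth_fraction,
                 tol_act = tol_act),
            class = "filter_criteria")
}

#' Filter knockout strategies
#'
#' Applies the three criteria in order and keeps a strategy only if all
#' pass; rejected strategies carry the first failed criterion
#' (\code{"environment"}, \code{"growth"} or \code{"coupling"}).
#'
#' @param model a \code{metabolic_model}.
#' @param strategies list of knockout character vectors.
#' @param criteria a \code{\link{filter_criteria}}.
#' @return list with \code{kept} (sub-list of \code{strategies}) and
#'   \code{rejected} (data frame: strategy, reason).
#' @export
filter_strategies <- function(model, strategies, criteria) {
  stopifnot(inherits(criteria, "filter_criteria"))
  base <- set_environment(model, criteria$env)
  wt <- fba(base)
  if (wt$status != "optimal")
    stop("wild-type is infeasible under the environment")
  kept <- list(); rej_s <- character(0); rej_r <- character(0)
  for (s in strategies) {
    reason <- .first_failed_criterion(base, s, criteria, wt$objective_value)
    if (is.na(reason)) kept[[length(kept) + 1L]] <- s
    else { rej_s <- c(rej_s, paste(s, collapse = ";")); rej_r <- c(rej_r, reason) }
  }
  list(kept = kept,
       rejected = data.frame(strategy = rej_s, reason = rej_r))
}

.first_failed_criterion <- function(base, strategy, criteria, wt_growth) {
  mut <- apply_knockouts(base, strategy)
  g <- fba(mut)
  if (g$status != "optimal") return("environment")
  if (g$objective_value < criteria$min_growth_fraction_of_wt * wt_growth)
    return("growth")
  rob <- production_robustness(base, strategy, criteria$product_id,
                               criteria$coupling_growth_fraction)
  if (!is.finite(rob) || rob <= criteria$tol_act) return("coupling")
  NA_character_
}

#' Production robustness at a growth fraction
#'
#' Minimum feasible production rate given that growth is at least
#' \code{fraction} of the mutant's maximum; production is robust at that
#' threshold when the value is non-zero.
#'
#' @param model a \code{metabolic_model} (environment applied).
#' @param strategy character vector of knockouts.
#' @param product_id product sink reaction id.
#' @param fraction growth fraction in \code{(0, 1]}.
#' @return the minimum product flux, or \code{NA} for infeasible mutants.
#' @export
production_robustness <- function(model, strategy, product_id, fraction) {
  mut <- apply_knockouts(model, strategy)
  g <- fba(mut)
  if (g$status != "optimal") return(NA_real_)
  brow <- .unit_row(mut, mut$objective_id)
  out <- .model_lp(mut, product_id, "min",
                   extra = list(T = matrix(brow, 1),
                                b = fraction * g$objective_value * (1 - .tol$opt)))
  if (out$status != "optimal") return(NA_real_)
  max(out$objval, 0)
}

#' Biomass-product coupled yield
#'
#' \code{BPCY = v_biomass * v_product / v_substrate}, with fluxes read from
#' the parsimonious-FBA phenotype and the substrate as uptake magnitude.
#'
#' @param v_biomass,v_product,v_substrate fluxes (substrate as positive
#'   uptake magnitude).
#' @return the yield (h^-1 weighted by mol/mol).
#' @export
bpcy <- function(v_biomass, v_product, v_substrate) {
  if (v_substrate <= 0) stop("BPCY undefined for zero substrate uptake")
  v_biomass * v_product / v_substrate
}

#' Product/substrate carbon yield
#'
#' Fraction of substrate carbon recovered in the product:
#' \code{(v_product * c_product) / (v_substrate * c_substrate)}.
#'
#' @param v_product,v_substrate fluxes (substrate as uptake magnitude).
#' @param c_product,c_substrate carbon atoms per molecule.
#' @return the carbon yield in \code{[0, 1]} for carbon-conserving networks.
#' @export
carbon_yield <- function(v_product, v_substrate, c_product, c_substrate) {
  if (c_product <= 0 || c_substrate <= 0) stop("carbon counts must be positive")
  if (v_substrate <= 0) stop("carbon yield undefined for zero substrate uptake")
  (v_product * c_product) / (v_substrate * c_substrate)
}

#' Count carbon atoms in a chemical formula
#'
#' @param formula chemical formula string, e.g. \code{"C6H12O6"}.
#' @return integer carbon count (0 when the formula has no carbon).
#' @export
carbon_count <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(NA_integer_)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  total <- 0L
  for (p in parts) {
    el <- gsub("[0-9]", "", p)
    cnt <- gsub("[^0-9]", "", p)
    if (el == "C") total <- total + if (nzchar(cnt)) as.integer(cnt) else 1L
  }
  total
}

#' Pathway membership matrix
#'
#' Binary pathways-by-reactions matrix from a two-column table
#' (\code{reaction_id}, \code{pathway}). Pathways without member reactions
#' are dropped with a warning.
#'
#' @param x data frame with columns \code{reaction_id} and \code{pathway},
#'   or a TSV path with that header.
#' @param reaction_ids optional universe of reactions (matrix columns);
#'   defaults to the reactions present in the table.
#' @return a \code{pathway_matrix} (binary matrix with pathway rownames).
#' @export
pathway_matrix <- function(x, reaction_ids = NULL) {
  df <- if (is.character(x)) read.table(x, header = TRUE, sep = "\t",
                                        stringsAsFactors = FALSE) else x
  stopifnot(all(c("reaction_id", "pathway") %in% names(df)))
  if (is.null(reaction_ids)) reaction_ids <- sort(unique(df$reaction_id))
  pws <- sort(unique(df$pathway))
  p <- matrix(0L, length(pws), length(reaction_ids),
              dimnames = list(pws, reaction_ids))
  keep <- df$reaction_id %in% reaction_ids
  p[cbind(match(df$pathway[keep], pws), match(df$reaction_id[keep], reaction_ids))] <- 1L
  empty <- rowSums(p) == 0
  if (any(empty)) {
    warning("dropping pathway(s) without member reactions: ",
            paste(pws[empty], collapse = ", "))
    p <- p[!empty, , drop = FALSE]
  }
  structure(p, class = c("pathway_matrix", class(p)))
}

#' Pathway activity distribution of a flux distribution
#'
#' For each pathway, the fraction of its member reactions carrying flux
#' above the activity tolerance:
#' \code{d_j = sum_i p_ji |sgn(v_i)| / sum_i p_ji}.
#'
#' @param v a \code{flux_distribution} or named flux vector.
#' @param p a \code{\link{pathway_matrix}}.
#' @param tol_act activity threshold for the sign function.
#' @return named vector of fractions in \code{[0, 1]}.
#' @export
pathway_distribution <- function(v, p, tol_act = .tol$act) {
  fluxes <- if (inherits(v, "flux_distribution")) v$fluxes else v
  miss <- setdiff(colnames(p), names(fluxes))
  if (length(miss))
    stop("flux distribution lacks reaction(s): ", paste(miss, collapse = ", "))
  active <- as.numeric(abs(fluxes[colnames(p)]) > tol_act)
  as.vector(p %*% active / rowSums(p)) |> setNames(rownames(p))
}

#' Mean pathway-activity difference from the wild-type
#'
#' Averages the pathway distributions of a strategy set's predicted
#' phenotypes and subtracts the wild-type distribution.
#'
#' @param strategy_fluxes list of flux distributions (one per strategy).
#' @param wild_type the wild-type (parsimonious) flux distribution.
#' @param p a \code{\link{pathway_matrix}}.
#' @param tol_act activity threshold.
#' @return named vector of differences in \code{[-1, 1]}.
#' @export
pathway_delta <- function(strategy_fluxes, wild_type, p, tol_act = .tol$act) {
  stopifnot(length(strategy_fluxes) >= 1)
  dists <- vapply(strategy_fluxes, pathway_distribution, numeric(nrow(p)),
                  p = p, tol_act = tol_act)
  if (is.null(dim(dists))) dists <- matrix(dists, nrow = nrow(p))
  rowMeans(dists) - pathway_distribution(wild_type, p, tol_act)
}

#' Knockout frequency table
#'
#' Relative frequency of each reaction — and of each reaction combination
#' up to \code{max_combo_size} — across a strategy set.
#'
#' @param strategies list of knockout character vectors.
#' @param max_combo_size largest combination size (default 2).
#' @return data frame (combo, size, frequency) sorted by decreasing
#'   frequency, then combo.
#' @export
knockout_frequency <- function(strategies, max_combo_size = 2) {
  if (!length(strategies))
    return(data.frame(combo = character(0), size = integer(0),
                      frequency = numeric(0)))
  n <- length(strategies)
  counts <- new.env(parent = emptyenv())
  for (s in strategies) {
    s <- sort(unique(s))
    for (size in seq_len(min(max_combo_size, length(s)))) {
      for (combo in combn(s, size, simplify = FALSE)) {
        key <- paste(combo, collapse = "+")
        counts[[key]] <- (if (is.null(counts[[key]])) 0 else counts[[key]]) + 1
      }
    }
  }
  keys <- ls(counts)
  df <- data.frame(combo = keys,
                   size = lengths(strsplit(keys, "+", fixed = TRUE)),
                   frequency = vapply(keys, function(k) counts[[k]] / n, 0))
  df <- df[order(-df$frequency, df$combo), ]
  rownames(df) <- NULL
  df
}

#' Per-strategy phenotype reports and set-level summary
#'
#' For each (already filtered) strategy: maximum growth, the parsimonious
#' phenotype's biomass/substrate/product fluxes, production robustness at 1
#' and 90 percent of maximum growth, biomass-product coupled yield, carbon
#' yield (when carbon counts are available), coupling class and optionally
#' the pathway activity distribution. The summary reports mean, min and max
#' of each metric plus the strategy size distribution.
#'
#' @param model a \code{metabolic_model}.
#' @param strategies list of knockout character vectors.
#' @param criteria a \code{\link{filter_criteria}} (supplies environment and
#'   product id).
#' @param substrate_id substrate reaction id (uptake magnitude read from the
#'   parsimonious phenotype).
#' @param pmat optional \code{\link{pathway_matrix}}.
#' @param carbon optional named numeric: carbon atoms for product and
#'   substrate *reactions* (names = reaction ids); falls back to metabolite
#'   formula annotations when absent.
#' @return a \code{phenotype_report_set}: list with \code{reports} (data
#'   frame), \code{pathway_distributions} (matrix or NULL), and
#'   \code{summary} (data frame).
#' @export
build_report <- function(model, strategies, criteria, substrate_id,
                         pmat = NULL, carbon = NULL) {
  base <- set_environment(model, criteria$env)
  if (!length(strategies)) {
    warning("empty strategy set; empty report")
    return(structure(list(reports = data.frame(), pathway_distributions = NULL,
                          summary = data.frame()),
                     class = "phenotype_report_set"))
  }
  cc <- .resolve_carbon(model, carbon, criteria$product_id, substrate_id)
  rows <- list(); dists <- list(); fluxes <- list()
  for (i in seq_along(strategies)) {
    s <- strategies[[i]]
    mut <- apply_knockouts(base, s)
    g <- fba(mut)
    ph <- pfba(mut)
    vb <- unname(ph$fluxes[mut$objective_id])
    vp <- unname(ph$fluxes[criteria$product_id])
    vs <- abs(unname(ph$fluxes[substrate_id]))
    cls <- classify_coupling(base, s, criteria$product_id)
    rows[[i]] <- data.frame(
      strategy = paste(s, collapse = ";"),
      size = length(s),
      max_growth = g$objective_value,
      v_biomass = vb, v_substrate = vs, v_product = vp,
      robustness_1 = production_robustness(base, s, criteria$product_id, 0.01),
      robustness_90 = production_robustness(base, s, criteria$product_id,
                                            criteria$coupling_growth_fraction),
      bpcy = if (vs > 0) bpcy(vb, vp, vs) else NA_real_,
      carbon_yield = if (!is.null(cc) && vs > 0)
        unname(carbon_yield(vp, vs, cc[["product"]], cc[["substrate"]])) else NA_real_,
      coupling = cls$class)
    fluxes[[i]] <- ph
    if (!is.null(pmat)) dists[[i]] <- pathway_distribution(ph, pmat)
  }
  reports <- do.call(rbind, rows)
  metrics <- c("max_growth", "robustness_1", "robustness_90", "bpcy",
               "carbon_yield", "size")
  summary <- do.call(rbind, lapply(metrics, function(mname) {
    v <- reports[[mname]]
    data.frame(metric = mname, mean = mean(v, na.rm = TRUE),
               min = suppressWarnings(min(v, na.rm = TRUE)),
               max = suppressWarnings(max(v, na.rm = TRUE)))
  }))
  structure(list(reports = reports,
                 pathway_distributions = if (length(dists))
                   do.call(cbind, dists) else NULL,
                 fluxes = fluxes,
                 summary = summary),
            class = "phenotype_report_set")
}

.resolve_carbon <- function(model, carbon, product_id, substrate_id) {
  get_count <- function(id) {
    if (!is.null(carbon) && id %in% names(carbon)) return(carbon[[id]])
    # from the formula of the reaction's main metabolite
    col <- model$S[, id]
    mets <- names(col)[col != 0]
    forms <- model$annotations$formula[mets]
    cnts <- vapply(forms, function(f)
      if (is.null(f) || is.na(f)) NA_integer_ else carbon_count(f), 0L)
    if (all(is.na(cnts))) return(NA_real_)
    max(cnts, na.rm = TRUE)
  }
  cp <- get_count(product_id); cs <- get_count(substrate_id)
  if (is.na(cp) || is.na(cs)) return(NULL)
  c(product = as.numeric(cp), substrate = as.numeric(cs))
}

#' @export
print.phenotype_report_set <- function(x, ...) {
  cat("<phenotype_report_set>", nrow(x$reports), "strategies\n")
  if (nrow(x$reports)) print(x$reports[, c("strategy", "max_growth",
                                           "robustness_90", "bpcy", "coupling")])
  invisible(x)
}
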