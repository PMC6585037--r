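#' Construct a constraint-based metabolic model
#'
#' A metabolic model is the steady-state system \code{S v = 0},
#' \code{l <= v <= u}: an m-by-n stoichiometric matrix over m metabolites and
#' n reactions, flux bounds in mmol/gDW/h, and a designated objective
#' (biomass) reaction. A reaction is reversible iff its lower bound is
#' negative.
#'
#' @param S stoichiometric matrix; rows are metabolites, columns reactions.
#'   Row/column names, when present, seed the id vectors.
#' @param lb,ub flux bounds (length = ncol(S)).
#' @param reaction_ids,metabolite_ids unique id vectors; default to
#'   dimnames of \code{S}.
#' @param objective_id id of the biomass pseudo-reaction (may be \code{NA}
#'   while loading; most analyses require it).
#' @param maintenance_id optional id of the maintenance-ATP pseudo-reaction.
#' @param annotations optional list with elements \code{pathway} (named list
#'   of character vectors per reaction), \code{ec} (named character) and
#'   \code{formula} (named character, per metabolite).
#' @return an object of class \code{metabolic_model}.
#' @export
metabolic_model <- function(S, lb, ub, reaction_ids = colnames(S),
                            metabolite_ids = rownames(S),
                            objective_id = NA_character_,
                            maintenance_id = NULL,
                            annotations = list()) {
  S <- as.matrix(S)
  if (is.null(reaction_ids)) stop("reaction_ids are required")
  if (is.null(metabolite_ids))
    metabolite_ids <- paste0("M", seq_len(nrow(S)))
  if (anyDuplicated(reaction_ids)) stop("duplicate reaction ids")
  if (anyDuplicated(metabolite_ids)) stop("duplicate metabolite ids")
  stopifnot(length(lb) == ncol(S), length(ub) == ncol(S),
            length(reaction_ids) == ncol(S),
            length(metabolite_ids) == nrow(S))
  if (any(lb > ub)) stop("lb > ub for reaction(s): ",
                         paste(reaction_ids[lb > ub], collapse = ", "))
  if (!is.na(objective_id) && !objective_id %in% reaction_ids)
    stop("objective_id '", objective_id, "' is not a reaction")
  dimnames(S) <- list(metabolite_ids, reaction_ids)
  structure(list(reaction_ids = reaction_ids,
                 metabolite_ids = metabolite_ids,
                 S = S,
                 lb = setNames(as.numeric(lb), reaction_ids),
                 ub = setNames(as.numeric(ub), reaction_ids),
                 objective_id = objective_id,
                 maintenance_id = maintenance_id,
                 annotations = annotations),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %d metabolites x %d reactions (%d reversible)\n",
              nrow(x$S), ncol(x$S), sum(reversible(x))))
  cat("  objective:", x$objective_id, "\n")
  invisible(x)
}

#' Reversibility flags of a model
#'
#' A reaction is reversible iff its lower bound is negative.
#' @param model a \code{metabolic_model}.
#' @return named logical vector.
#' @export
reversible <- function(model) model$lb < 0

#' Split reversible reactions into forward/backward pairs
#'
#' Produces an irreversible model in which every reversible reaction is
#' replaced by a forward copy (bounds \code{[0, ub]}) and a backward copy
#' with negated stoichiometry (bounds \code{[0, -lb]}). Any feasible split
#' flux maps back to the original model through fwd - bwd.
#'
#' @param model a \code{metabolic_model}.
#' @return a \code{split_model}: list with the irreversible \code{model},
#'   \code{fwd_of}/\code{bwd_of} (split column index -> original id) and
#'   \code{pairing} (two-column matrix of forward/backward indices).
#' @export
split_reversible <- function(model) {
  rev <- reversible(model)
  n <- length(model$reaction_ids)
  cols <- list(); ids <- character(0); lb <- numeric(0); ub <- numeric(0)
  fwd_of <- character(0); bwd_of <- character(0)
  pairing <- matrix(integer(0), ncol = 2,
                    dimnames = list(NULL, c("fwd", "bwd")))
  for (j in seq_len(n)) {
    rid <- model$reaction_ids[j]
    cols[[length(cols) + 1L]] <- model$S[, j]
    ids <- c(ids, rid)
    lb <- c(lb, max(model$lb[j], 0))
    ub <- c(ub, max(model$ub[j], 0))
    fwd_of <- c(fwd_of, rid); bwd_of <- c(bwd_of, NA_character_)
    if (rev[j]) {
      cols[[length(cols) + 1L]] <- -model$S[, j]
      ids <- c(ids, paste0(rid, "__bwd"))
      lb <- c(lb, 0)
      ub <- c(ub, -model$lb[j])
      fwd_of <- c(fwd_of, NA_character_); bwd_of <- c(bwd_of, rid)
      pairing <- rbind(pairing, c(length(ids) - 1L, length(ids)))
    }
  }
  Ssp <- do.call(cbind, cols)
  colnames(Ssp) <- ids
  split <- metabolic_model(Ssp, lb, ub, reaction_ids = ids,
                           metabolite_ids = model$metabolite_ids,
                           objective_id = model$objective_id,
                           maintenance_id = model$maintenance_id,
                           annotations = model$annotations)
  structure(list(model = split, fwd_of = fwd_of, bwd_of = bwd_of,
                 pairing = pairing, original = model),
            class = "split_model")
}

#' Recombine a split flux vector onto the original reactions
#'
#' @param split a \code{split_model}.
#' @param v flux vector over the split columns.
#' @return named flux vector over the original reactions (fwd - bwd).
#' @export
recombine_fluxes <- function(split, v) {
  orig <- split$original$reaction_ids
  out <- setNames(numeric(length(orig)), orig)
  for (k in seq_along(v)) {
    if (!is.na(split$fwd_of[k])) out[split$fwd_of[k]] <- out[split$fwd_of[k]] + v[k]
    if (!is.na(split$bwd_of[k])) out[split$bwd_of[k]] <- out[split$bwd_of[k]] - v[k]
  }
  out
}

#' Apply reaction knockouts
#'
#' Knocked-out reactions keep their column (indices stay stable) but have
#' both bounds set to zero.
#'
#' @param model a \code{metabolic_model}.
#' @param knockouts character vector of reaction ids (may be empty).
#' @return the modified copy of the model.
#' @export
apply_knockouts <- function(model, knockouts) {
  knockouts <- unique(as.character(knockouts))
  bad <- setdiff(knockouts, model$reaction_ids)
  if (length(bad))
    stop("unknown reaction id(s): ", paste(bad, collapse = ", "))
  model$lb[knockouts] <- 0
  model$ub[knockouts] <- 0
  model
}

#' Environmental condition: per-reaction bound overrides
#'
#' @param ... named arguments, each a numeric \code{c(lb, ub)} pair, e.g.
#'   \code{environment_spec(EX_glc = c(-1.15, -1.15))}.
#' @return an \code{environment_spec} (named list of bound pairs).
#' @export
environment_spec <- function(...) {
  env <- list(...)
  if (length(env) && (is.null(names(env)) || any(names(env) == "")))
    stop("all environment entries must be named by reaction id")
  for (nm in names(env)) {
    b <- env[[nm]]
    if (length(b) != 2 || !is.numeric(b)) stop("entry '", nm, "' must be c(lb, ub)")
    if (b[1] > b[2]) stop("entry '", nm, "' has lb > ub")
  }
  structure(env, class = "environment_spec")
}

#' Apply an environmental condition to a model
#'
#' Overrides bounds for exactly the listed reactions; all others untouched.
#'
#' @param model a \code{metabolic_model}.
#' @param env an \code{environment_spec} (or plain named list of
#'   \code{c(lb, ub)} pairs).
#' @return the modified copy of the model.
#' @export
set_environment <- function(model, env) {
  if (is.null(env) || length(env) == 0) return(model)
  bad <- setdiff(names(env), model$reaction_ids)
  if (length(bad))
    stop("unknown reaction id(s) in environment: ", paste(bad, collapse = ", "))
  for (nm in names(env)) {
    b <- as.numeric(env[[nm]])
    if (b[1] > b[2]) stop("environment entry '", nm, "' has lb > ub")
    model$lb[nm] <- b[1]
    model$ub[nm] <- b[2]
  }
  model
}

# boundary (exchange-like) reactions: only products or only reactants
.boundary_reactions <- function(model) {
  apply(model$S, 2, function(col) all(col >= 0) || all(col <= 0))
}

#' Default knockout candidate pool
#'
#' Internal reactions eligible as genetic targets: everything except
#' boundary/exchange reactions, the biomass objective and the
#' maintenance-ATP pseudo-reaction.
#'
#' @param model a \code{metabolic_model}.
#' @return character vector of reaction ids.
#' @export
knockout_pool <- function(model) {
  drop <- model$reaction_ids[.boundary_reactions(model)]
  drop <- union(drop, c(model$objective_id, model$maintenance_id))
  setdiff(model$reaction_ids, drop)
}

#' Write a model summary as TSV
#'
#' One row per reaction: id, lb, ub, reversible, pathway tags.
#'
#' @param model a \code{metabolic_model}.
#' @param path output file.
#' @return the summary data frame, invisibly.
#' @export
write_model_summary <- function(model, path) {
  pw <- model$annotations$pathway
  tags <- vapply(model$reaction_ids, function(r)
    paste(pw[[r]], collapse = ";"), character(1))
  df <- data.frame(reaction_id = model$reaction_ids,
                   lb = unname(model$lb), ub = unname(model$ub),
                   reversible = unname(reversible(model)),
                   pathways = unname(tags))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
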