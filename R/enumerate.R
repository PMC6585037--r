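#' Create a cut-set record
#'
#' @param reactions character vector of reaction ids.
#' @param formulation label of the originating formulation.
#' @param order index in enumeration order.
#' @param minimal,constrained status flags.
#' @return a \code{cut_set}.
#' @export
cut_set <- function(reactions, formulation = NA_character_, order = NA_integer_,
                    minimal = NA, constrained = NA) {
  reactions <- sort(unique(as.character(reactions)))
  structure(list(reactions = reactions, size = length(reactions),
                 minimal = minimal, constrained = constrained,
                 formulation = formulation, order = order),
            class = "cut_set")
}

#' @export
print.cut_set <- function(x, ...) {
  cat(sprintf("<cut_set> {%s} size=%d minimal=%s constrained=%s\n",
              paste(x$reactions, collapse = ", "), x$size,
              format(x$minimal), format(x$constrained)))
  invisible(x)
}

#' Enumerate shortest cut sets from a dual system
#'
#' k-shortest support enumeration: binary indicators are attached to the
#' \code{v}/\code{h} blocks (one indicator per reaction, bounding both its
#' violation variables, which also guarantees that forward/backward
#' certificate variables of a reaction are never counted twice), the number
#' of active indicators is minimized by branch-and-bound, and after each
#' incumbent an exclusion row over its (minimality-reduced) support is
#' appended before re-solving. Supports therefore come out in
#' non-decreasing size.
#'
#' @param dual a \code{dual_system}.
#' @param max_size largest support to return.
#' @param max_solutions stop after this many cut sets.
#' @param time_limit wall-clock budget in seconds.
#' @param exclude reaction ids that may never enter a cut set.
#' @param big_m indicator linking constant (the witness constraint pins the
#'   cone scale, so a fixed constant is safe).
#' @return list with \code{cutsets} (list of \code{\link{cut_set}}) and
#'   \code{status} (\code{"complete"}, \code{"max_solutions"},
#'   \code{"time_limit"}, \code{"node_limit"} or
#'   \code{"target already blocked"}).
#' @export
enumerate_shortest <- function(dual, max_size = 3, max_solutions = Inf,
                               time_limit = Inf, exclude = character(0),
                               big_m = 1e4) {
  stopifnot(inherits(dual, "dual_system"))
  if (max_size < 1)
    return(list(cutsets = list(), status = "complete"))
  if (!flux_space_feasible(dual$model, dual$target))
    return(list(cutsets = list(), status = "target already blocked"))
  t0 <- Sys.time()
  n <- length(dual$reaction_ids)
  nlp <- ncol(dual$A)
  idx_z <- nlp + seq_len(n)
  nvar <- nlp + n
  # rows: dual system | links M z - v >= 0, M z - h >= 0 | size cap
  nrow0 <- nrow(dual$A)
  A <- matrix(0, nrow0 + 2 * n + 1, nvar)
  A[seq_len(nrow0), seq_len(nlp)] <- dual$A
  for (j in seq_len(n)) {
    A[nrow0 + j, idx_z[j]] <- big_m
    A[nrow0 + j, dual$idx_v[j]] <- -1
    A[nrow0 + n + j, idx_z[j]] <- big_m
    A[nrow0 + n + j, dual$idx_h[j]] <- -1
  }
  A[nrow0 + 2 * n + 1, idx_z] <- -1            # -sum z >= -max_size
  rlb <- c(dual$rlb, rep(0, 2 * n), -max_size)
  rub <- c(dual$rub, rep(Inf, 2 * n), Inf)
  lb <- c(dual$lb, rep(0, n))
  ub <- c(dual$ub, rep(1, n))
  ub[idx_z[match(intersect(exclude, dual$reaction_ids), dual$reaction_ids)]] <- 0
  obj <- numeric(nvar)
  obj[idx_z] <- 1

  cutsets <- list()
  seen <- character(0)
  status <- "complete"
  repeat {
    remaining <- if (is.finite(time_limit))
      time_limit - as.numeric(Sys.time() - t0, units = "secs") else Inf
    if (remaining <= 0) { status <- "time_limit"; break }
    sol <- .milp_bb(obj, A, rlb, rub, lb, ub, int_idx = idx_z,
                    time_limit = remaining)
    if (sol$status == "infeasible") break
    if (sol$status != "optimal") { status <- sol$status; break }
    supp <- dual$reaction_ids[sol$x[idx_z] > 0.5]
    # reduce to a minimal blocking subset before recording/excluding
    ver <- verify_minimality(dual$model, dual$target, supp)
    if (!isTRUE(ver$blocking)) {
      # numerically unsound support: exclude it and move on without recording
      row <- numeric(nvar)
      row[idx_z[match(supp, dual$reaction_ids)]] <- -1
      A <- rbind(A, row)
      rlb <- c(rlb, -(length(supp) - 1))
      rub <- c(rub, Inf)
      next
    }
    supp <- ver$reactions
    key <- paste(supp, collapse = ";")
    if (!key %in% seen) {
      seen <- c(seen, key)
      cutsets[[length(cutsets) + 1L]] <-
        cut_set(supp, formulation = dual$target$label,
                order = length(cutsets) + 1L, minimal = TRUE)
    }
    # exclusion: sum of z over the support <= |support| - 1
    row <- numeric(nvar)
    row[idx_z[match(supp, dual$reaction_ids)]] <- -1
    A <- rbind(A, row)
    rlb <- c(rlb, -(length(supp) - 1))
    rub <- c(rub, Inf)
    if (length(cutsets) >= max_solutions) { status <- "max_solutions"; break }
  }
  list(cutsets = cutsets, status = status)
}

#' Verify (and greedily restore) minimality of a cut set
#'
#' A cut set is minimal when the target space is infeasible under the full
#' knockout set but becomes feasible again after removing any single
#' element. Non-minimal blocking sets are reduced to a minimal subset by
#' greedy element removal; the \code{minimal} flag reports whether the set
#' *as given* was already minimal.
#'
#' @param model a \code{metabolic_model}.
#' @param target a \code{linear_flux_space}.
#' @param cutset character vector (or \code{cut_set}) of reaction ids.
#' @return a \code{cut_set}; \code{blocking = FALSE} (with
#'   \code{minimal = FALSE}) when the given set does not block the target.
#' @export
verify_minimality <- function(model, target, cutset) {
  ids <- if (inherits(cutset, "cut_set")) cutset$reactions else
    sort(unique(as.character(cutset)))
  form <- if (inherits(cutset, "cut_set")) cutset$formulation else target$label
  if (flux_space_feasible(model, target, ids)) {
    out <- cut_set(ids, formulation = form, minimal = FALSE)
    out$blocking <- FALSE
    return(out)
  }
  reduced <- ids
  repeat {
    dropped <- FALSE
    for (r in reduced) {
      if (!flux_space_feasible(model, target, setdiff(reduced, r))) {
        reduced <- setdiff(reduced, r)
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }
  out <- cut_set(reduced, formulation = form,
                 minimal = identical(sort(reduced), sort(ids)))
  out$blocking <- TRUE
  out
}

#' Constrain cut sets against a desired space
#'
#' Keeps exactly the cut sets under which the desired flux space stays
#' feasible (discarding lethal ones, e.g. those abolishing growth).
#'
#' @param model a \code{metabolic_model}.
#' @param cutsets list of \code{cut_set}s (minimality-verified).
#' @param desired a \code{linear_flux_space}.
#' @return the surviving cut sets, with \code{constrained = TRUE}.
#' @export
constrain_mcs <- function(model, cutsets, desired) {
  keep <- list()
  for (cs in cutsets) {
    if (flux_space_feasible(model, desired, cs$reactions)) {
      cs$constrained <- TRUE
      keep[[length(keep) + 1L]] <- cs
    }
  }
  keep
}

#' Enumerate constrained minimal cut sets for a formulation
#'
#' End-to-end convenience: validates the target space (refusing origin
#' inclusion), builds the dual system, enumerates shortest supports,
#' verifies minimality and, when a desired space is given, filters lethal
#' cut sets.
#'
#' @param model a \code{metabolic_model} with the environment applied.
#' @param target a \code{linear_flux_space} (see
#'   \code{\link{build_target_space}}).
#' @param desired optional \code{linear_flux_space} of phenotypes to keep.
#' @inheritParams enumerate_shortest
#' @return list with \code{cutsets} and \code{status}.
#' @export
enumerate_mcs <- function(model, target, desired = NULL, max_size = 3,
                          max_solutions = Inf, time_limit = Inf,
                          exclude = character(0)) {
  val <- validate_target_space(model, target)
  if (!val$valid)
    stop("target space includes the origin of the flux cone; no cut set can block it")
  dual <- build_dual_system(model, target)
  res <- enumerate_shortest(dual, max_size = max_size,
                            max_solutions = max_solutions,
                            time_limit = time_limit, exclude = exclude)
  if (!is.null(desired))
    res$cutsets <- constrain_mcs(model, res$cutsets, desired)
  res
}

#' Tabulate cut sets
#'
#' @param cutsets list of \code{cut_set}s.
#' @return data frame with semicolon-joined reactions, size and flags.
#' @export
cutsets_to_df <- function(cutsets) {
  if (!length(cutsets))
    return(data.frame(reactions = character(0), size = integer(0),
                      minimal = logical(0), constrained = logical(0),
                      formulation = character(0)))
  data.frame(
    reactions = vapply(cutsets, function(x) paste(x$reactions, collapse = ";"), ""),
    size = vapply(cutsets, function(x) x$size, 0L),
    minimal = vapply(cutsets, function(x) isTRUE(x$minimal), FALSE),
    constrained = vapply(cutsets, function(x) isTRUE(x$constrained), FALSE),
    formulation = vapply(cutsets, function(x) as.character(x$formulation), ""))
}

#' Write cut sets as TSV (and optionally JSON with provenance)
#'
#' @param cutsets list of \code{cut_set}s.
#' @param path output TSV path.
#' @param json_path optional JSON output with provenance metadata.
#' @param meta optional named list merged into the JSON provenance block.
#' @return the data frame, invisibly.
#' @export
write_cutsets <- function(cutsets, path, json_path = NULL, meta = list()) {
  df <- cutsets_to_df(cutsets)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path)) {
    payload <- list(
      provenance = c(list(package = "coupledesign",
                          created = format(Sys.time(), tz = "UTC")), meta),
      cutsets = df)
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(df)
}
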