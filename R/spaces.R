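#' Linear flux space (target or desired)
#'
#' A set of inequality rows \code{T v >= b} interpreted jointly with a
#' model's steady-state and bound constraints. All rows are stored in the
#' canonical ">=" direction; "<=" constraints are negated on entry and
#' equalities become an opposing pair of rows.
#'
#' @param T coefficient matrix (rows = constraints, columns named by
#'   reaction id).
#' @param b right-hand side vector.
#' @param label free-text description.
#' @return a \code{linear_flux_space}.
#' @export
linear_flux_space <- function(T, b, label = "") {
  T <- as.matrix(T)
  if (nrow(T) < 1) stop("a flux space needs at least one row")
  stopifnot(length(b) == nrow(T))
  structure(list(T = T, b = as.numeric(b), label = label,
                 homogeneous = all(abs(b) <= .tol$feas)),
            class = "linear_flux_space")
}

#' @export
print.linear_flux_space <- function(x, ...) {
  cat(sprintf("<linear_flux_space> '%s': %d row(s), %s\n", x$label, nrow(x$T),
              if (x$homogeneous) "homogeneous" else "inhomogeneous"))
  invisible(x)
}

#' Parameters of a cut-set formulation
#'
#' Bundles the reaction roles and numeric settings of the three target-space
#' formulations:
#' \describe{
#'   \item{MCSe}{block flux vectors with product/substrate yield at most
#'     \code{y_min} while uptake stays at most \code{s_max} and the
#'     maintenance-ATP flux is at least \code{m_atp}.}
#'   \item{MCSf}{same yield cut, but with the uptake fixed at \code{s_max}.}
#'   \item{MCSw}{block near-zero product flux (at most \code{eps}) at growth
#'     of at least \code{F} times the wild-type maximum.}
#' }
#'
#' @param formulation \code{"MCSe"}, \code{"MCSf"} or \code{"MCSw"}.
#' @param product,substrate,biomass,atpm reaction ids (roles used by the
#'   chosen formulation must be present).
#' @param s_max substrate uptake magnitude (mmol/gDW/h).
#' @param y_min minimum product/substrate yield to *block below* (mol/mol).
#' @param m_atp maintenance-ATP rate threshold.
#' @param eps product-flux threshold for MCSw.
#' @param F biomass fraction in \code{[0, 1]} for MCSw.
#' @return a \code{formulation_params} list.
#' @export
formulation_params <- function(formulation = c("MCSe", "MCSf", "MCSw"),
                               product = NULL, substrate = NULL,
                               biomass = NULL, atpm = NULL,
                               s_max = NULL, y_min = NULL, m_atp = NULL,
                               eps = .tol$eps, F = NULL) {
  formulation <- match.arg(formulation)
  req <- switch(formulation,
                MCSe = c("product", "substrate", "atpm", "s_max", "y_min", "m_atp"),
                MCSf = c("product", "substrate", "s_max", "y_min"),
                MCSw = c("product", "biomass", "eps", "F"))
  vals <- list(product = product, substrate = substrate, biomass = biomass,
               atpm = atpm, s_max = s_max, y_min = y_min, m_atp = m_atp,
               eps = eps, F = F)
  missing <- req[vapply(vals[req], is.null, logical(1))]
  if (length(missing))
    stop("formulation ", formulation, " requires parameter(s): ",
         paste(missing, collapse = ", "))
  if (!is.null(y_min) && y_min < 0) stop("y_min must be >= 0")
  if (!is.null(F) && (F < 0 || F > 1)) stop("F must be in [0, 1]")
  structure(c(list(formulation = formulation), vals),
            class = "formulation_params")
}

# uptake sign: exchange reactions with negative lb run uptake at negative
# flux (BiGG convention); toy-style sources run it positive.
.uptake_sign <- function(model, substrate) {
  if (model$lb[substrate] < 0) -1 else 1
}

.unit_row <- function(model, id, coef = 1) {
  r <- setNames(numeric(length(model$reaction_ids)), model$reaction_ids)
  r[id] <- coef
  r
}

#' Build the target (undesired) flux space of a formulation
#'
#' Encodes the formulation rows in canonical ">=" form. The yield constraint
#' \code{v_p / v_s <= y_min} is linearized as
#' \code{y_min * v_s - v_p >= 0}, valid because every formulation using it
#' also keeps \code{v_s > 0}. Substrate rows are expressed on the uptake
#' magnitude under the model's sign convention.
#'
#' @param model a \code{metabolic_model} (with the environment applied; MCSw
#'   computes the wild-type maximum growth from it).
#' @param params a \code{\link{formulation_params}}.
#' @return a \code{linear_flux_space} labelled by the formulation.
#' @export
build_target_space <- function(model, params) {
  stopifnot(inherits(params, "formulation_params"))
  for (role in c("product", "substrate", "biomass", "atpm")) {
    id <- params[[role]]
    if (!is.null(id) && !id %in% model$reaction_ids)
      stop(role, " reaction '", id, "' not in model")
  }
  f <- params$formulation
  if (f %in% c("MCSe", "MCSf")) {
    sg <- .uptake_sign(model, params$substrate)
    yield <- params$y_min * sg * .unit_row(model, params$substrate) -
      .unit_row(model, params$product)
    if (f == "MCSe") {
      T <- rbind(yield,
                 -sg * .unit_row(model, params$substrate),
                 .unit_row(model, params$atpm))
      b <- c(0, -params$s_max, params$m_atp)
    } else {
      T <- rbind(yield,
                 sg * .unit_row(model, params$substrate),
                 -sg * .unit_row(model, params$substrate))
      b <- c(0, params$s_max, -params$s_max)
    }
  } else {
    wt <- fba(model, params$biomass, "max")
    if (wt$status != "optimal" || wt$objective_value <= .tol$act)
      stop("MCSw needs a wild-type with positive maximum growth")
    T <- rbind(-.unit_row(model, params$product),
               .unit_row(model, params$biomass))
    b <- c(-params$eps, params$F * wt$objective_value)
  }
  rownames(T) <- NULL
  linear_flux_space(T, b, label = f)
}

#' Build the desired flux space
#'
#' Environmental bounds plus a positive lower bound on the biomass
#' pseudo-reaction; constraining enumerated cut sets against this space
#' discards lethal ones.
#'
#' @param model a \code{metabolic_model}.
#' @param env an \code{environment_spec} (bounds become rows; infinite
#'   bounds are skipped).
#' @param biomass_id biomass reaction id (default: model objective).
#' @param min_biomass strictly positive growth demand.
#' @return a \code{linear_flux_space}.
#' @export
build_desired_space <- function(model, env = NULL, biomass_id = NULL,
                                min_biomass = .tol$eps) {
  if (min_biomass <= 0)
    stop("min_biomass must be > 0 (a zero demand would never discard lethal cut sets)")
  biomass_id <- .resolve_objective(model, biomass_id)
  rows <- list(); b <- numeric(0)
  for (nm in names(env)) {
    if (!nm %in% model$reaction_ids)
      stop("unknown reaction id in environment: ", nm)
    bounds <- as.numeric(env[[nm]])
    if (is.finite(bounds[1])) {
      rows[[length(rows) + 1L]] <- .unit_row(model, nm); b <- c(b, bounds[1])
    }
    if (is.finite(bounds[2])) {
      rows[[length(rows) + 1L]] <- -.unit_row(model, nm); b <- c(b, -bounds[2])
    }
  }
  rows[[length(rows) + 1L]] <- .unit_row(model, biomass_id)
  b <- c(b, min_biomass)
  linear_flux_space(do.call(rbind, rows), b, label = "desired")
}

#' Validate a target space before enumeration
#'
#' Flags \code{ORIGIN_INCLUDED} when the zero flux vector satisfies every
#' target row (all \code{b <= 0}) and the model bounds admit it: the origin
#' of the flux cone then lies inside the undesired space and no cut set of
#' any size can block it, so enumeration is refused. Also reports whether
#' the target is feasible at all in the unperturbed model.
#'
#' @param model a \code{metabolic_model}.
#' @param space a \code{linear_flux_space}.
#' @return a \code{target_validation}: list with \code{valid},
#'   \code{origin_included}, \code{feasible_wildtype}.
#' @export
validate_target_space <- function(model, space) {
  zero_ok_bounds <- all(model$lb <= .tol$feas) && all(model$ub >= -.tol$feas)
  origin <- zero_ok_bounds && all(space$b <= .tol$feas)
  feas <- flux_space_feasible(model, space)
  structure(list(valid = !origin, origin_included = origin,
                 feasible_wildtype = feas),
            class = "target_validation")
}

#' @export
print.target_validation <- function(x, ...) {
  cat("<target_validation>", if (x$valid) "valid" else "ORIGIN_INCLUDED",
      "| feasible in wild-type:", x$feasible_wildtype, "\n")
  invisible(x)
}

#' Is a flux space feasible under a model (optionally with knockouts)?
#'
#' LP feasibility of \code{\{S v = 0, l <= v <= u, T v >= b\}} with the
#' given reactions constrained to zero.
#'
#' @param model a \code{metabolic_model}.
#' @param space a \code{linear_flux_space}.
#' @param knockouts character vector of reaction ids.
#' @return logical.
#' @export
flux_space_feasible <- function(model, space, knockouts = character(0)) {
  mut <- apply_knockouts(model, knockouts)
  T <- .align_space_columns(space$T, mut$reaction_ids)
  out <- .model_lp(mut, rep(0, length(mut$reaction_ids)), "min",
                   extra = list(T = T, b = space$b))
  out$status == "optimal"
}

# reorder space columns onto the model's reaction order; unnamed matrices
# of matching width are taken to be aligned already
.align_space_columns <- function(T, reaction_ids) {
  if (is.null(colnames(T))) {
    if (ncol(T) != length(reaction_ids))
      stop("flux space has ", ncol(T), " columns but the model has ",
           length(reaction_ids), " reactions")
    colnames(T) <- reaction_ids
    return(T)
  }
  miss <- setdiff(colnames(T), reaction_ids)
  if (length(miss))
    stop("flux space references unknown reactions: ",
         paste(miss, collapse = ", "))
  T[, reaction_ids, drop = FALSE]
}
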