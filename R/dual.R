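#' Build the dual system of a target space
#'
#' The dual of the intervention problem is a transposed, extended linear
#' system whose feasible points certify (by Farkas' lemma) that the target
#' space is infeasible: one free variable \code{u} per metabolite, a
#' nonnegative pair \code{v}/\code{h} per reaction, and one nonnegative
#' \code{w} per target row. Row \code{j} reads
#' \code{S[,j]'u - T[,j]'w + v_j - h_j >= 0} for irreversible reactions and
#' \code{= 0} for reversible ones, with the witness constraint
#' \code{b'w >= c}, \code{c = 1} (any positive constant gives the same
#' supports, the system being a cone). The support of \code{v}/\code{h} in
#' any feasible point is a reaction set whose knockout blocks the target
#' space.
#'
#' Because knockout semantics and the brute-force oracle operate on the
#' *bounded* flux polyhedron, every finite model bound (upper bounds,
#' nonzero lower bounds) is appended to the target block as an extra
#' \code{w} row; the textbook pure-cone dual is the special case of a
#' model without engaged finite bounds.
#'
#' @param model a \code{metabolic_model}; reversible reactions are handled
#'   natively through equality rows (no prior splitting needed).
#' @param target a validated \code{linear_flux_space} (no origin inclusion).
#' @return a \code{dual_system}: constraint matrices plus index maps from
#'   the \code{v}/\code{h} blocks back to reaction ids.
#' @export
build_dual_system <- function(model, target) {
  n <- length(model$reaction_ids)
  m <- length(model$metabolite_ids)
  target$T <- .align_space_columns(target$T, model$reaction_ids)

  # extended target block: formulation rows + engaged finite bound rows
  Text <- target$T
  bext <- target$b
  rev <- reversible(model)
  for (j in seq_len(n)) {
    if (is.finite(model$ub[j])) {
      Text <- rbind(Text, -.unit_row(model, model$reaction_ids[j]))
      bext <- c(bext, -model$ub[j])
    }
    if (is.finite(model$lb[j]) && abs(model$lb[j]) > .tol$feas) {
      Text <- rbind(Text, .unit_row(model, model$reaction_ids[j]))
      bext <- c(bext, model$lb[j])
    }
  }
  rownames(Text) <- NULL
  cext <- nrow(Text)

  # variables: [u (m, free) | v (n, >=0) | h (n, >=0) | w (cext, >=0)]
  nvar <- m + 2 * n + cext
  idx_u <- seq_len(m)
  idx_v <- m + seq_len(n)
  idx_h <- m + n + seq_len(n)
  idx_w <- m + 2 * n + seq_len(cext)
  A <- matrix(0, n + 1, nvar)
  for (j in seq_len(n)) {
    A[j, idx_u] <- model$S[, j]
    A[j, idx_w] <- -Text[, j]
    A[j, idx_v[j]] <- 1
    A[j, idx_h[j]] <- -1
  }
  A[n + 1, idx_w] <- bext
  rlb <- c(rep(0, n), 1)          # witness row: b'w >= 1
  rub <- c(ifelse(rev, 0, Inf), Inf)
  lb <- c(rep(-Inf, m), rep(0, 2 * n + cext))
  ub <- rep(Inf, nvar)

  structure(list(A = A, rlb = rlb, rub = rub, lb = lb, ub = ub,
                 idx_u = idx_u, idx_v = idx_v, idx_h = idx_h, idx_w = idx_w,
                 reaction_ids = model$reaction_ids,
                 model = model, target = target),
            class = "dual_system")
}

#' @export
print.dual_system <- function(x, ...) {
  cat(sprintf("<dual_system> %d reaction rows + witness; %d u, %d v, %d h, %d w variables\n",
              nrow(x$A) - 1, length(x$idx_u), length(x$idx_v),
              length(x$idx_h), length(x$idx_w)))
  invisible(x)
}

#' Support of a feasible dual point
#'
#' Reactions whose \code{v} or \code{h} entry exceeds the activity
#' tolerance; knocking them out blocks the target space.
#'
#' @param dual a \code{dual_system}.
#' @param x a feasible point of the dual LP.
#' @param tol activity threshold.
#' @return character vector of reaction ids.
#' @export
dual_support <- function(dual, x, tol = .tol$act) {
  act <- pmax(x[dual$idx_v], x[dual$idx_h]) > tol
  dual$reaction_ids[act]
}
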