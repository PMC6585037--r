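#' Solve a small dense linear program
#'
#' Thin wrapper around the package's bounded-variable simplex. Solves
#' \code{min/max obj' x} subject to \code{rlb <= A x <= rub} and
#' \code{lb <= x <= ub}. Use equal \code{rlb}/\code{rub} entries for
#' equality rows and infinities for one-sided rows or free bounds.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A dense constraint matrix (m x n).
#' @param rlb,rub row lower/upper limits (length m).
#' @param lb,ub variable bounds (length n).
#' @param maximize logical; maximize instead of minimize.
#' @return list with \code{status} (one of \code{"optimal"},
#'   \code{"infeasible"}, \code{"unbounded"}, \code{"error"}), \code{x}
#'   and \code{objval}.
#' @export
lp_solve <- function(obj, A, rlb, rub, lb, ub, maximize = FALSE) {
  if (!is.matrix(A)) A <- matrix(A, nrow = length(rlb))
  stopifnot(length(obj) == ncol(A), length(rlb) == nrow(A),
            length(rub) == nrow(A), length(lb) == ncol(A),
            length(ub) == ncol(A))
  res <- .simplex_solve(as.numeric(obj), A, as.numeric(rlb), as.numeric(rub),
                        as.numeric(lb), as.numeric(ub), isTRUE(maximize))
  status <- switch(as.character(res$status),
                   "0" = "optimal", "1" = "infeasible", "2" = "unbounded",
                   "error")
  list(status = status, x = res$x, objval = res$objval)
}

# LP over a model's flux space with optional extra inequality rows
# (extra$T %*% v >= extra$b). obj may be a reaction id or coefficient vector.
.model_lp <- function(model, obj, sense = c("max", "min"), extra = NULL) {
  sense <- match.arg(sense)
  n <- length(model$reaction_ids)
  if (is.character(obj)) {
    cvec <- numeric(n)
    cvec[match(obj, model$reaction_ids)] <- 1
  } else cvec <- obj
  A <- model$S
  rlb <- numeric(nrow(A))
  rub <- numeric(nrow(A))
  if (!is.null(extra) && nrow(extra$T) > 0) {
    A <- rbind(A, extra$T)
    rlb <- c(rlb, extra$b)
    rub <- c(rub, rep(Inf, length(extra$b)))
  }
  out <- lp_solve(cvec, A, rlb, rub, model$lb, model$ub,
                  maximize = (sense == "max"))
  if (!is.null(out$x)) names(out$x) <- model$reaction_ids
  out
}
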