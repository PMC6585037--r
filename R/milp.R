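# Branch-and-bound for small mixed-binary programs (minimization).
# Relies on the package simplex for the LP relaxations; scoped to the
# shortest-support dual MILPs of desk-scale networks.

.milp_bb <- function(obj, A, rlb, rub, lb, ub, int_idx,
                     integral_obj = TRUE, max_nodes = 200000L,
                     time_limit = Inf) {
  t0 <- Sys.time()
  best_x <- NULL
  best_obj <- Inf
  nodes <- 0L
  stack <- list(list(lb = lb, ub = ub))
  status <- "optimal"
  while (length(stack)) {
    if (nodes >= max_nodes) { status <- "node_limit"; break }
    if (as.numeric(Sys.time() - t0, units = "secs") > time_limit) {
      status <- "time_limit"; break
    }
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nodes <- nodes + 1L
    rel <- lp_solve(obj, A, rlb, rub, node$lb, node$ub, maximize = FALSE)
    if (rel$status != "optimal") next
    bound <- if (integral_obj) ceiling(rel$objval - 1e-6) else rel$objval
    if (bound >= best_obj - 1e-9) next
    xi <- rel$x[int_idx]
    frac <- abs(xi - round(xi))
    # strict test: with big-M links a z of ~1e-6 is a real fractional value
    # (v = M z > 0), so rounding it down would fabricate infeasible solutions
    if (all(frac <= 1e-9)) {
      best_obj <- rel$objval
      best_x <- rel$x
      best_x[int_idx] <- round(xi)
      next
    }
    j <- int_idx[which.max(frac)]
    down <- node; down$ub[j] <- floor(rel$x[j])
    up <- node; up$lb[j] <- ceiling(rel$x[j])
    # LIFO: push the 0-branch first so the 1-branch (diving) is explored next
    stack[[length(stack) + 1L]] <- down
    stack[[length(stack) + 1L]] <- up
  }
  if (is.null(best_x) && status == "optimal") status <- "infeasible"
  list(status = status, x = best_x, objval = best_obj, nodes = nodes)
}
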