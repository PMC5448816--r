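#' Linear program container
#'
#' A `linear_program` is the package's internal LP representation: a set of
#' bounded variables, a sparse constraint matrix in triplet form with row
#' bounds, and a linear objective.  Equality rows are expressed as rows with
#' identical lower and upper bounds; one-sided rows use `-Inf`/`Inf`.  This is
#' deliberately solver-agnostic; [solve_lp()] dispatches to the bundled GLPK
#' backend.
#'
#' @param var_id character vector of variable identifiers (unique).
#' @param var_lb,var_ub numeric bounds per variable (`-Inf`/`Inf` allowed).
#' @param row_i,row_j,row_x triplet representation of the constraint matrix:
#'   integer row index, integer variable index, coefficient.
#' @param row_lb,row_ub numeric bounds per row.
#' @param obj numeric objective coefficients (one per variable).
#' @param maximize logical; maximize (`TRUE`) or minimize the objective.
#' @return An object of class `linear_program`.
#' @seealso [solve_lp()], [lp_set_objective()], [lp_set_var_bounds()],
#'   [lp_add_row()]
#' @export
linear_program <- function(var_id, var_lb, var_ub,
                           row_i = integer(), row_j = integer(),
                           row_x = numeric(),
                           row_lb = numeric(), row_ub = numeric(),
                           obj = numeric(length(var_id)),
                           maximize = TRUE) {
  n <- length(var_id)
  stopifnot(!anyDuplicated(var_id),
            length(var_lb) == n, length(var_ub) == n, length(obj) == n,
            length(row_i) == length(row_j),
            length(row_j) == length(row_x),
            length(row_lb) == length(row_ub))
  if (length(row_j) && (min(row_j) < 1L || max(row_j) > n))
    stop("row coefficient references an undeclared variable")
  if (length(row_i) && (min(row_i) < 1L || max(row_i) > length(row_lb)))
    stop("row coefficient references an undeclared row")
  if (any(var_lb > var_ub)) stop("variable lower bound exceeds upper bound")
  structure(list(var_id = as.character(var_id),
                 var_lb = as.numeric(var_lb), var_ub = as.numeric(var_ub),
                 row_i = as.integer(row_i), row_j = as.integer(row_j),
                 row_x = as.numeric(row_x),
                 row_lb = as.numeric(row_lb), row_ub = as.numeric(row_ub),
                 obj = as.numeric(obj), maximize = isTRUE(maximize)),
            class = "linear_program")
}

#' @export
print.linear_program <- function(x, ...) {
  cat(sprintf("Linear program: %d variables, %d rows, %d nonzeros (%s)\n",
              length(x$var_id), length(x$row_lb), length(x$row_x),
              if (x$maximize) "maximize" else "minimize"))
  invisible(x)
}

#' Set the objective of a linear program
#'
#' @param lp a [linear_program()].
#' @param coef named numeric vector of objective coefficients; names are
#'   variable ids, unnamed variables get coefficient zero.
#' @param maximize logical direction.
#' @return The modified `linear_program`.
#' @export
lp_set_objective <- function(lp, coef, maximize = TRUE) {
  obj <- numeric(length(lp$var_id))
  idx <- match(names(coef), lp$var_id)
  if (anyNA(idx)) stop("unknown variable in objective: ",
                       paste(names(coef)[is.na(idx)], collapse = ", "))
  obj[idx] <- as.numeric(coef)
  lp$obj <- obj
  lp$maximize <- isTRUE(maximize)
  lp
}

#' Set bounds of a single variable
#'
#' @param lp a [linear_program()].
#' @param id variable identifier.
#' @param lb,ub new bounds.
#' @return The modified `linear_program`.
#' @export
lp_set_var_bounds <- function(lp, id, lb, ub) {
  i <- match(id, lp$var_id)
  if (is.na(i)) stop("unknown variable: ", id)
  if (lb > ub) stop("lower bound exceeds upper bound")
  lp$var_lb[i] <- lb
  lp$var_ub[i] <- ub
  lp
}

#' Append a constraint row to a linear program
#'
#' @param lp a [linear_program()].
#' @param coef named numeric vector (names are variable ids).
#' @param lb,ub row bounds; equal values give an equality row.
#' @return The modified `linear_program`.
#' @export
lp_add_row <- function(lp, coef, lb, ub) {
  idx <- match(names(coef), lp$var_id)
  if (anyNA(idx)) stop("unknown variable in row: ",
                       paste(names(coef)[is.na(idx)], collapse = ", "))
  r <- length(lp$row_lb) + 1L
  lp$row_i <- c(lp$row_i, rep.int(r, length(coef)))
  lp$row_j <- c(lp$row_j, idx)
  lp$row_x <- c(lp$row_x, as.numeric(coef))
  lp$row_lb <- c(lp$row_lb, lb)
  lp$row_ub <- c(lp$row_ub, ub)
  lp
}

#' Solve a linear program
#'
#' Solves with the bundled GLPK simplex backend.
#'
#' @param lp a [linear_program()].
#' @return A list with elements `status` (one of `"optimal"`, `"infeasible"`,
#'   `"unbounded"`, `"failed"`), `objval` (objective value at the reported
#'   solution) and `x` (named numeric vector of variable values).
#' @export
solve_lp <- function(lp) {
  stopifnot(inherits(lp, "linear_program"))
  res <- .Call(C_glpk_solve,
               lp$var_lb, lp$var_ub, lp$obj, lp$maximize,
               lp$row_lb, lp$row_ub,
               lp$row_i, lp$row_j, lp$row_x)
  names(res$x) <- lp$var_id
  res
}
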