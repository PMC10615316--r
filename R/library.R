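# Candidate function libraries for implicit sparse regression.

# all exponent vectors over n variables with total degree exactly d, ordered
# with the first variable's exponent descending (the conventional layout:
# 1, x1, x2, x1^2, x1*x2, x2^2, ...)
.mono_deg <- function(n, d) {
  if (n == 1) return(matrix(as.integer(d), 1, 1))
  out <- NULL
  for (e1 in d:0) {
    rest <- .mono_deg(n - 1, d - e1)
    out <- rbind(out, cbind(as.integer(e1), rest))
  }
  out
}

monomial_exponents <- function(n, degree) {
  do.call(rbind, lapply(0:degree, function(d) .mono_deg(n, d)))
}

#' Build an implicit candidate library
#'
#' The library for a target state contains every monomial in the states up to
#' total degree `degree`, followed by the same monomials each multiplied by
#' the target state's derivative. For `n` states and degree `d` this gives
#' `2 * choose(n + d, d)` terms.
#'
#' @param states character vector of state names.
#' @param target_state the state whose derivative enters the library.
#' @param degree maximum monomial total degree (>= 0).
#' @return an object of class `function_library`: `states`, `target`,
#'   `degree`, `E` (exponent matrix for the monomial block), `terms`
#'   (readable term strings, monomial block then derivative block).
#' @export
build_implicit_library <- function(states, target_state, degree) {
  if (!target_state %in% states) stop("target_state must be one of states")
  if (degree < 0) stop("degree must be >= 0")
  E <- monomial_exponents(length(states), degree)
  colnames(E) <- states
  mono_str <- apply(E, 1, function(e) {
    s <- character(0)
    for (k in seq_along(states)) {
      if (e[k] == 1) s <- c(s, states[k])
      else if (e[k] > 1) s <- c(s, paste0(states[k], "^", e[k]))
    }
    if (!length(s)) "1" else paste(s, collapse = "*")
  })
  dname <- paste0("d", target_state)
  dmono_str <- ifelse(mono_str == "1", dname, paste0(dname, "*", mono_str))
  structure(list(states = states, target = target_state, degree = degree,
                 E = E, terms = c(mono_str, dmono_str),
                 n_mono = nrow(E)),
            class = "function_library")
}

#' @export
print.function_library <- function(x, ...) {
  cat("implicit library for d", x$target, "/dt: ", length(x$terms),
      " terms (degree ", x$degree, ", ", length(x$states), " states)\n",
      sep = "")
  cat(" [", paste(utils::head(x$terms, 12), collapse = ", "),
      if (length(x$terms) > 12) ", ..." else "", "]\n", sep = "")
  invisible(x)
}

#' Evaluate a library on data
#'
#' @param library a `function_library`.
#' @param data a `ts_data` object.
#' @return an m x |terms| numeric matrix; columns follow `library$terms`.
#' @export
evaluate_library <- function(library, data) {
  X <- data$X
  ti <- match(library$target, library$states)
  M <- apply(library$E, 1, function(e) {
    v <- rep(1, nrow(X))
    for (k in seq_along(e)) if (e[k] > 0) v <- v * X[, k]^e[k]
    v
  })
  out <- cbind(M, M * data$Xdot[, ti])
  colnames(out) <- library$terms
  out
}
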